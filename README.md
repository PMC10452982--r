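# stochid

Practical parameter identifiability analysis for stochastic models of
well-stirred biochemical reaction networks.

## The problem

Kinetic models of cellular reaction networks — epidemic-style interaction
models, enzyme kinetics, gene circuits — depend on rate parameters that
usually have to be estimated from data. Estimation only works for
parameters that are *practically identifiable*: the observed behaviour must
be sensitive to each of them, and no parameter's effect may be reproducible
by compensating changes in the others. For deterministic (ODE) models this
is classical territory; for the discrete stochastic description that is
appropriate at low copy numbers — a Markov jump process whose mean
$E[X(t)]$ is the observable — the sensitivities themselves have to be
estimated by Monte Carlo, and the identifiability machinery must be built
on top of those estimates.

`stochid` implements that pipeline end to end:

1. **Simulation** of a reaction network as an exact jump process
   (Gillespie direct method and random-time-change/next-reaction method),
   as a chemical Langevin diffusion (Euler–Maruyama), or as deterministic
   reaction rate equations.
2. **Sensitivity estimation** $S_{ik}(t_\ell) = \partial E[X_i(t_\ell)] /
   \partial c_k$ by forward finite differences over *coupled* pairs of
   exact trajectories — common random numbers (CRN), common reaction paths
   (CRP), or the coupled finite-difference construction (CFD), which
   splits each reaction into a shared channel at rate $\min(a_j, a_j')$
   and two residual channels and achieves the smallest estimator variance
   — plus pathwise Langevin sensitivities and forward sensitivity ODEs as
   cross-validation backends.
3. **Identifiability analysis** on the concatenated non-dimensional
   sensitivity matrix $s_{ik}(t_\ell) = c_k\, S_{ik}(t_\ell) /
   E[X_i(t_\ell)]$: per-parameter importance $\delta^{msqr}_k$ (column
   RMS), collinearity indices $CI_K = \lambda_{\min}(\tilde S_K^\top
   \tilde S_K)^{-1/2}$ over unit-normalized columns, the singular value
   spectrum and numerical rank, determinant measures, and automatic
   selection of identifiable parameter subsets ($\delta > 0.2$,
   $CI \le 20$).

Three case-study models ship as fixtures (`model_fixture()`): an
infectious-disease network, the Michaelis–Menten system and a bistable
genetic toggle switch. Arbitrary models are read from YAML/JSON configs
(`read_model()`), with mass-action and rational-repression kinetics.

## Worked example

```r
library(stochid)
rep <- run_pipeline("michaelis_menten", backend = "RRE")
print(rep)
#> <identifiability_report>
#>   delta_msqr: c1=1.1, c2=0.00188, c3=1.31
#>   ranked (delta > 0.2): c3, c1
#>   singular values: 72.7, 24.5, 0.0228  (rank 3)
#>   subsets: 1 tested, 1 identifiable (CI <= 20)
#>   subset size       ci       rho identifiable
#> 1  c1 c3    2 2.178917 0.7835283         TRUE
```

Reading: the binding and catalysis rates (`c1`, `c3`) matter
($\delta > 1$), while the unbinding rate `c2` barely moves the mean state
($\delta \approx 0.002$) and cannot be estimated from these observations.
The surviving pair has a low collinearity index (2.18, far below the
cutoff of 20), so `c1` and `c3` are jointly identifiable. The same
analysis with the stochastic backend (`backend = "CFD"`, `R` coupled pairs
per parameter) confirms the conclusion from the jump-process model itself:

```r
run_pipeline("michaelis_menten", backend = "CFD", R = 2000,
             theta = 0.01, seed = 1)$subsets
```

On the bistable toggle switch the deterministic backend is misleading —
its single trajectory commits to one basin — while the CFD analysis over
basin-switching stochastic paths finds all four parameters identifiable;
see the methods vignette (`vignettes/identifiability-methods.Rmd`).

A thin command-line driver is installed with the package
(`inst/cli/stochid`), exposing `simulate`, `sensitivity`, `identify` and
`compare` subcommands over the same functions.

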