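species:
- U
- V
reactions:
- reactants: []
  products:
  - U
  propensity:
    kind: rational_repression
    rate: alpha1
    exponent: beta
    regulator: V
- reactants:
  - U
  products: []
  propensity:
    kind: first
- reactants: []
  products:
  - V
  propensity:
    kind: rational_repression
    rate: alpha2
    exponent: gamma
    regulator: U
- reactants:
  - V
  products: []
  propensity:
    kind: first
parameters:
  alpha1: 50.0
  beta: 2.5
  alpha2: 16.0
  gamma: 1.0
initial_state:
  U: 0
  V: 0
horizon: 50.0
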