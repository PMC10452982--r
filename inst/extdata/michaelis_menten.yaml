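species:
- S1
- S2
- S3
- S4
reactions:
- reactants:
  - S1
  - S2
  products:
  - S3
  propensity:
    kind: second_hetero
    rate: c1
- reactants:
  - S3
  products:
  - S1
  - S2
  propensity:
    kind: first
    rate: c2
- reactants:
  - S3
  products:
  - S2
  - S4
  propensity:
    kind: first
    rate: c3
parameters:
  c1: 0.001660302174996
  c2: 0.0001
  c3: 0.1
initial_state:
  S1: 301
  S2: 120
  S3: 0
  S4: 0
horizon: 50.0
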