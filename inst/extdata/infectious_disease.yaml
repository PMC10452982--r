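species:
- S1
- S2
reactions:
- reactants:
  - S1
  products: []
  propensity:
    kind: first
    rate: c1
- reactants:
  - S2
  products: []
  propensity:
    kind: first
    rate: c2
- reactants: []
  products:
  - S1
  propensity:
    kind: zeroth
    rate: c3
- reactants: []
  products:
  - S2
  propensity:
    kind: zeroth
    rate: c4
- reactants:
  - S1
  - S2
  products:
  - S1
  - S1
  propensity:
    kind: second_hetero
    rate: c5
parameters:
  c1: 2.0
  c2: 0.1
  c3: 25.0
  c4: 75.0
  c5: 0.05
initial_state:
  S1: 20
  S2: 40
horizon: 10.0
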