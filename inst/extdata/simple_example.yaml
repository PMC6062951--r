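name: simple_example
compounds:
- X1
- X2
- X3
- X4
complexes:
  C1:
    X1: 1
  C2:
    X2: 1
  C3:
    X3: 1
  C4:
    X4: 1
reactions:
  R1:
    substrate: C1
    product: C2
    rate: k1
  R2:
    substrate: C1
    product: C3
    rate: k2
  R3:
    substrate: C2
    product: C4
    rate: k3
  R4:
    substrate: C3
    product: C4
    rate: k4
boundary:
- complex: C1
  type: in
  param: k5
- complex: C4
  type: out
  param: k6
important:
- X1
- X4
parameters:
  k1: 0.44
  k2: 0.03
  k3: 0.55000000000000004
  k4: 0.44
  k5: 0.41999999999999998
  k6: 0.33000000000000002
initial_values:
  X1: 0.40000000000000002
  X2: 0.0
  X3: 0.5
  X4: 0.40000000000000002

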