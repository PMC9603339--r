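states:
- E09
- E02
- H03
- A1
- A3
- V04
- A6
start:
  H03: 0.7
  E09: 0.1
  A1: 0.2
transitions:
  E09:
    E02: 0.8
    H03: 0.2
  E02:
    A1: 1.0
  H03:
    A1: 0.7
    A3: 0.3
  A1:
    A3: 0.3
    V04: 0.5
    A6: 0.2
  A3:
    V04: 0.7
    A6: 0.3
  V04:
    A6: 1.0
overrides:
- context:
  - E02
  - A1
  probs:
    A3: 0.9
    A6: 0.1
lengths:
  '3': 0.25
  '4': 0.25
  '5': 0.25
  '6': 0.25
terminals: A6
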