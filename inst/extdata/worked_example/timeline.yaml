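stages:
- id: pm1
  period: preMZT
- id: e1
  period: early
- id: e2
  period: early
- id: m1
  period: middle
- id: l1
  period: late
- id: l2
  period: late
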