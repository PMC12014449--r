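children:
  bw: 25.9
  at: 3285.0
  ef: 365.0
  ed: 9.0
  rfd: 0.06
  ir:
    tofu:
      median: 0.012
      min: 0.0
      max: 0.05
    corn:
      median: 0.01
      min: 0.0
      max: 0.08
    pork:
      median: 0.033
      min: 0.004
      max: 0.1
    chili:
      median: 0.028
      min: 0.002
      max: 0.08
adults:
  bw: 56.8
  at: 25550.0
  ef: 365.0
  ed: 70.0
  rfd: 0.06
  ir:
    tofu:
      median: 0.023
      min: 0.0
      max: 0.1
    corn:
      median: 0.021
      min: 0.0
      max: 0.17
    pork:
      median: 0.067
      min: 0.008
      max: 0.2
    chili:
      median: 0.056
      min: 0.004
      max: 0.17
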