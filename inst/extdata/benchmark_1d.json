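{
  "r": 2, "n_partners": 1,
  "rho1": 0.1, "a1": 1, "alpha1": 5, "cstar1": 0.2, "w1": 1,
  "x_lo": 0, "x_hi": 5, "x_min": 0
}
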