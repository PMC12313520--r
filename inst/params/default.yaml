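params:
  k_on: 3000000.0
  k_max_tmsd: 3000000.0
  k0_toe: 0.32
  b_toe: 15.0
  n_star: 6
  k_max_hmsd: 1000000.0
  v_star: 8
  dG_nt: -2.5
  dG_init: 3.0
  ddG_mm: 9.0
  dG_coop: 2.0
  dG_clamp: -4.0
  k_leak: 0.32
  temperature_C: 25.0
  C0: 1.0
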