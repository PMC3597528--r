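densities:
  na:
    soma: 5.0
    proximal: 20.0
    dendrite: 20.0
    distal: 20.0
  kdr:
    soma: 2.0
    proximal: 5.0
    dendrite: 5.0
    distal: 5.0
  hcn:
    soma: 0.0
    proximal: 0.0005
    dendrite: 0.001
    distal: 0.005
passive:
  e_leak: -68.0
  Rm: 28000.0
  Ri: 200.0
  Cm: 1.0
reversals:
  e_na: 50.0
  e_k: -77.0
  e_hcn: -20.0
kinetics:
  na_shift: 8.0
  na_h_shift: 18.0
  kdr_shift: 15.0
  na_persistent:
    frac: 0.00038
    v_half: -52.0
    slope: 16.0
    tau: 5.0
  hcn:
    v_half: -82.0
    slope: 5.0
    rate_max: 0.01
    mult_alpha: 0.33
    mult_beta: 2.0
    voltage_offset: 20.513916
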