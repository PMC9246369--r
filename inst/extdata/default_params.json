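{
  "rates": {
    "k_mis": 0.0008,
    "k_fold": 0.004,
    "k_ox": 1,
    "k_red": 0.1,
    "k_dim": 5.08658813825668e-07,
    "k_diss": 0.0005,
    "k_nuc": 0.005,
    "k_elong": 0.0002,
    "k_coal": 0.001,
    "k_settle": 0.0002,
    "K_I": 45.4421645649305,
    "w_P": 0.02,
    "w_G": 0.04,
    "dim_oxidizes": false,
    "inhibit_coal": false
  },
  "observable": {
    "note": "turbidity = w_P*P1 + w_G*(G1+S1); w_G = 2*w_P permits biphasic traces"
  }
}
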