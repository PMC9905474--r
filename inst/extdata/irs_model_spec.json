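{
  "comment": "Locked Immunotherapy Response Score model. Coefficients apply to log2(max(TMB, tmb_floor)) and to log2(nRPM+1)-log2(median+1) centered expression. Gene medians are frozen nRPM constants from the packaged synthetic reference run; reference_rpm is the housekeeping reads-per-million table of the reference sample used for nRPM scaling.",
  "coefficients": {
    "TMB": 0.273758,
    "PD-1": 0.112641,
    "PD-L1": 0.061904,
    "TOP2A": -0.077011,
    "ADAM12": -0.057991
  },
  "threshold": 0.873569,
  "gene_medians": {
    "PD-1": 30,
    "PD-L1": 60,
    "ADAM12": 100,
    "TOP2A": 150
  },
  "tmb_floor": 0.5,
  "tmb_high_cutoff": 10,
  "reference_rpm": {
    "HK1": 2000,
    "HK2": 1500,
    "HK3": 3000
  }
}
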