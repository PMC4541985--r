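{
  "species": {
    "name": "E. binotata 'Ptelea'",
    "mean_frequency": 338,
    "signals_per_bout": 6
  },
  "design": {
    "n_families": 15,
    "replicates_per_sex": 2,
    "females_per_replicate": 5,
    "males_per_replicate": 7
  },
  "architecture": {
    "G": [[32.1, -5.04], [-5.04, 40.4]],
    "V_rep": [10, 10],
    "V_within": [86.2, 353.7]
  },
  "chain": {
    "iterations": 20000,
    "burn_in": 10000,
    "thin": 10
  },
  "alpha": 0.05,
  "seed": 20150619
}
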