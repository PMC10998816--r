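{
  "params": {
    "mu_max": 0.141, "ks": 24.4, "ki": 450,
    "alpha": 3.0, "beta": 0.18,
    "y_xs": 0.22, "y_ps": 0.88, "m_s": 0.005,
    "p_crit": 110, "n_tox": 2.2,
    "x0": 0.5, "s0": 150, "t_end": 72, "dt_out": 4,
    "noise_cv": 0.02, "seed": 1
  },
  "stress": {
    "ph_min": 2.5, "ph_opt": 4.5, "ph_max": 8.0,
    "sal_opt": 0.6, "sal_decay": 0.5, "sal_decay_low": 0.25
  },
  "s0_grid": [50, 75, 100, 125, 150, 175, 200, 225, 250],
  "ph_grid": [3, 3.5, 4, 4.5, 5, 5.5, 6, 6.5, 7],
  "salinity_grid": ["distilled", "half_seawater", "seawater", "1", "2", "3", "4"],
  "base": { "s0": 175, "ph": 5.5, "salinity": "seawater" },
  "replicates": 3,
  "seed": 1,
  "alpha": 0.05,
  "fit_which": ["growth", "production"],
  "out_dir": "results/study"
}
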