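{
  "model_id": "synthetic_garfield2017_death_reduced",
  "outcome": "death",
  "horizons": [12],
  "terms": [
    {"covariate": "age", "transform": {"type": "linear"}, "beta": 0.05},
    {"covariate": "pulse", "transform": {"type": "linear"}, "beta": 0.01},
    {"covariate": "sbp", "transform": {"type": "linear"}, "beta": -0.005},
    {"covariate": "vascular_disease", "transform": {"type": "linear"}, "beta": 0.3},
    {"covariate": "bleeding_history", "transform": {"type": "linear"}, "beta": 0.2},
    {"covariate": "chf", "transform": {"type": "linear"}, "beta": 0.5},
    {"covariate": "ckd_grade3plus", "transform": {"type": "linear"}, "beta": 0.4},
    {"covariate": "oac", "transform": {"type": "linear"}, "beta": -0.4}
  ],
  "centering": {"age": 71, "pulse": 78, "sbp": 131},
  "baseline_survival": {"12": 0.96}
}
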