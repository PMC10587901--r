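{
  "model_id": "synthetic_garfield2017_stroke",
  "outcome": "stroke_se",
  "horizons": [12],
  "terms": [
    {"covariate": "age", "transform": {"type": "linear"}, "beta": 0.04},
    {"covariate": "prior_stroke_tia", "transform": {"type": "linear"}, "beta": 0.6},
    {"covariate": "bleeding_history", "transform": {"type": "linear"}, "beta": 0.15},
    {"covariate": "chf", "transform": {"type": "linear"}, "beta": 0.25},
    {"covariate": "ckd_grade3plus", "transform": {"type": "linear"}, "beta": 0.2},
    {"covariate": "ethnicity_asian", "transform": {"type": "linear"}, "beta": 0.2},
    {"covariate": "ethnicity_black_mixed_other", "transform": {"type": "linear"}, "beta": 0.1},
    {"covariate": "oac", "transform": {"type": "linear"}, "beta": -0.3}
  ],
  "centering": {"age": 71},
  "baseline_survival": {"12": 0.985}
}
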