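{
  "model_id": "synthetic_garfield2017_bleed",
  "outcome": "major_bleed",
  "horizons": [12],
  "terms": [
    {"covariate": "age", "transform": {"type": "linear"}, "beta": 0.03},
    {"covariate": "bleeding_history", "transform": {"type": "linear"}, "beta": 0.7},
    {"covariate": "antiplatelet_or_nsaid", "transform": {"type": "linear"}, "beta": 0.25},
    {"covariate": "oac", "transform": {"type": "linear"}, "beta": -0.1}
  ],
  "centering": {"age": 71},
  "baseline_survival": {"12": 0.99}
}
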