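{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "af-risk-model-spec",
  "title": "Coefficient file for a Cox risk equation",
  "type": "object",
  "required": ["model_id", "outcome", "horizons", "terms", "baseline_survival"],
  "properties": {
    "model_id": { "type": "string", "minLength": 1 },
    "outcome": { "enum": ["death", "stroke_se", "major_bleed"] },
    "horizons": {
      "type": "array",
      "items": { "type": "number", "exclusiveMinimum": 0 },
      "minItems": 1,
      "description": "months, strictly increasing"
    },
    "terms": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["covariate", "transform", "beta"],
        "properties": {
          "covariate": { "type": "string" },
          "beta": { "type": "number" },
          "transform": {
            "type": "object",
            "required": ["type"],
            "properties": {
              "type": { "enum": ["linear", "log", "linear_spline", "indicator_gt"] },
              "knot": { "type": "number" },
              "threshold": { "type": "number" }
            }
          }
        }
      }
    },
    "centering": {
      "oneOf": [
        { "const": "precentered" },
        { "type": "object", "additionalProperties": { "type": "number" } }
      ],
      "description": "reference covariate values subtracted from each term; covariates not listed are referenced at 0"
    },
    "baseline_survival": {
      "type": "object",
      "additionalProperties": { "type": "number", "exclusiveMinimum": 0, "maximum": 1 },
      "description": "keys are horizons in months; values S0(t), non-increasing in horizon"
    }
  }
}
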