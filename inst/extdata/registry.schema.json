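{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "sahrisk evidence registry",
  "description": "All model parameters for SAH risk estimation. Every leaf parameter is an object {value, ci, provenance} so that each number carries its source. Validation enforced by sahrisk::load_registry().",
  "type": "object",
  "required": ["baseline_prevalence", "tests", "ottawa_items", "weights", "thresholds"],
  "additionalProperties": false,
  "definitions": {
    "param": {
      "type": "object",
      "required": ["value", "provenance"],
      "properties": {
        "value": {"type": "number"},
        "ci": {
          "oneOf": [
            {"type": "null"},
            {"type": "array", "items": {"type": "number"}, "minItems": 2, "maxItems": 2}
          ]
        },
        "provenance": {"type": "string"}
      },
      "additionalProperties": false
    },
    "proportion_param": {
      "allOf": [{"$ref": "#/definitions/param"}],
      "properties": {"value": {"minimum": 0, "maximum": 1}}
    }
  },
  "properties": {
    "baseline_prevalence": {
      "$ref": "#/definitions/proportion_param",
      "description": "Baseline SAH prevalence in the ED headache population; must lie strictly inside (0,1)."
    },
    "tests": {
      "type": "object",
      "required": ["noncontrast_ct", "ct_angiogram"],
      "additionalProperties": {
        "type": "object",
        "required": ["label", "sensitivity", "specificity"],
        "properties": {
          "label": {"type": "string"},
          "sensitivity": {"$ref": "#/definitions/proportion_param"},
          "specificity": {"$ref": "#/definitions/proportion_param"},
          "time_model": {
            "type": "object",
            "description": "Exponential decay: sensitivity(t) = s0 * exp(-rate * t), t in hours since symptom onset. Mutually exclusive with 'stratified'.",
            "required": ["s0", "rate"],
            "properties": {
              "s0": {"$ref": "#/definitions/proportion_param"},
              "rate": {"$ref": "#/definitions/param"}
            },
            "additionalProperties": false
          },
          "stratified": {
            "type": "array",
            "description": "Half-open time bands [low, high) in hours since symptom onset; high = null means unbounded. Mutually exclusive with 'time_model'.",
            "items": {
              "type": "object",
              "required": ["low", "sensitivity"],
              "properties": {
                "low": {"type": "number", "minimum": 0},
                "high": {"oneOf": [{"type": "null"}, {"type": "number"}]},
                "sensitivity": {"$ref": "#/definitions/proportion_param"}
              },
              "additionalProperties": false
            }
          }
        },
        "additionalProperties": false
      }
    },
    "ottawa_items": {
      "type": "object",
      "description": "Clinical findings updating the pre-test probability. For each item lr_positive >= 1 >= lr_negative > 0.",
      "additionalProperties": {
        "type": "object",
        "required": ["label", "lr_positive", "lr_negative"],
        "properties": {
          "label": {"type": "string"},
          "lr_positive": {"$ref": "#/definitions/param"},
          "lr_negative": {"$ref": "#/definitions/param"}
        },
        "additionalProperties": false
      }
    },
    "weights": {
      "type": "object",
      "description": "Nonnegative procedural-difficulty weights per LP risk factor.",
      "required": ["difficult_habitus", "antithrombotic_use"],
      "additionalProperties": {"$ref": "#/definitions/param"}
    },
    "thresholds": {
      "type": "object",
      "required": ["base_test_threshold", "yellow_band_ratio", "weight_scale"],
      "properties": {
        "base_test_threshold": {"$ref": "#/definitions/proportion_param"},
        "yellow_band_ratio": {"$ref": "#/definitions/param"},
        "weight_scale": {"$ref": "#/definitions/param"}
      },
      "additionalProperties": false
    }
  }
}
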