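{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "ipQC consolidated QC report",
  "type": "object",
  "required": ["tool", "config", "runs"],
  "properties": {
    "tool": {
      "type": "object",
      "required": ["name", "version"],
      "properties": {
        "name": {"type": "string"},
        "version": {"type": "string"}
      }
    },
    "config": {
      "type": "object",
      "required": ["nRuns", "deconvLengths"],
      "properties": {
        "nRuns": {"type": "integer", "minimum": 1},
        "deconvLengths": {},
        "predictor": {
          "type": "object",
          "required": ["backend", "alleles", "nBackground", "calibrationSeed"],
          "properties": {
            "backend": {"type": "string"},
            "alleles": {"type": "array", "items": {"type": "string"}},
            "nBackground": {"type": "integer", "minimum": 1000},
            "calibrationSeed": {"type": "integer"}
          }
        }
      }
    },
    "runs": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["run_id", "tissue", "n_peptides", "length_distribution"],
        "properties": {
          "run_id": {"type": "string"},
          "tissue": {"enum": ["tumor", "benign", "cell_line"]},
          "n_peptides": {"type": "integer", "minimum": 0},
          "length_distribution": {
            "type": "object",
            "required": ["table", "fraction_8_13", "fraction_9_of_all"],
            "properties": {
              "fraction_8_13": {"type": "number", "minimum": 0, "maximum": 100},
              "fraction_9_of_all": {"type": "number", "minimum": 0, "maximum": 100},
              "fraction_9_of_8_13": {"type": ["number", "null"], "minimum": 0, "maximum": 100}
            }
          },
          "binder_fraction_8_13": {"type": ["number", "null"], "minimum": 0, "maximum": 100},
          "binder_fraction_9": {"type": ["number", "null"], "minimum": 0, "maximum": 100},
          "specificity": {
            "type": "object",
            "required": ["composition", "non_binders", "unassignable"],
            "properties": {
              "non_binders": {"type": "integer", "minimum": 0},
              "unassignable": {"type": "integer", "minimum": 0}
            }
          }
        }
      }
    },
    "overlap": {
      "type": ["array", "null"],
      "items": {
        "type": "object",
        "required": ["subset", "degree", "size"],
        "properties": {
          "subset": {"type": "string"},
          "degree": {"type": "integer", "minimum": 1},
          "size": {"type": "integer", "minimum": 0}
        }
      }
    }
  }
}
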