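{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "toposcreen run configuration",
  "type": "object",
  "required": ["out_dir", "simulate", "master_seed"],
  "properties": {
    "out_dir": {"type": "string"},
    "simulate": {"type": "boolean"},
    "data_dir": {"type": ["string", "null"]},
    "master_seed": {"type": "integer"},
    "n_designs": {"type": "integer", "minimum": 1},
    "n_rows": {"type": "integer", "minimum": 1},
    "n_cols": {"type": "integer", "minimum": 1},
    "resolution_um": {"type": "number", "exclusiveMinimum": 0},
    "qc_multiplier": {"type": "number", "exclusiveMinimum": 0},
    "threshold_method": {"enum": ["intersection", "fixed"]},
    "percentile": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 100},
    "alpha": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1},
    "adjusted": {"type": "boolean"},
    "ml_features": {
      "type": "array",
      "items": {"enum": ["design", "shape"]},
      "minItems": 1
    },
    "n_repeats": {"type": "integer", "minimum": 1},
    "train_fraction": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1},
    "cv_folds": {"type": "integer", "minimum": 2},
    "num_trees": {"type": "integer", "minimum": 1},
    "log_level": {"enum": ["info", "quiet"]}
  },
  "additionalProperties": true
}
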