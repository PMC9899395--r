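{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "gbs3d design report",
  "type": "object",
  "required": ["parameters", "prediction"],
  "properties": {
    "parameters": {
      "type": "object",
      "required": ["enzymes", "rare_set", "frequent_cutter", "size_window",
                   "reads_per_sample", "genome_length"],
      "properties": {
        "enzymes": {"type": "array", "items": {"type": "string"}},
        "rare_set": {"type": ["array", "string"]},
        "frequent_cutter": {"type": "string"},
        "size_window": {"type": "array", "items": {"type": "number"}},
        "adapter_extension": {"type": "number"},
        "reads_per_sample": {"type": "number"},
        "min_depth": {"type": "number"},
        "run_capacity": {"type": ["number", "null"]},
        "partial_block_prob": {"type": "number"},
        "seed": {"type": ["number", "null"]},
        "genome_length": {"type": "number"},
        "n_sequences": {"type": "number"}
      }
    },
    "prediction": {
      "type": "object",
      "required": ["n_selected", "captured_bases", "genome_length",
                   "coverage_fraction"],
      "properties": {
        "n_selected": {"type": "number"},
        "captured_bases": {"type": "number"},
        "genome_length": {"type": "number"},
        "coverage_fraction": {"type": "number"},
        "coverage_percent": {"type": "number"},
        "pairs": {"type": "array"},
        "per_chromosome": {"type": "array"}
      }
    },
    "budget": {
      "type": ["object", "null"],
      "properties": {
        "n_fragments": {"type": "number"},
        "reads_per_sample": {"type": "number"},
        "lambda": {"type": "number"},
        "dropout_probability": {"type": "number"},
        "min_depth": {"type": "number"},
        "p_below_min_depth": {"type": "number"},
        "run_capacity": {"type": ["number", "null"]},
        "multiplex_capacity": {"type": ["number", "null"]}
      }
    }
  }
}
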