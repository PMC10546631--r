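{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "WebRDS monitoring report",
  "type": "object",
  "required": ["generated_at", "sample_descriptives", "performance",
               "stalled_tokens", "convergence_snapshot", "duplicate_alerts"],
  "properties": {
    "generated_at": {"type": "string"},
    "sample_descriptives": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["variable", "category", "n", "pct"],
        "properties": {
          "variable": {"type": "string"},
          "category": {"type": "string"},
          "n": {"type": "integer"},
          "pct": {"type": "number"}
        }
      }
    },
    "performance": {
      "type": "object",
      "required": ["n_total", "n_seeds", "n_after_seed_removal",
                   "out_degree_histogram", "pct_recruited_ge1",
                   "pct_recruited_ge2", "pct_recruited_3",
                   "chain_length_median", "chain_length_min",
                   "chain_length_max", "largest_tree_size",
                   "largest_tree_pct"],
      "properties": {
        "n_total": {"type": "integer"},
        "n_seeds": {"type": "integer"},
        "n_after_seed_removal": {"type": "integer"},
        "out_degree_histogram": {"type": "object"},
        "pct_recruited_ge1": {"type": "number"},
        "pct_recruited_ge2": {"type": "number"},
        "pct_recruited_3": {"type": "number"},
        "chain_length_median": {"type": "number"},
        "chain_length_min": {"type": "integer"},
        "chain_length_max": {"type": "integer"},
        "largest_tree_size": {"type": "integer"},
        "largest_tree_pct": {"type": "number"}
      }
    },
    "stalled_tokens": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "token", "uses_left", "days_since_completion"],
        "properties": {
          "id": {"type": "integer"},
          "token": {"type": "string"},
          "uses_left": {"type": "integer"},
          "days_since_completion": {"type": "number"},
          "contact": {"type": "string"}
        }
      }
    },
    "convergence_snapshot": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["variable", "category", "estimate"],
        "properties": {
          "variable": {"type": "string"},
          "category": {"type": "string"},
          "estimate": {"type": "number"}
        }
      }
    },
    "duplicate_alerts": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["member_ids", "evidence", "kept_id"],
        "properties": {
          "member_ids": {"type": "array"},
          "evidence": {"type": "string"},
          "kept_id": {"type": "integer"}
        }
      }
    }
  }
}
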