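{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "tmatriad hypothesis test report",
  "type": "object",
  "required": ["model", "table", "test", "p_value", "alpha", "decision", "provenance"],
  "properties": {
    "model": {
      "type": "object",
      "required": ["shared", "classifier", "dependent", "direction"]
    },
    "table": {
      "type": "object",
      "required": ["n11", "n12", "n21", "n22"],
      "properties": {
        "n11": {"type": "integer", "minimum": 0},
        "n12": {"type": "integer", "minimum": 0},
        "n21": {"type": "integer", "minimum": 0},
        "n22": {"type": "integer", "minimum": 0}
      }
    },
    "test": {"type": "string"},
    "p_value": {"type": "number", "minimum": 0, "maximum": 1},
    "alpha": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1},
    "decision": {"enum": ["supported", "rejected"]},
    "provenance": {
      "type": "object",
      "required": ["n_cores", "n_slides", "n_experiments"]
    }
  }
}
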