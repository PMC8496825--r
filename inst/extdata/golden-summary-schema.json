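{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "hdring run digest",
  "type": "object",
  "required": ["protocol", "seed", "tests"],
  "properties": {
    "protocol": {"type": "string"},
    "seed": {"type": "integer"},
    "tests": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["test", "scenery", "recruited"],
        "properties": {
          "test": {"type": "string"},
          "scenery": {"type": "string"},
          "recruited": {"type": "integer"},
          "mean_lobes": {"type": "number"},
          "all_unimodal": {"type": "boolean"},
          "heading_mean": {"type": "number"}
        }
      }
    },
    "iou": {"type": "object"}
  }
}
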