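{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Screening protocol configuration",
  "type": "object",
  "properties": {
    "screening_level": {"type": "integer", "description": "dB HL; must be a device-supported level", "default": 20},
    "required_frequencies": {
      "type": "array",
      "items": {"enum": [250, 500, 1000, 2000, 4000, 8000]},
      "minItems": 1,
      "default": [1000, 2000, 4000]
    },
    "ears_required": {"const": "both"},
    "enforce_order": {"type": "boolean", "default": true}
  }
}
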