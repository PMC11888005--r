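{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Tympanometry normative ranges",
  "type": "object",
  "properties": {
    "peak_pressure": {"$ref": "#/definitions/range", "description": "daPa"},
    "static_compliance": {"$ref": "#/definitions/range", "description": "mL"},
    "ecv": {
      "type": "object",
      "properties": {
        "child": {"$ref": "#/definitions/range"},
        "adult": {"$ref": "#/definitions/range"}
      },
      "description": "Equivalent ear canal volume range (mL) per age band"
    }
  },
  "definitions": {
    "range": {
      "type": "array",
      "items": {"type": "number"},
      "minItems": 2,
      "maxItems": 2,
      "description": "[min, max] with min < max"
    }
  }
}
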