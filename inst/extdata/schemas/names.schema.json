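{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Name pool",
  "type": "array",
  "minItems": 1,
  "items": {
    "type": "object",
    "required": ["name", "sex"],
    "properties": {
      "name": {"type": "string", "minLength": 1},
      "sex": {"enum": ["female", "male"]}
    }
  }
}
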