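{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Scripted session actions",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["action"],
    "properties": {
      "action": {
        "enum": ["select_mode", "select_ear", "set_level", "set_frequency",
                 "oto_exam", "tymp_exam", "present_tone", "save_notes",
                 "end_session"]
      },
      "params": {
        "type": "object",
        "properties": {
          "mode": {"enum": ["otoscopy", "tympanometry", "audiometry"]},
          "ear": {"enum": ["left", "right"]},
          "level": {"type": "integer", "minimum": -10, "maximum": 90, "multipleOf": 5},
          "frequency": {"enum": [250, 500, 1000, 2000, 4000, 8000]},
          "notes": {"type": "object"}
        }
      }
    }
  }
}
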