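{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Patient roster",
  "type": "object",
  "required": ["patients"],
  "properties": {
    "patients": {
      "type": "array",
      "minItems": 1,
      "items": {"$ref": "#/definitions/patient"}
    }
  },
  "definitions": {
    "patient": {
      "type": "object",
      "required": ["id", "age_years", "case_history_template", "explanation",
                   "audiogram", "tympanogram", "otoscopy"],
      "properties": {
        "id": {"type": "string", "minLength": 1},
        "age_years": {"type": "number", "exclusiveMinimum": 0},
        "condition": {"type": "string"},
        "case_history_template": {
          "type": "string",
          "description": "Backstory with {name}, {age}, {sex}, {pronoun_subject}, {pronoun_object}, {pronoun_possessive} placeholders (capitalised variants allowed)."
        },
        "explanation": {"type": "string"},
        "audiogram": {"$ref": "#/definitions/perEar_audiogram"},
        "tympanogram": {"$ref": "#/definitions/perEar_tympanogram"},
        "otoscopy": {"$ref": "#/definitions/perEar_otoscopy"}
      }
    },
    "perEar_audiogram": {
      "type": "object",
      "required": ["left", "right"],
      "properties": {
        "left": {"$ref": "#/definitions/audiogram"},
        "right": {"$ref": "#/definitions/audiogram"}
      }
    },
    "audiogram": {
      "type": "object",
      "required": ["thresholds"],
      "properties": {
        "thresholds": {
          "type": "object",
          "description": "Keys are frequencies in Hz from {250,500,1000,2000,4000,8000}; must include every protocol-required frequency. Values are thresholds in dB HL.",
          "additionalProperties": {"type": "integer", "minimum": -10, "maximum": 120}
        },
        "inconsistency": {
          "type": "object",
          "description": "Optional psychometric parameters; absent means a deterministic step listener.",
          "properties": {
            "slope": {"type": "number", "minimum": 0},
            "guess": {"type": "number", "minimum": 0, "exclusiveMaximum": 1},
            "lapse": {"type": "number", "minimum": 0, "exclusiveMaximum": 1}
          }
        }
      }
    },
    "perEar_tympanogram": {
      "type": "object",
      "required": ["left", "right"],
      "properties": {
        "left": {"$ref": "#/definitions/tympanogram"},
        "right": {"$ref": "#/definitions/tympanogram"}
      }
    },
    "tympanogram": {
      "type": "object",
      "required": ["peak_present", "ear_canal_volume"],
      "properties": {
        "peak_present": {"type": "boolean"},
        "peak_pressure": {"type": "number", "minimum": -400, "maximum": 200},
        "static_compliance": {"type": "number", "minimum": 0},
        "ear_canal_volume": {"type": "number", "exclusiveMinimum": 0}
      }
    },
    "perEar_otoscopy": {
      "type": "object",
      "required": ["left", "right"],
      "properties": {
        "left": {"$ref": "#/definitions/otoscopy"},
        "right": {"$ref": "#/definitions/otoscopy"}
      }
    },
    "otoscopy": {
      "type": "object",
      "required": ["category"],
      "properties": {
        "category": {
          "enum": ["clear_normal", "occluding_cerumen", "erythema", "effusion",
                   "perforation", "pe_tube", "foreign_body", "other"]
        },
        "description": {"type": "string"},
        "image_ref": {"type": "string"}
      }
    }
  }
}
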