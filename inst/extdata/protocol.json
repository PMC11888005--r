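{
  "screening_level": 20,
  "required_frequencies": [1000, 2000, 4000],
  "ears_required": "both",
  "enforce_order": true
}
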