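{
  "peak_pressure": [-150, 100],
  "static_compliance": [0.3, 1.5],
  "ecv": {
    "child": [0.4, 1.0],
    "adult": [0.6, 2.0]
  }
}
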