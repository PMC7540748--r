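{
  "n_events": 15,
  "chance_level": 0.25,
  "ceiling_threshold": 0.95,
  "floor_threshold": 0.3,
  "exclusion_scope": "overall"
}
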