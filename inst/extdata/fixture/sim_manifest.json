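{
  "seed": 420,
  "config_hash": "3ec024c95e75636d584f4b7dddddab34",
  "generator": "kmeflow simulate_study"
}
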