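{
  "name": "human_constant",
  "species": "Homo sapiens",
  "citation": "stdpopsim default constant-size model for HomSap",
  "c": 1.30981e-08,
  "default_Q": 10,
  "epochs": [
    {"duration": null, "size_start": 10000, "growth_rate": 0}
  ]
}
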