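{
  "name": "athal_constant",
  "species": "Arabidopsis thaliana",
  "citation": "stdpopsim default constant-size model for AraTha",
  "c": 8.06452e-10,
  "default_Q": 10,
  "epochs": [
    {"duration": null, "size_start": 10000, "growth_rate": 0}
  ]
}
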