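{
  "name": "dmel_constant",
  "species": "Drosophila melanogaster",
  "citation": "stdpopsim default constant-size model for DroMel (Li & Stephan 2006)",
  "c": 1.7966e-08,
  "default_Q": 100,
  "epochs": [
    {"duration": null, "size_start": 1720600, "growth_rate": 0}
  ]
}
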