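{
  "name": "dmel_3epoch_sheehan",
  "species": "Drosophila melanogaster",
  "citation": "African three-epoch model of Sheehan & Song (2016); stdpopsim African3Epoch_1S16",
  "c": 1.7966e-08,
  "default_Q": 100,
  "epochs": [
    {"duration": null, "size_start": 652700, "growth_rate": 0},
    {"duration": 2000000, "size_start": 145300, "growth_rate": 0},
    {"duration": 200000, "size_start": 544200, "growth_rate": 0}
  ]
}
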