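{
  "name": "athal_3epoch_SMA",
  "species": "Arabidopsis thaliana",
  "citation": "South Middle Atlas three-epoch model of Huber et al. (2018); stdpopsim African3Epoch_1H18",
  "c": 8.06452e-10,
  "default_Q": 10,
  "epochs": [
    {"duration": null, "size_start": 161744, "growth_rate": 0},
    {"duration": 7420, "size_start": 24076, "growth_rate": 0},
    {"duration": 14534, "size_start": 203077, "growth_rate": 0}
  ]
}
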