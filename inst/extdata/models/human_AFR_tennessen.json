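{
  "name": "human_AFR_tennessen",
  "species": "Homo sapiens",
  "citation": "AFR population of Tennessen et al. (2012) two-population model; stdpopsim OutOfAfrica_2T12, single-population size trajectory (no migration)",
  "c": 1.30981e-08,
  "default_Q": 10,
  "epochs": [
    {"duration": null, "size_start": 7310, "growth_rate": 0},
    {"duration": 5715, "size_start": 14474, "growth_rate": 0},
    {"duration": 205, "size_start": 14474, "growth_rate": 0.0166}
  ]
}
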