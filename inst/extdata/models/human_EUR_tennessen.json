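{
  "name": "human_EUR_tennessen",
  "species": "Homo sapiens",
  "citation": "EUR population of Tennessen et al. (2012) two-population model; stdpopsim OutOfAfrica_2T12, single-population size trajectory (no migration); ancestral epochs shared with AFR",
  "c": 1.30981e-08,
  "default_Q": 10,
  "epochs": [
    {"duration": null, "size_start": 7310, "growth_rate": 0},
    {"duration": 3880, "size_start": 14474, "growth_rate": 0},
    {"duration": 1120, "size_start": 1861, "growth_rate": 0},
    {"duration": 715, "size_start": 1032, "growth_rate": 0.00307},
    {"duration": 205, "size_start": 9279.212349452768, "growth_rate": 0.0195}
  ]
}
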