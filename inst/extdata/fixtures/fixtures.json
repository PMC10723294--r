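[
  {"name": "hard_fixed", "fixed": true,
   "counts": {"AB": 200}},
  {"name": "pseudo_soft_fixed", "fixed": true,
   "counts": {"AB": 195, "aB": 5}},
  {"name": "pseudo_soft_fixed_10", "fixed": true,
   "counts": {"AB": 190, "aB": 10}},
  {"name": "original_lost", "fixed": true,
   "counts": {"aB": 200}},
  {"name": "unfixed_partial_soft", "fixed": false,
   "counts": {"AB": 40, "aB": 10, "ab": 150}},
  {"name": "unfixed_hard", "fixed": false,
   "counts": {"AB": 60, "ab": 140}},
  {"name": "unfixed_no_B", "fixed": false,
   "counts": {"ab": 199, "Ab": 1}},
  {"name": "sample_hard_pop_soft", "fixed": true,
   "counts": {"AB": 200},
   "pop_counts": {"AB": 1995, "aB": 5}}
]
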