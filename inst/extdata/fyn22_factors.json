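[
  {"name": "soluble_starch", "symbol": "A", "unit": "1e-2 g/ml", "center": 1.2, "step": 0.2, "g_per_l": 10},
  {"name": "yeast",          "symbol": "B", "unit": "1e-3 g/ml", "center": 2.5, "step": 0.5, "g_per_l": 1},
  {"name": "nh4cl",          "symbol": "C", "unit": "1e-3 g/ml", "center": 1.5, "step": 0.5, "g_per_l": 1},
  {"name": "fecl3",          "symbol": "D", "unit": "1e-3 g/ml", "center": 0.8, "step": 0.1, "g_per_l": 1}
]
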