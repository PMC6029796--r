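{
  "currency": "AUD, 2011 prices",
  "program_costs": {
    "hinh_staff": 361943,
    "in_kind": 77294,
    "travel": 6835,
    "admin_training": 10858,
    "stationery": 720,
    "telephone": 2136,
    "equipment_price": 19100,
    "office_space": 9230
  },
  "equipment_life": 1,
  "discount_rate": 0,
  "utilisation": {
    "a": 63.19,
    "b": 49.77,
    "c": 13.09,
    "d": 80.22,
    "e": -10.47,
    "f": -23.48,
    "g": -6.14,
    "h": -15.27,
    "i": 0.5,
    "j": 2.485
  },
  "unit_costs": {
    "k": 193,
    "l": 70,
    "m": 679
  },
  "distributions": [
    {"id": "equipment_life", "kind": "uniform", "lo": 0, "hi": 10},
    {"id": "discount_rate", "kind": "uniform", "lo": 0, "hi": 0.05},
    {"id": "a", "kind": "poisson", "baseline": 63.19, "se": 6.58},
    {"id": "b", "kind": "poisson", "baseline": 49.77, "se": 7.11},
    {"id": "c", "kind": "gamma_mom", "baseline": 13.09, "se": 1.06},
    {"id": "d", "kind": "gamma_mom", "baseline": 80.22, "se": 23.28},
    {"id": "e", "kind": "normal", "baseline": -10.47, "se": 7.09},
    {"id": "f", "kind": "normal", "baseline": -23.48, "se": 7.35},
    {"id": "g", "kind": "normal", "baseline": -6.14, "se": 0.99},
    {"id": "h", "kind": "normal", "baseline": -15.27, "se": 17.09},
    {"id": "i", "kind": "uniform", "baseline": 0.5, "lo": 0.375, "hi": 0.625},
    {"id": "k", "kind": "triangular", "lo": 144.75, "mode": 193, "hi": 241.25},
    {"id": "l", "kind": "triangular", "lo": 52.5, "mode": 70, "hi": 87.5},
    {"id": "m", "kind": "triangular", "lo": 509.25, "mode": 679, "hi": 848.75}
  ]
}
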