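[
  {"name": "pH", "group": "II", "units": "", "transform": "raw",
   "curve": "parabolic", "thresholds": {"L1": 3, "L": 5, "H": 7, "H1": 9}},
  {"name": "SOM", "group": "II", "units": "g/kg", "transform": "raw",
   "curve": "s_type", "thresholds": {"L": 6, "H": 40}},
  {"name": "CEC", "group": "II", "units": "cmol(+)/kg", "transform": "raw",
   "curve": "s_type", "thresholds": {"L": 10, "H": 20}},
  {"name": "A-N", "group": "II", "units": "mg/kg", "transform": "raw",
   "curve": "s_type", "thresholds": {"L": 30, "H": 150}},
  {"name": "A-P", "group": "II", "units": "mg/kg", "transform": "raw",
   "curve": "s_type", "thresholds": {"L": 3, "H": 40}},
  {"name": "A-K", "group": "II", "units": "mg/kg", "transform": "raw",
   "curve": "s_type", "thresholds": {"L": 30, "H": 200}},
  {"name": "AHM", "group": "III", "units": "mg/kg",
   "transform": "reduction_rate", "curve": "s_type",
   "thresholds": {"L": 0, "H": 75}, "metal": "Cd",
   "note": "scored on the reduction rate alpha (percent) via a rising ramp; the worked-example scores rise with alpha against H = 75%"},
  {"name": "THM", "group": "I", "units": "mg/kg", "transform": "raw",
   "curve": "inverse_s", "thresholds": {"L": 0.6, "H": 3.0}, "metal": "Cd",
   "standard_limit": 0.6,
   "note": "Cd screening/control values; reconfigure per metal for other contaminants"},
  {"name": "biomass", "group": "II", "units": "ratio",
   "transform": "ratio_to_reference", "curve": "s_type",
   "thresholds": {"L": 0, "H": 1}, "reference_value": 1.27,
   "assumption": true,
   "note": "reference crop weight (g) back-computed from the published worked-example scores; the published threshold table lists H = 0.8, but the worked example scores biomass by the ratio itself capped at 1"},
  {"name": "production", "group": "II", "units": "ratio",
   "transform": "ratio_to_reference", "curve": "s_type",
   "thresholds": {"L": 0, "H": 0.9},
   "note": "reference_value (average local production) is a mandatory site-specific input"},
  {"name": "edible_hm", "group": "I", "units": "mg/kg", "transform": "raw",
   "curve": "inverse_s", "thresholds": {"L": 0, "H": 0.2}, "metal": "Cd",
   "standard_limit": 0.2},
  {"name": "aboveground_hm", "group": "III", "units": "mg/kg",
   "transform": "baf", "curve": "inverse_s",
   "thresholds": {"L": 10, "H": 100},
   "note": "scored on the bio-accumulation factor (percent)"},
  {"name": "root_hm", "group": "III", "units": "mg/kg", "transform": "baf",
   "curve": "inverse_s", "thresholds": {"L": 10, "H": 100},
   "note": "scored on the bio-accumulation factor (percent)"},
  {"name": "cost", "group": "II", "units": "ratio",
   "transform": "ratio_to_reference", "curve": "inverse_s",
   "thresholds": {"L": 0.5, "H": 0.7}, "reference_value": 1.0,
   "assumption": true,
   "note": "cost / crop revenue; unit revenue placeholder, set per project"},
  {"name": "amendment_hm", "group": "I", "units": "mg/kg",
   "transform": "raw", "curve": "inverse_s", "thresholds": {"L": 0, "H": 10},
   "metal": "Cd", "standard_limit": 10},
  {"name": "stability", "group": "III", "units": "years", "transform": "raw",
   "curve": "s_type", "thresholds": {"L": 0, "H": 3},
   "note": "amendment effect lifetime; 3-year life cycle as the criterion"}
]
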