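[
  {"organ": "lung",  "x": 50, "cohort": "left_pmrmrt",  "slope": -0.05, "intercept": 6.88,  "r_squared": 0.51, "p_value": null, "n": 93,  "p_bound": "<0.001", "source": "published"},
  {"organ": "lung",  "x": 35, "cohort": "left_pmrmrt",  "slope": -0.33, "intercept": 17.84, "r_squared": 0.61, "p_value": null, "n": 93,  "p_bound": "<0.001", "source": "published"},
  {"organ": "lung",  "x": 25, "cohort": "left_pmrmrt",  "slope": -0.80, "intercept": 32.08, "r_squared": 0.65, "p_value": null, "n": 93,  "p_bound": "<0.001", "source": "published"},
  {"organ": "heart", "x": 10, "cohort": "left_pmrmrt",  "slope": -0.92, "intercept": 28.45, "r_squared": 0.70, "p_value": null, "n": 93,  "p_bound": "<0.001", "source": "published"},
  {"organ": "heart", "x": 5,  "cohort": "left_pmrmrt",  "slope": -1.63, "intercept": 43.62, "r_squared": 0.68, "p_value": null, "n": 93,  "p_bound": "<0.001", "source": "published"},
  {"organ": "lung",  "x": 50, "cohort": "right_pmrmrt", "slope": -0.04, "intercept": 6.58,  "r_squared": 0.52, "p_value": null, "n": 104, "p_bound": "<0.001", "source": "published"},
  {"organ": "lung",  "x": 35, "cohort": "right_pmrmrt", "slope": -0.17, "intercept": 14.17, "r_squared": 0.51, "p_value": null, "n": 104, "p_bound": "<0.001", "source": "published"},
  {"organ": "lung",  "x": 25, "cohort": "right_pmrmrt", "slope": -0.67, "intercept": 29.35, "r_squared": 0.62, "p_value": null, "n": 104, "p_bound": "<0.001", "source": "published"},
  {"organ": "lung",  "x": 50, "cohort": "left_bcrt",    "slope": -0.04, "intercept": 4.99,  "r_squared": 0.53, "p_value": null, "n": 71,  "p_bound": "<0.001", "source": "published"},
  {"organ": "lung",  "x": 35, "cohort": "left_bcrt",    "slope": -0.27, "intercept": 15.31, "r_squared": 0.64, "p_value": null, "n": 71,  "p_bound": "<0.001", "source": "published"},
  {"organ": "lung",  "x": 25, "cohort": "left_bcrt",    "slope": -0.70, "intercept": 28.28, "r_squared": 0.72, "p_value": null, "n": 71,  "p_bound": "<0.001", "source": "published"},
  {"organ": "heart", "x": 10, "cohort": "left_bcrt",    "slope": -0.93, "intercept": 29.36, "r_squared": 0.72, "p_value": null, "n": 71,  "p_bound": "<0.001", "source": "published"},
  {"organ": "heart", "x": 5,  "cohort": "left_bcrt",    "slope": -1.54, "intercept": 37.57, "r_squared": 0.69, "p_value": null, "n": 71,  "p_bound": "<0.001", "source": "published"},
  {"organ": "lung",  "x": 50, "cohort": "right_bcrt",   "slope": -0.04, "intercept": 5.35,  "r_squared": 0.55, "p_value": null, "n": 54,  "p_bound": "<0.001", "source": "published"},
  {"organ": "lung",  "x": 35, "cohort": "right_bcrt",   "slope": -0.15, "intercept": 11.04, "r_squared": 0.59, "p_value": null, "n": 54,  "p_bound": "<0.001", "source": "published"},
  {"organ": "lung",  "x": 25, "cohort": "right_bcrt",   "slope": -0.56, "intercept": 23.87, "r_squared": 0.68, "p_value": null, "n": 54,  "p_bound": "<0.001", "source": "published"}
]
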