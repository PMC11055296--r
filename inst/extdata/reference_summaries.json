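{
  "description": "Published cohort summary statistics (n, mean, SD in mm) for the six talar trochlear regions and the cylinder-fit radius, from a CT morphometry study of 91 tali (61 subjects: 28 male, 33 female; 41 right, 50 left; median age 38 y). Sex-specific talus counts were not published and are reconstructed (37 male + 54 female = 91) from the reported pooled t statistic.",
  "regions": [
    {"label": "AM", "n": 91, "mean": 15.97, "sd": 3.08, "min": 10.19, "max": 25.51},
    {"label": "AL", "n": 91, "mean": 22.06, "sd": 3.94, "min": 14.78, "max": 38.74},
    {"label": "PL", "n": 91, "mean": 27.95, "sd": 12.08, "min": 16.07, "max": 89.98},
    {"label": "PM", "n": 91, "mean": 34.17, "sd": 16.22, "min": 14.4, "max": 91.41},
    {"label": "MP", "n": 91, "mean": 22.44, "sd": 5.05, "min": 15.34, "max": 52.98},
    {"label": "MA", "n": 91, "mean": 16.97, "sd": 3.09, "min": 10.46, "max": 27.87}
  ],
  "fitted_radius": {
    "by_sex": [
      {"label": "male", "n": 37, "mean": 21.90, "sd": 1.97, "n_reconstructed": true},
      {"label": "female", "n": 54, "mean": 19.57, "sd": 1.26, "n_reconstructed": true}
    ],
    "by_side": [
      {"label": "right", "n": 41, "mean": 20.69, "sd": 2.00},
      {"label": "left", "n": 50, "mean": 20.37, "sd": 1.92}
    ],
    "pooled": {"n": 91, "mean": 20.52, "sd": 1.95},
    "range": [15.18, 25.30]
  },
  "published_tests": {
    "anova_f_six_regions": 54.905,
    "t_fitted_radius_sex": 6.894,
    "t_fitted_radius_side": 0.783
  },
  "region_ordering": ["PM", "PL", "MP", "AL", "MA", "AM"]
}
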