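{
  "name": "acta2-demo",
  "seed": 1,
  "mode": "imaging",
  "acquisition": { "preset": "low-res", "kvp": 50, "n_projections": 1440 },
  "contrast": { "iodine_dose_g_per_kg": 2.2, "vessel_hu_slope": 300, "kvp": 50 },
  "vesselness": {
    "scales_um": [35, 55, 90, 150],
    "low_threshold": 0.05,
    "high_threshold": 0.3
  },
  "cohorts": [
    { "group": "wt", "n_subjects": 3, "cow_width_mean_mm": 2.82,
      "cow_width_sd_mm": 0.19 },
    { "group": "ko", "n_subjects": 3, "cow_width_mean_mm": 2.56,
      "cow_width_sd_mm": 0.08, "straightening": 0.4, "stenosis_prob": 0.5 }
  ],
  "stats": { "alpha_gate": 0.05, "var_equal": false, "holm": false }
}
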