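{
  "comment": [
    "Published prediction-equation registry for sugarcane yeast energy values,",
    "dry-matter basis. Coefficient units: kcal/kg per predictor unit (age in",
    "days; DM, CP, MM, EE, NDF in % of DM; MGD in micrometres; GE in kcal/kg).",
    "r2 and aic are the published fit diagnostics (metadata: the underlying",
    "96-unit raw data are unpublished, so aic is not recomputable here).",
    "Where the equation tables and the validation-table headers disagree on a",
    "coefficient (eq 2 intercept -2666.26 vs -26660.26; eq 10 age -32.1550 vs",
    "-32.1551; AMEn eq 5 age -27.7185 vs -27.7557), the equation tables are",
    "kept as authoritative."
  ],
  "equations": [
    {"target": "AME", "eq_id": 1, "source": "printed", "intercept": 8905.51,
     "coefficients": {"age": -32.1006, "DM": -81.048, "MGD": 0.50052},
     "r2": 0.680, "aic": 1071.3604},
    {"target": "AME", "eq_id": 2, "source": "printed", "intercept": -2666.26,
     "coefficients": {"age": -32.1006, "CP": 136.940, "EE": 5496.06},
     "r2": 0.680, "aic": 1071.3926},
    {"target": "AME", "eq_id": 3, "source": "printed", "intercept": 968.43,
     "coefficients": {"age": -32.1006, "EE": 2104.38, "NDF": 22.159},
     "r2": 0.679, "aic": 1071.5403},
    {"target": "AME", "eq_id": 4, "source": "printed", "intercept": null,
     "coefficients": {"age": -32.1253, "CP": 49.372, "EE": 2736.44},
     "r2": 0.968, "aic": 1070.0169},
    {"target": "AME", "eq_id": 5, "source": "printed", "intercept": null,
     "coefficients": {"age": -32.1032, "DM": 41.444, "CP": -123.228, "NDF": 59.644},
     "r2": 0.968, "aic": 1071.4826},
    {"target": "AME", "eq_id": 6, "source": "printed", "intercept": null,
     "coefficients": {"age": -32.1032, "DM": 9.545, "EE": 2308.82, "NDF": 25.886},
     "r2": 0.968, "aic": 1071.4875},
    {"target": "AME", "eq_id": 7, "source": "printed", "intercept": null,
     "coefficients": {"age": -32.1032, "CP": 36.863, "EE": 2999.92, "NDF": 15.797},
     "r2": 0.968, "aic": 1071.4889},
    {"target": "AME", "eq_id": 8, "source": "printed", "intercept": null,
     "coefficients": {"age": -32.1033, "DM": -14.902, "CP": 94.450, "EE": 4078.07},
     "r2": 0.968, "aic": 1071.4913},
    {"target": "AME", "eq_id": 9, "source": "printed", "intercept": null,
     "coefficients": {"age": -32.1195, "CP": -39.032, "MM": 90.297, "GE": 0.46072},
     "r2": 0.968, "aic": 1071.5986},
    {"target": "AME", "eq_id": 10, "source": "printed", "intercept": null,
     "coefficients": {"age": -32.1550, "MM": -667.258, "NDF": 247.075, "MGD": 7.9364},
     "r2": 0.968, "aic": 1071.6804},
    {"target": "AMEn", "eq_id": 1, "source": "printed", "intercept": -4190.27,
     "coefficients": {"age": -27.6797, "CP": 184.997, "EE": 6718.77},
     "r2": 0.576, "aic": 1085.744},
    {"target": "AMEn", "eq_id": 2, "source": "printed", "intercept": 14361.06,
     "coefficients": {"age": -27.6797, "DM": -115.544, "GE": -0.5221},
     "r2": 0.576, "aic": 1085.774},
    {"target": "AMEn", "eq_id": 3, "source": "printed", "intercept": 8198.04,
     "coefficients": {"age": -27.6797, "DM": -74.273, "MGD": 0.3902},
     "r2": 0.575, "aic": 1085.892},
    {"target": "AMEn", "eq_id": 4, "source": "printed", "intercept": null,
     "coefficients": {"age": -27.7557, "MM": -519.001, "NDF": 202.870, "MGD": 6.4243},
     "r2": 0.957, "aic": 1086.003},
    {"target": "AMEn", "eq_id": 5, "source": "printed", "intercept": null,
     "coefficients": {"age": -27.7185, "CP": 47.377, "EE": 2381.78},
     "r2": 0.957, "aic": 1085.067},
    {"target": "AMEn", "eq_id": 6, "source": "printed", "intercept": null,
     "coefficients": {"age": -27.6858, "DM": 38.318, "CP": -119.241, "NDF": 64.030},
     "r2": 0.957, "aic": 1086.056},
    {"target": "AMEn", "eq_id": 7, "source": "printed", "intercept": null,
     "coefficients": {"age": -27.6857, "DM": 7.456, "EE": 2233.32, "NDF": 31.348},
     "r2": 0.957, "aic": 1086.066},
    {"target": "AMEn", "eq_id": 8, "source": "printed", "intercept": null,
     "coefficients": {"age": -27.6856, "CP": 28.785, "EE": 2773.38, "NDF": 23.479},
     "r2": 0.957, "aic": 1086.068},
    {"target": "AMEn", "eq_id": 9, "source": "printed", "intercept": null,
     "coefficients": {"age": -27.7120, "CP": -29.099, "MM": 95.567, "GE": 0.3645},
     "r2": 0.957, "aic": 1086.68},
    {"target": "AMEn", "eq_id": 10, "source": "printed", "intercept": null,
     "coefficients": {"age": -27.5216, "EE": 2298.95, "NDF": 55.062, "MGD": 0.6399},
     "r2": 0.957, "aic": 1086.070}
  ]
}
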