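{
  "description": "Reference per-stratum infiltration-factor regression coefficients (Bq m-3 h-1 per predictor unit) and annual indoor-radon summary statistics (Bq m-3), from the Korean national residence calibration study. Strata cross residence type (detached vs other) with groundwater usage.",
  "reference_levels": {
    "material": "concrete",
    "cracks": "0-1",
    "floors": "1"
  },
  "survey": {
    "gm": 86.52,
    "gsd": 2.14,
    "n_districts": 233,
    "n_provinces": 17
  },
  "strata": {
    "1": {
      "label": "detached house, groundwater",
      "res_type": "detached",
      "groundwater": "yes",
      "gm": 62.19,
      "gsd": 1.68,
      "am": 71.07,
      "sd": 38.05,
      "predictors": ["greenery", "district_gm", "material", "cracks", "floors"],
      "materials": ["concrete", "red_brick", "cement_block", "soil", "wood", "other"],
      "coefficients": {
        "intercept": -15.89,
        "greenery": 0.18,
        "district_gm": 2.73,
        "material_red_brick": -1.52,
        "material_cement_block": -0.41,
        "material_soil": -2.54,
        "material_wood": -8.01,
        "material_other": -3.22,
        "cracks_2plus": 1.17,
        "floors_2plus": -4.94
      },
      "se": {
        "intercept": 6.05,
        "greenery": 0.07,
        "district_gm": 0.07,
        "material_red_brick": 3.00,
        "material_cement_block": 2.96,
        "material_soil": 3.98,
        "material_wood": 5.48,
        "material_other": 3.52,
        "cracks_2plus": 2.44,
        "floors_2plus": 2.34
      }
    },
    "2": {
      "label": "detached house, no groundwater",
      "res_type": "detached",
      "groundwater": "no",
      "gm": 49.71,
      "gsd": 1.78,
      "am": 58.98,
      "sd": 37.27,
      "predictors": ["greenery", "district_gm", "material", "cracks", "floors"],
      "materials": ["concrete", "red_brick", "cement_block", "soil", "wood", "other"],
      "coefficients": {
        "intercept": -8.90,
        "greenery": 0.12,
        "district_gm": 2.72,
        "material_red_brick": -2.62,
        "material_cement_block": -4.76,
        "material_soil": -0.22,
        "material_wood": -5.32,
        "material_other": -7.16,
        "cracks_2plus": 2.43,
        "floors_2plus": -5.56
      },
      "se": {
        "intercept": 2.58,
        "greenery": 0.03,
        "district_gm": 0.02,
        "material_red_brick": 1.37,
        "material_cement_block": 1.43,
        "material_soil": 2.81,
        "material_wood": 2.75,
        "material_other": 2.06,
        "cracks_2plus": 1.64,
        "floors_2plus": 1.35
      }
    },
    "3": {
      "label": "other residence, groundwater",
      "res_type": "other",
      "groundwater": "yes",
      "gm": 34.26,
      "gsd": 1.25,
      "am": 34.98,
      "sd": 7.76,
      "predictors": ["greenery", "district_gm", "material"],
      "materials": ["concrete", "red_brick", "cement_block"],
      "coefficients": {
        "intercept": 4.49,
        "greenery": -0.10,
        "district_gm": 2.59,
        "material_red_brick": -4.00,
        "material_cement_block": -6.88
      },
      "se": {
        "intercept": 5.77,
        "greenery": 0.04,
        "district_gm": 0.07,
        "material_red_brick": 1.68,
        "material_cement_block": 1.68
      }
    },
    "4": {
      "label": "other residence, no groundwater",
      "res_type": "other",
      "groundwater": "no",
      "gm": 44.48,
      "gsd": 1.53,
      "am": 48.73,
      "sd": 22.05,
      "predictors": ["greenery", "district_gm", "material", "cracks", "floors"],
      "materials": ["concrete", "red_brick", "cement_block", "other"],
      "coefficients": {
        "intercept": 11.09,
        "greenery": 0.08,
        "district_gm": 2.48,
        "material_red_brick": 1.29,
        "material_cement_block": -2.81,
        "material_other": -14.19,
        "cracks_2plus": 2.24,
        "floors_2plus": -0.58
      },
      "se": {
        "intercept": 2.11,
        "greenery": 0.03,
        "district_gm": 0.02,
        "material_red_brick": 1.71,
        "material_cement_block": 3.29,
        "material_other": 9.13,
        "cracks_2plus": 2.58,
        "floors_2plus": 1.49
      }
    }
  }
}
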