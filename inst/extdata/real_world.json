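{
  "scenario": "real_world",
  "label": "Real-world scenario: trastuzumab-arm inputs from the routine-care cohort; trial hazard ratios",
  "synthetic_fields": [
    "treatment_effect.hr_dfs", "treatment_effect.hr_os", "treatment_effect.hr_dm",
    "treatment_effect.rr_cardiac", "transitions.p_cardiac",
    "utilities.dfs.subsequent", "utilities.lr", "utilities.dm",
    "trastuzumab.her2_testing", "start_age"
  ],
  "transitions": {
    "p_os": {
      "first": {"mean": 0.000, "se": 0, "dist": "fixed"},
      "subsequent": {"mean": 0.026, "se": 0.006, "dist": "beta"}
    },
    "p_dfs": {
      "first": {"mean": 0.016, "se": 0.031, "dist": "beta"},
      "subsequent": {"mean": 0.054, "se": 0.067, "dist": "beta"}
    },
    "p_dm": {
      "first": {"mean": 0.003, "se": 0.002, "dist": "beta"},
      "subsequent": {"mean": 0.041, "se": 0.006, "dist": "beta"}
    },
    "p_cardiac": {"mean": 0.125, "se": 0.022, "dist": "beta"}
  },
  "treatment_effect": {
    "hr_dfs": 0.76,
    "hr_os": 0.76,
    "hr_dm": 0.75,
    "rr_cardiac": 5.33,
    "benefit_duration": 8,
    "hr_dm_after_lr": 1.0
  },
  "state_costs": {
    "dfs": {
      "first": {"mean": 12776, "se": 798.14, "dist": "gamma"},
      "subsequent": {"mean": 1237, "se": 107.49, "dist": "gamma"}
    },
    "lr": {
      "first": {"mean": 12777, "se": 2203.85, "dist": "gamma"},
      "subsequent": {"mean": 14149, "se": 4679.22, "dist": "gamma"}
    },
    "dm": {
      "first": {"mean": 30165, "se": 2339.46, "dist": "gamma"},
      "subsequent": {"mean": 47959, "se": 13877.79, "dist": "gamma"}
    }
  },
  "cardiac_monitoring": {"mean": 467, "se": 18.90, "dist": "gamma"},
  "cardiac_monitoring_scope": "arm",
  "trastuzumab": {
    "vials_per_cycle": {"mean": 3, "se": 0.050, "dist": "gamma"},
    "n_administrations": {"mean": 15, "se": 0.420, "dist": "gamma"},
    "vial_price": 605,
    "admin_price": 257,
    "her2_testing": 0
  },
  "utilities": {
    "dfs": {"first": 0.728, "subsequent": 0.80},
    "lr": {"first": 0.71, "subsequent": 0.71},
    "dm": {"first": 0.60, "subsequent": 0.60}
  },
  "cardiac_disutility": 0.128,
  "discount": {"costs": 0.04, "effects": 0.015},
  "start_age": 55,
  "wtp": 80000,
  "dm_mortality": "derived"
}
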