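{
  "scenario": "trial",
  "label": "Trial scenario: both arms parameterised from trial survival (SYNTHETIC placeholders at trial-like magnitudes; the trial's own tables are not reprinted here). 1-DFS < 1-DM in both arms, so the local-recurrence state is unused.",
  "synthetic_fields": [
    "transitions (all rows)", "control_transitions (all rows)",
    "treatment_effect", "utilities.dfs.subsequent", "utilities.lr",
    "utilities.dm", "trastuzumab.n_administrations", "start_age"
  ],
  "transitions": {
    "p_os": {
      "first": {"mean": 0.005, "se": 0.002, "dist": "beta"},
      "subsequent": {"mean": 0.014, "se": 0.004, "dist": "beta"}
    },
    "p_dfs": {
      "first": {"mean": 0.020, "se": 0.005, "dist": "beta"},
      "subsequent": {"mean": 0.034, "se": 0.006, "dist": "beta"}
    },
    "p_dm": {
      "first": {"mean": 0.024, "se": 0.005, "dist": "beta"},
      "subsequent": {"mean": 0.040, "se": 0.006, "dist": "beta"}
    },
    "p_cardiac": {"mean": 0.030, "se": 0.008, "dist": "beta"}
  },
  "control_transitions": {
    "p_os": {
      "first": {"mean": 0.007, "se": 0.002, "dist": "beta"},
      "subsequent": {"mean": 0.018, "se": 0.004, "dist": "beta"}
    },
    "p_dfs": {
      "first": {"mean": 0.026, "se": 0.005, "dist": "beta"},
      "subsequent": {"mean": 0.044, "se": 0.007, "dist": "beta"}
    },
    "p_dm": {
      "first": {"mean": 0.032, "se": 0.006, "dist": "beta"},
      "subsequent": {"mean": 0.053, "se": 0.007, "dist": "beta"}
    }
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
    "n_administrations": {"mean": 17, "se": 0.300, "dist": "gamma"},
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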