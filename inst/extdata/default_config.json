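{
  "regimens": {
    "IFX5_Q8": {
      "id": "IFX5_Q8",
      "cycle_weeks": 8,
      "cost_cents": 184018,
      "lor_range": [0.019, 0.023],
      "ae_range": [0.026, 0.032],
      "response_range": null
    },
    "IFX10_Q8": {
      "id": "IFX10_Q8",
      "cycle_weeks": 8,
      "cost_cents": 331861,
      "lor_range": [0.098, 0.104],
      "ae_range": [0.026, 0.032],
      "response_range": [0.896, 0.902]
    },
    "IFX10_Q6": {
      "id": "IFX10_Q6",
      "cycle_weeks": 6,
      "cost_cents": 331861,
      "lor_range": [0.075, 0.079],
      "ae_range": [0.021, 0.023],
      "response_range": [0.921, 0.925]
    },
    "IFX10_Q6_IS": {
      "id": "IFX10_Q6_IS",
      "cycle_weeks": 6,
      "cost_cents": 334842,
      "lor_range": [0.075, 0.079],
      "ae_range": [0.019, 0.024],
      "response_range": [0.921, 0.925]
    },
    "ADA_INDUCTION": {
      "id": "ADA_INDUCTION",
      "cycle_weeks": 4,
      "cost_cents": 188420,
      "lor_range": [0, 0],
      "ae_range": [0, 0],
      "response_range": null
    },
    "ADA_Q2": {
      "id": "ADA_Q2",
      "cycle_weeks": 2,
      "cost_cents": 30672,
      "lor_range": [0.007697, 0.008689],
      "ae_range": [0.006729, 0.007603],
      "response_range": [0.9913, 0.9923]
    },
    "ADA_Q1": {
      "id": "ADA_Q1",
      "cycle_weeks": 1,
      "cost_cents": 30672,
      "lor_range": [0.003832, 0.004354],
      "ae_range": [0.0033645, 0.0038015],
      "response_range": [0.9956, 0.9961]
    },
    "POSTOP_IFX_Q8": {
      "id": "POSTOP_IFX_Q8",
      "cycle_weeks": 8,
      "cost_cents": 184018,
      "lor_range": [0, 0],
      "ae_range": [0, 0],
      "response_range": null
    }
  },
  "ifx_test": {
    "HIGH_TROUGH": {
      "label": "HIGH_TROUGH",
      "probability": 0.5,
      "decision": "switch_class",
      "routed_regimen": null,
      "efficacy_horizon_weeks": [],
      "efficacy_retention": []
    },
    "LOW_TROUGH_NO_AB": {
      "label": "LOW_TROUGH_NO_AB",
      "probability": 0.29,
      "decision": "optimize_same_drug",
      "routed_regimen": "IFX10_Q8",
      "efficacy_horizon_weeks": 52,
      "efficacy_retention": 0.8
    },
    "LOW_TROUGH_WITH_AB": {
      "label": "LOW_TROUGH_WITH_AB",
      "probability": 0.21,
      "decision": "switch_other_anti_tnf",
      "routed_regimen": "ADA_Q2",
      "efficacy_horizon_weeks": 52,
      "efficacy_retention": 0.75
    }
  },
  "ada_test": {
    "HIGH_TROUGH": {
      "label": "HIGH_TROUGH",
      "probability": 0.43,
      "decision": "switch_class",
      "routed_regimen": null,
      "efficacy_horizon_weeks": [],
      "efficacy_retention": []
    },
    "LOW_TROUGH_NO_AB": {
      "label": "LOW_TROUGH_NO_AB",
      "probability": 0.24,
      "decision": "optimize_same_drug",
      "routed_regimen": "ADA_Q1",
      "efficacy_horizon_weeks": [26, 52],
      "efficacy_retention": [0.67, 0.57]
    },
    "LOW_TROUGH_WITH_AB": {
      "label": "LOW_TROUGH_WITH_AB",
      "probability": 0.33,
      "decision": "switch_other_anti_tnf",
      "routed_regimen": "IFX5_Q8",
      "efficacy_horizon_weeks": [26, 52],
      "efficacy_retention": [0.8, 0.57]
    }
  },
  "costs": {
    "test_cents": 10000,
    "surgery_cents": 1200000,
    "postop_fraction": 0.25,
    "ifx_vial_cents": 49281,
    "infusion_cents": 36175,
    "ada_40mg_cents": 41705
  },
  "horizons_weeks": [52, 156, 260],
  "cohort_sizes": [3000, 10000],
  "tests_counted_as": "events"
}
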