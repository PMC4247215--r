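{
  "format": "womacpr_rule",
  "version": 1,
  "name": "five-item WOMAC rule (synthetic stand-in)",
  "note": "Synthetic stand-in for the published five-item rule: the item set and the narrative branch constraints (mild toilet difficulty toward at-risk early; severe toilet difficulty toward not-at-risk later) are respected, but the thresholds are calibrated to this package's synthetic cohort generator, not taken from the original figures.",
  "questions": [
    {
      "item": "F10",
      "branches": {
        "0": "q2",
        "1": "q2",
        "2": "q2",
        "3": "q2",
        "4": "at_risk"
      }
    },
    {
      "item": "F15",
      "branches": {
        "0": "q5",
        "1": "q3",
        "2": "q3",
        "3": "q3",
        "4": "q3"
      }
    },
    {
      "item": "F17",
      "branches": {
        "0": "q4",
        "1": "q4",
        "2": "q4",
        "3": "q4",
        "4": "at_risk"
      }
    },
    {
      "item": "F15",
      "branches": {
        "0": "q5",
        "1": "q5",
        "2": "q5",
        "3": "not_at_risk",
        "4": "at_risk"
      }
    },
    {
      "item": "F11",
      "branches": {
        "0": "q6",
        "1": "q6",
        "2": "q6",
        "3": "q6",
        "4": "at_risk"
      }
    },
    {
      "item": "S1",
      "branches": {
        "0": "not_at_risk",
        "1": "not_at_risk",
        "2": "not_at_risk",
        "3": "not_at_risk",
        "4": "at_risk"
      }
    }
  ],
  "classes": [
    "at_risk",
    "not_at_risk"
  ]
}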