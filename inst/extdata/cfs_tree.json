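{
  "item": "badl_help_count", "op": ">=", "value": 5,
  "yes": {"cfs": 7},
  "no": {
    "item": "badl_help_count", "op": ">=", "value": 1,
    "yes": {"cfs": 6},
    "no": {
      "item": "iadl_help_count", "op": ">=", "value": 1,
      "yes": {"cfs": 5},
      "no": {
        "item": "effort_frequency", "op": ">=", "value": "occasionally/moderate",
        "yes": {"cfs": 4},
        "no": {
          "item": "self_rated_health", "op": "in", "value": ["fair", "poor"],
          "yes": {"cfs": 4},
          "no": {
            "item": "active_past_week", "op": "==", "value": true,
            "yes": {
              "item": "condition_count", "op": "<=", "value": 1,
              "yes": {
                "item": "self_rated_health", "op": "in",
                "value": ["excellent", "very good"],
                "yes": {"cfs": 1},
                "no": {"cfs": 2}
              },
              "no": {"cfs": 2}
            },
            "no": {
              "item": "condition_count", "op": ">=", "value": 1,
              "yes": {"cfs": 3},
              "no": {"cfs": 2}
            }
          }
        }
      }
    }
  }
}
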