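{
  "baseline_prevalence": {
    "value": 0.075,
    "ci": [
      0.04,
      0.12
    ],
    "provenance": "Configurable placeholder for the SAH prevalence among ED acute-headache patients selected for workup; not pinned to a single study. Override per site."
  },
  "tests": {
    "noncontrast_ct": {
      "label": "Non-contrast head CT",
      "sensitivity": {
        "value": 0.94,
        "ci": [
          0.91,
          0.96
        ],
        "provenance": "Pooled sensitivity of modern non-contrast CT for subarachnoid blood, meta-analytic estimate."
      },
      "specificity": {
        "value": 0.999,
        "ci": null,
        "provenance": "Editable literature-derived placeholder; false-positive CT reads for subarachnoid blood are rare and no pooled figure is pinned here."
      },
      "stratified": [
        {
          "low": 0,
          "high": 6,
          "sensitivity": {
            "value": 1.0,
            "ci": [
              0.98,
              1.0
            ],
            "provenance": "Non-contrast CT sensitivity for subarachnoid blood when scanned within 6 hours of symptom onset."
          }
        },
        {
          "low": 6,
          "high": null,
          "sensitivity": {
            "value": 0.89,
            "ci": [
              0.83,
              0.93
            ],
            "provenance": "Non-contrast CT sensitivity for subarachnoid blood when scanned 6 or more hours after symptom onset."
          }
        }
      ]
    },
    "ct_angiogram": {
      "label": "CT angiogram",
      "sensitivity": {
        "value": 0.98,
        "ci": [
          0.96,
          0.99
        ],
        "provenance": "Aneurysm detection by CT angiography; effectively time-stable. Editable literature-derived placeholder."
      },
      "specificity": {
        "value": 0.999,
        "ci": null,
        "provenance": "Editable literature-derived placeholder."
      }
    }
  },
  "ottawa_items": {
    "sudden_onset": {
      "label": "Sudden-onset (thunderclap) headache",
      "lr_positive": {
        "value": 2,
        "ci": null,
        "provenance": "Default placeholder pending literature-derived per-item likelihood ratios; flagged for clinical review."
      },
      "lr_negative": {
        "value": 0.5,
        "ci": null,
        "provenance": "Default placeholder pending literature-derived per-item likelihood ratios; flagged for clinical review."
      }
    },
    "instant_peak": {
      "label": "Pain peaking instantly or within an hour",
      "lr_positive": {
        "value": 2,
        "ci": null,
        "provenance": "Default placeholder pending literature-derived per-item likelihood ratios; flagged for clinical review."
      },
      "lr_negative": {
        "value": 0.5,
        "ci": null,
        "provenance": "Default placeholder pending literature-derived per-item likelihood ratios; flagged for clinical review."
      }
    },
    "exertion": {
      "label": "Onset during exertion",
      "lr_positive": {
        "value": 2,
        "ci": null,
        "provenance": "Default placeholder pending literature-derived per-item likelihood ratios; flagged for clinical review."
      },
      "lr_negative": {
        "value": 0.5,
        "ci": null,
        "provenance": "Default placeholder pending literature-derived per-item likelihood ratios; flagged for clinical review."
      }
    },
    "loc": {
      "label": "Witnessed loss of consciousness",
      "lr_positive": {
        "value": 2,
        "ci": null,
        "provenance": "Default placeholder pending literature-derived per-item likelihood ratios; flagged for clinical review."
      },
      "lr_negative": {
        "value": 0.5,
        "ci": null,
        "provenance": "Default placeholder pending literature-derived per-item likelihood ratios; flagged for clinical review."
      }
    },
    "neck_pain": {
      "label": "Neck pain or limited neck flexion",
      "lr_positive": {
        "value": 2,
        "ci": null,
        "provenance": "Default placeholder pending literature-derived per-item likelihood ratios; flagged for clinical review."
      },
      "lr_negative": {
        "value": 0.5,
        "ci": null,
        "provenance": "Default placeholder pending literature-derived per-item likelihood ratios; flagged for clinical review."
      }
    },
    "age_40": {
      "label": "Age 40 years or older",
      "lr_positive": {
        "value": 2,
        "ci": null,
        "provenance": "Default placeholder pending literature-derived per-item likelihood ratios; flagged for clinical review."
      },
      "lr_negative": {
        "value": 0.5,
        "ci": null,
        "provenance": "Default placeholder pending literature-derived per-item likelihood ratios; flagged for clinical review."
      }
    }
  },
  "weights": {
    "difficult_habitus": {
      "value": 2,
      "ci": null,
      "provenance": "Difficult body habitus doubles procedural difficulty (best clinical estimate; LP failure is common at BMI > 30)."
    },
    "antithrombotic_use": {
      "value": 2,
      "ci": null,
      "provenance": "Anti-platelet/anticoagulant use raises post-procedure bleeding risk; weight set at parity with habitus as a model choice, not literature-derived."
    }
  },
  "thresholds": {
    "base_test_threshold": {
      "value": 0.01,
      "ci": null,
      "provenance": "LP test threshold at zero procedural difficulty; model choice, not literature-derived."
    },
    "yellow_band_ratio": {
      "value": 3,
      "ci": null,
      "provenance": "Multiplicative half-width of the indeterminate (yellow) zone around the threshold on the log-probability axis; model choice."
    },
    "weight_scale": {
      "value": 1.5,
      "ci": null,
      "provenance": "Per-unit-difficulty multiplier applied to the test threshold; model choice, not literature-derived."
    }
  }
}
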