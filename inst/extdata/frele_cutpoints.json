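{
  "note": "Published FRéLE-dialect deficit thresholds, shipped as a reference fixture for cut-point serialization tests. Deficit = score at or below threshold. The slowness thresholds are reproduced as printed; the source table mixes a time label with speed units, and this package's own tables always store slowness thresholds on the speed (cm/s) scale.",
  "thresholds": {
    "component": ["exhaustion",
                  "low_activity", "low_activity",
                  "slowness", "slowness", "slowness", "slowness",
                  "weakness", "weakness", "weakness", "weakness", "weakness",
                  "weakness", "weakness", "weakness", "weakness", "weakness"],
    "stratum": ["all",
                "sex=F", "sex=M",
                "sex=F,height=short", "sex=F,height=tall",
                "sex=M,height=short", "sex=M,height=tall",
                "sex=F,bmi_q=1", "sex=F,bmi_q=2", "sex=F,bmi_q=3",
                "sex=F,bmi_q=4", "sex=F,bmi_q=5",
                "sex=M,bmi_q=1", "sex=M,bmi_q=2", "sex=M,bmi_q=3",
                "sex=M,bmi_q=4", "sex=M,bmi_q=5"],
    "threshold": [46.88,
                  32.33, 39.35,
                  5.6, 6.54, 6.3, 7.0,
                  37.0, 35.0, 35.0, 35.0, 35.0,
                  47.4, 55.0, 55.0, 53.6, 55.0],
    "direction": ["below", "below", "below",
                  "below", "below", "below", "below",
                  "below", "below", "below", "below", "below",
                  "below", "below", "below", "below", "below"]
  },
  "height_mean": {"F": 155.81, "M": 169.55},
  "bmi_breaks": {
    "F": [23.49, 25.97, 28.56, 32.11],
    "M": [24.17, 26.42, 28.59, 31.31]
  },
  "weight_loss_rule": "any unintentional loss >= 10% of usual weight or >= 4.5 kg"
}
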