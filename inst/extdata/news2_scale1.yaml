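# NEWS2 (2017) aggregate scoring chart, SpO2 Scale 1.
# Intervals are half-open [lo, hi); with integer vitals and one-decimal
# temperatures this reproduces the inclusive printed chart exactly.
version: news2_scale1
oxygen_weight: 2
consciousness:
  alert: 0
  new_confusion: 3
  voice: 3
  pain: 3
  unresponsive: 3
parameters:
  respiratory_rate:
    unit: breaths/min
    bands:
      - {lo: 0.0, hi: 9.0, score: 3}    # <= 8
      - {lo: 9.0, hi: 12.0, score: 1}   # 9-11
      - {lo: 12.0, hi: 21.0, score: 0}  # 12-20
      - {lo: 21.0, hi: 25.0, score: 2}  # 21-24
      - {lo: 25.0, hi: .inf, score: 3}  # >= 25
  spo2:
    unit: percent
    bands:
      - {lo: 0.0, hi: 92.0, score: 3}   # <= 91
      - {lo: 92.0, hi: 94.0, score: 2}  # 92-93
      - {lo: 94.0, hi: 96.0, score: 1}  # 94-95
      - {lo: 96.0, hi: .inf, score: 0}  # >= 96 (observations validated <= 100)
  systolic_bp:
    unit: mmHg
    bands:
      - {lo: 0.0, hi: 91.0, score: 3}    # <= 90
      - {lo: 91.0, hi: 101.0, score: 2}  # 91-100
      - {lo: 101.0, hi: 111.0, score: 1} # 101-110
      - {lo: 111.0, hi: 220.0, score: 0} # 111-219
      - {lo: 220.0, hi: .inf, score: 3}  # >= 220
  heart_rate:
    unit: beats/min
    bands:
      - {lo: 0.0, hi: 41.0, score: 3}    # <= 40
      - {lo: 41.0, hi: 51.0, score: 1}   # 41-50
      - {lo: 51.0, hi: 91.0, score: 0}   # 51-90
      - {lo: 91.0, hi: 111.0, score: 1}  # 91-110
      - {lo: 111.0, hi: 131.0, score: 2} # 111-130
      - {lo: 131.0, hi: .inf, score: 3}  # >= 131
  temperature:
    unit: degC
    bands:
      - {lo: 0.0, hi: 35.1, score: 3}   # <= 35.0
      - {lo: 35.1, hi: 36.1, score: 1}  # 35.1-36.0
      - {lo: 36.1, hi: 38.1, score: 0}  # 36.1-38.0
      - {lo: 38.1, hi: 39.1, score: 1}  # 38.1-39.0
      - {lo: 39.1, hi: .inf, score: 2}  # >= 39.1
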