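# Original NEWS (2012) aggregate scoring chart.
# Numeric bands coincide with NEWS2 Scale 1; the 2017 revision changed the
# consciousness ladder (ACVPU adds new-onset confusion) and added SpO2
# Scale 2, which is out of scope here. The 2012 chart has no "confusion"
# level; any non-alert level scores 3, so new_confusion maps to 3 as well.
version: news_2012
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
      - {lo: 0.0, hi: 9.0, score: 3}
      - {lo: 9.0, hi: 12.0, score: 1}
      - {lo: 12.0, hi: 21.0, score: 0}
      - {lo: 21.0, hi: 25.0, score: 2}
      - {lo: 25.0, hi: .inf, score: 3}
  spo2:
    unit: percent
    bands:
      - {lo: 0.0, hi: 92.0, score: 3}
      - {lo: 92.0, hi: 94.0, score: 2}
      - {lo: 94.0, hi: 96.0, score: 1}
      - {lo: 96.0, hi: .inf, score: 0}
  systolic_bp:
    unit: mmHg
    bands:
      - {lo: 0.0, hi: 91.0, score: 3}
      - {lo: 91.0, hi: 101.0, score: 2}
      - {lo: 101.0, hi: 111.0, score: 1}
      - {lo: 111.0, hi: 220.0, score: 0}
      - {lo: 220.0, hi: .inf, score: 3}
  heart_rate:
    unit: beats/min
    bands:
      - {lo: 0.0, hi: 41.0, score: 3}
      - {lo: 41.0, hi: 51.0, score: 1}
      - {lo: 51.0, hi: 91.0, score: 0}
      - {lo: 91.0, hi: 111.0, score: 1}
      - {lo: 111.0, hi: 131.0, score: 2}
      - {lo: 131.0, hi: .inf, score: 3}
  temperature:
    unit: degC
    bands:
      - {lo: 0.0, hi: 35.1, score: 3}
      - {lo: 35.1, hi: 36.1, score: 1}
      - {lo: 36.1, hi: 38.1, score: 0}
      - {lo: 38.1, hi: 39.1, score: 1}
      - {lo: 39.1, hi: .inf, score: 2}
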