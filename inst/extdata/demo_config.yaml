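# Demo configuration for the Score-to-Door pipeline.
seed: 42
band_version: news2_scale1
bootstrap_B: 200
thresholds:
  high: 7
  floor: 5
  cap_hours: 168
simulate:
  n_patients: 400
paths:
  output_dir: std_demo
  observations: std_demo/observations.csv
  events: std_demo/events.csv
  covariates: std_demo/covariates.csv
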