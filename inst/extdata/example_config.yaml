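# Example prmflow pipeline configuration
seed: 7
out_dir: prmflow_out

simulate:
  n_precursors: 100
  gradient_length: 30
  multiplicative_cv: 0.05
  interference_rate: 0.1
  sample_interval_s: 2.15

refine:
  min_area: 1000
  min_width: 5.2
  max_width: 26.1
  min_clean_transitions: 3
  coelution_threshold: 0.9
  fragment_tolerance: 0.7
  isolation_width: 1.0

schedule:
  points_per_peak: 6
  expected_peak_width: 12.9
  scan_rate: 125000
  scan_range: [200, 1500]
  min_injection_time: 15
  min_window: 0.75
  max_injections: 3

align:
  time_bin: 0.05

calibration:
  fractions: [1, 0.7, 0.5, 0.3, 0.1, 0.05, 0.01, 0.005, 0.001]
  replicates: 3
  multiplicative_cv: 0.05

fom:
  cv_ceiling: 20
  bootstrap_reps: 100
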