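# Default pipeline configuration: synthetic stroke-schema cohort with the
# planted five-factor signal, all stages enabled.
global_seed: 1
cohort:
  n: 1000
  missing_rate: 0.1
  minority_fraction: 0.3
daem:
  epochs: 200
  refeed_rounds: 3
gfs:
  population_size: 12
  iterations: 40
colbgan:
  epochs: 300
  delta: 0.1
wdo:
  n_drops: 4
  max_iterations: 6
pipeline:
  delta_grid: [0, 0.01, 0.1, 0.5, 1, 2]
  tune_epochs: 30
  test_fraction: 0.25
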