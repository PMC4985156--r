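# Demonstration pipeline configuration: small synthetic deployment.
seed: 42
stages: [all]
simulate:
  n_individuals: 3
  n_trips_per_individual: 4
  p_sea: 0.5
thresholds:
  n_sim: 2000
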