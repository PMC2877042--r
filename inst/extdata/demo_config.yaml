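# Demo pipeline configuration: a small fully synthetic end-to-end run.
seed: 1
out_dir: xsmm_demo_results
simulate:
  enabled: true
  n_probesets: 15
  probes_per_set: 11
  tissues: 5
  replicates: 2
  noise_sd: 0.3
  control_fraction: 0.6
  multi_mismatch_fraction: 0.1
normalize:
  group_by: [platform, tissue]
analyze:
  var_equal: true
crossstudy:
  enabled: false
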