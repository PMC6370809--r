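# Example pipeline configuration for a fully synthetic run.
# Any field omitted here falls back to default_pipeline_config().
seed: 42
output_dir: lysoflux_run
precision: 6
simulate:
  counts:
    n_genes: 1000
    samples_per_group: 10    # mirrors the 11 lean vs 10 obese cohort scale
    baseline_mean: 100.0
    dispersion: 0.1
    n_planted: 60
    planted_log2fc: 2.0
  timecourse:
    n_genes: 300
    n_planted: 120
    noise_sd: 0.25
    replicates: 3
    step_size: 1.0
  coexpression:
    n_genes: 322             # scale of a curated lysosomal/autophagic list
    n_samples: 100
    module_size: 12
    loading_hub: 0.95
    loading_member: 0.6
diffexp:
  fc_up: 1.2                 # human cohort gates
  fc_down: 0.833
  alpha: 0.2
  alpha_kind: fdr
profiles:
  c: 1
  step_size: 1.0
  n_permutations: 100
gsea:
  n_permutations: 200
  weight_p: 1.0
  metric: signal_to_noise
network:
  fdr_max: 0.05
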