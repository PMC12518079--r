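# Demo configuration for run_pipeline(): a small synthetic two-cohort study
# with two planted low-heterogeneity prognostic genes.
seed: 1
outdir: results/pipeline_demo
synthetic:
  n_genes: 200
  planted: [1, 2]
  n_cohort: 150
  log_hr: 0.5
  n_vaf_samples: 10
heterogeneity:
  method: mom
  linkage: ward.D2
  threshold: 0.5
math:
  min_variants: 3
  vaf_floor: 0
signature:
  fc_cut: 0.137
  fdr_cut: 0.05
  alpha: 0.05
  split_rule: median
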