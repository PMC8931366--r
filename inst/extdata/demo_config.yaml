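# Demonstration configuration: small synthetic cohort, full pipeline.
seed: 42
out_dir: codevel_demo
simulate:
  n_subjects: 40
  k_states: 6
  n_taxa_nasal: 20
  n_taxa_rectal: 20
  n_immune_pops: 12
state_models:
  k_range: [1, 6]
dev_index:
  n_draws: 25
outcome:
  n_draws: 20
  eval_folds: 20
verbose: true
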