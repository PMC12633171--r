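# Demo pipeline configuration: small synthetic family study.
seed: 1
simulate:
  n_snps: 300
  n_families: 800        # trio families for the causal-effect sample
  n_gwas: 4000           # unrelated individuals for the training GWAS
  n_children: 1
  h2_direct: 0.30
  parental_share: 0.10
  theta_prop: 0.3
  theta_orth_sd: 0.3
  spousal_corr: 0.0
weights:
  shrink: 1.0
impute:
  mask_parents: false
correct:
  inputs: ~              # null: use the bundled repository worked example
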