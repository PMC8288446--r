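# Demo pipeline configuration: five species (one per dispersal strategy)
# over a small longitudinal cohort. Runs in well under five minutes on one
# CPU: run_pipeline("demo_config.yaml").
seed: 42
n_species: 5
cohort:
  n_families: 10
  sampling_days: [0, 120, 240, 365]
species:
  n_genes: 4
  gene_length_nt: 600
geo:
  n_perm: 199
popgen:
  n_genes: 4
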