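# Demo pipeline configuration: simulate the default synthetic study and run
# every stage. Use with:  run_pipeline(load_pipeline_config(<this file>))
out_dir: results/demo
seed: 42
n_permutations: 50
simulate:
  n_strains: 20
  n_molecules: 60
  n_families: 15
  library_fraction: 0.13
  seed: 42
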