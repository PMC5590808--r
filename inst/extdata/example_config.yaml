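# Example pipeline configuration: simulate the reference study design and
# run every analysis stage. Swap `simulation:` for a `paths:` block with
# CSV file locations to analyse field data instead.
seed: 42
n_boot: 1000
n_perm: 10000
ci_level: 0.95
run_permutations: false
simulation:
  seed: 42
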