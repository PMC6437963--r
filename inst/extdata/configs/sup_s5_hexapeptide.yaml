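# Supplementary example: 6 variable positions over 10 candidates plus a
# fixed glycine appended after the variable stretch.
mode: optimize
positions: [hfranesywi, hfranesywi, hfranesywi, hfranesywi, hfranesywi, hfranesywi, G]
tolerance: 1.0
objectives: 2
seed: 42
output_dir: sup_s5_out
ga:
  population_size: 500
  max_generations: 200
  stall_generations: 50
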