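# Supplementary example: 5 variable positions over 10 candidates.
mode: optimize
positions: [hfranesywi, hfranesywi, hfranesywi, hfranesywi, hfranesywi]
tolerance: 1.0
objectives: 2
seed: 42
output_dir: sup_s4_out
ga:
  population_size: 500
  max_generations: 200
  stall_generations: 50
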