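# Two-objective NSGA-II on the pentapeptide input.
mode: optimize
positions: [serwaG, serwaG, serwaG, serwaG, serwaG]
tolerance: 1.0
objectives: 2
seed: 42
output_dir: fig1_opt_out
ga:
  population_size: 500
  max_generations: 200
  stall_generations: 50
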