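# Three-objective run: 5 variable positions of 6 candidates plus a fixed
# C-terminal y.
mode: optimize
positions: [serwaG, serwaG, serwaG, serwaG, serwaG, y]
tolerance: 1.0
objectives: 3
seed: 42
output_dir: fig5a_out
ga:
  population_size: 500
  max_generations: 200
  stall_generations: 50
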