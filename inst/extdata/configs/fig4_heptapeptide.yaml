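# All-D heptapeptide: 5 variable positions of 7 candidates with two fixed
# positions, x3 = p and x7 = y.
mode: optimize
positions: [serwaGi, serwaGi, p, serwaGi, serwaGi, serwaGi, y]
tolerance: 1.0
objectives: 2
seed: 42
output_dir: fig4_out
ga:
  population_size: 500
  max_generations: 200
  stall_generations: 50
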