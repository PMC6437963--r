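# Supplementary example: 7 variable positions of 7 candidates; the fixed
# tyrosine is appended after the variable stretch (the source statement
# indexes it ambiguously).
mode: optimize
positions: [wrepsia, wrepsia, wrepsia, wrepsia, wrepsia, wrepsia, wrepsia, y]
tolerance: 1.0
objectives: 2
seed: 42
output_dir: sup_s3_out
ga:
  population_size: 500
  max_generations: 200
  stall_generations: 50
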