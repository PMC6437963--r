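# Pentapeptide library swept over decreasing mass-discrimination
# tolerances; one unique-by-mass CSV is written per tolerance.
mode: calc
positions: [serwaG, serwaG, serwaG, serwaG, serwaG]
tolerance: [2.5, 1.0, 0.5, 0.1, 0.01, 0.001]
output_dir: sweep_out
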