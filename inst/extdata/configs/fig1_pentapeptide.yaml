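# Pentapeptide calculator input: 5 variable positions, 6 candidate
# D-amino acids (glycine achiral) per position, T = 1 Da.
mode: calc
positions: [serwaG, serwaG, serwaG, serwaG, serwaG]
tolerance: 1.0
output_dir: fig1_out
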