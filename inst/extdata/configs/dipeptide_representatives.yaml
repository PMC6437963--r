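# Dipeptide schematic: one representative L-residue per polarity class
# (F aromatic, A aliphatic, S uncharged polar, R positive, E negative),
# chosen so that the only mass collisions at T = 1 Da are compositional.
mode: calc
positions: [FASRE, FASRE]
tolerance: 1.0
output_dir: dipeptide_out
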