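Package: peplibdesign
Title: Mass and Sequence Diversity Oriented Design of Combinatorial Peptide Libraries
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for designing one-bead-one-compound (OBOC) style random
    peptide libraries from L- and D-amino-acid building blocks. Provides a
    combinatorial peptide mass calculator that enumerates every permutation of
    a positional library and reports average, monoisotopic, [M+H]+ and
    [M+2H]2+ masses; tolerance-based redundancy filters that identify
    peptides unique by mass and unique by amino-acid composition; and an
    NSGA-II multi-objective genetic algorithm over bit-string genomes that
    searches per-position amino-acid subsets trading library size against
    mass and sequence diversity, returning a Pareto front of design
    suggestions with sequence-logo frequency matrices and CSV exports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
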