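# peplibdesign

Design tools for random (one-bead-one-compound style) combinatorial peptide
libraries built from L- and D-amino acids.

A split-and-mix library with `r` variable positions and `m` candidate amino
acids per position contains `R = m^r` peptide permutations, but many of them
are redundant for mass-spectrometry readout: permutations of the same
residue multiset share a monoisotopic mass exactly, and unrelated sequences
can fall within the resolution of the instrument. `peplibdesign` answers two
questions a library designer faces before committing to synthesis:

* **How redundant is a given design?** A combinatorial mass calculator
  enumerates every permutation, computes its average and monoisotopic
  masses and the [M+H]+ / [M+2H]2+ ion species, and filters the list down
  to the peptides *unique by mass* — a peptide is removed when its
  monoisotopic mass lies strictly within a user tolerance `T` (Da) of an
  earlier surviving peptide — and *unique by composition* (distinct sorted
  residue multisets).
* **Which designs are worth making?** An NSGA-II genetic algorithm searches
  the space of per-position amino-acid subsets, encoded as bit-string
  genomes of length `sum(m_i)` (one bit per candidate per position). Each
  genome is scored by ff1 = total permutations, ff2 = peptides unique by
  mass and, optionally, ff3 = peptides unique by composition. The optimizer
  minimises library size while maximising the uniqueness counts, returning
  a Pareto front that runs from small, fully mass-resolved designs (100%
  mass diversity) to large designs with extensive mass overlap. The user
  picks a front point and gets the full calculator output plus a
  sequence-logo frequency matrix for it.

Peptide masses follow residue-mass summation: `M = sum(m(a_i)) + m(H2O)`,
with the case convention lowercase = D stereoisomer, uppercase = L, achiral
glycine `"G"`. Mass diversity is `100 * unique_by_mass / total`; sequence
diversity is `100 * unique_by_composition / total`.

## Worked example

The classic pentapeptide input — five variable positions, candidates
`{s, e, r, w, a, G}` at each, tolerance 1 Da:

```r
library(peplibdesign)

spec <- library_spec(rep("serwaG", 5), tolerance = 1)
diversity_metrics(spec)
#> Library diversity (T = 1 Da)
#>   total permutations:    7776
#>   unique by mass:        137  (1.8%)
#>   unique by composition: 252  (3.2%)
```

Only 137 of the 7776 peptides carry a monoisotopic mass at least 1 Da away
from every earlier-enumerated survivor, and only 252 residue multisets
exist at all — the full library is massively redundant for MS readout.
The optimizer suggests simplified designs instead:

```r
fr <- optimize_library(spec, control = ga_control(population_size = 200,
                                                  max_generations = 100),
                       seed = 42)
fr
#> NSGA-II peptide library optimization (2 objectives)
#>   generations: 100 (generation limit)
#>   genomes evaluated: 18566
#>   Pareto front: 50 designs
#>   mass diversity range:  3.0% - 100.0%

head(subset(fr$front, mass_diversity_pct == 100), 4)
#>   pos1 pos2 pos3 pos4 pos5 ff1 ff2 mass_diversity_pct
#> 1    r    a    r    a    e   1   1                100
#> 2    r    s    r    a   ea   2   2                100
#> 3    w    s  saG    s    G   3   3                100
#> 4    a    a   sr    a   sG   4   4                100
```

Each front row is a design: per-position subsets, its size `ff1`, its
unique-by-mass count `ff2` and the resulting mass diversity. A known
hand-checkable point is the 2^5 design `{a,G},{w,a},{r,G},{e,r},{s,r}`:

```r
diversity_metrics(library_spec(c("aG", "wa", "rG", "er", "sr")))
#> Library diversity (T = 1 Da)
#>   total permutations:    32
#>   unique by mass:        32  (100.0%)
#>   unique by composition: 32  (100.0%)
```

All 32 peptides are mutually separated by at least 1.95 Da, so every one of
them is individually addressable by mass. `pick_solution(fr, i)` re-runs
the calculator for front row `i`; `run_calc()` / `run_optimize()` drive the
same machinery from YAML configs (shipped examples under
`inst/extdata/configs/`) and write the CSV outputs;
`inst/cli/peplib.R` wraps them for shell use.

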