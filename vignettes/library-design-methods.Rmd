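---
title: "Designing mass- and sequence-diverse peptide libraries: methods and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing mass- and sequence-diverse peptide libraries: methods and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peplibdesign)
```

## The problem

Split-and-mix (one-bead-one-compound) synthesis produces a random peptide
library as the cartesian product of per-position amino-acid sets: with
`r` variable positions and sets `x_1, ..., x_r` of sizes `m_1, ..., m_r`,
the library holds `prod(m_i)` peptide permutations. Downstream
identification by chromatography-coupled mass spectrometry works only for
peptides whose masses can be told apart, and a naive design wastes most of
its synthetic effort on mass-redundant members: permutations of one residue
multiset share a monoisotopic mass exactly, and unrelated compositions can
still fall within instrument resolution. The package quantifies that
redundancy for a given design and searches for better designs.

## Mass model

A peptide's mass is the sum of its residue masses plus one water,
`M = sum(m(a_i)) + m(H2O)` — identical to summing free amino-acid masses
and subtracting `r - 1` waters of condensation, since a free amino acid
weighs its residue plus one water. The shipped table holds standard
monoisotopic and average residue masses at 5-decimal precision for the 20
proteinogenic amino acids; D-stereoisomers (lowercase tokens) carry the
masses of their L-counterparts (uppercase), and glycine has the single
achiral token `G`. Constants: water 18.010565 Da (monoisotopic) /
18.01528 Da (average), proton 1.007276 Da per charge, so
`[M+H]+ = M + p` and `[M+2H]2+ = (M + 2p)/2` on the m/z scale. The table is
a plain-text file (`inst/extdata/residue_masses.tsv`) and can be replaced
at run time (`set_residue_table()`) to admit non-natural building blocks,
which OBOC chemistry handles readily.

All masses are rounded to 9 decimals on computation. With a 5-decimal
residue table this is lossless, and it guarantees that permutations of the
same residue multiset carry *bit-identical* doubles regardless of summation
order — without it, floating-point association noise (~1e-13 Da) would make
tolerance comparisons depend on the order in which equal sums were
accumulated.

## Uniqueness filters

**Unique by mass.** The filter walks the peptide list in its canonical
enumeration order and keeps a record iff its monoisotopic mass differs by
at least the tolerance `T` from every *earlier surviving* record
(`exclude_similar_mass()`; the scan is compiled, with surviving masses in
an ordered set, so a full pass is `O(n log k)`). Three consequences are
deliberate and documented rather than incidental:

* *Strict comparison.* A collision requires `|ΔM| < T`, so `T = 0` keeps
  everything; `run_calc()` warns when it sees a zero tolerance.
* *Chain semantics.* Eliminated records do not themselves eliminate:
  masses `{0, 0.9, 1.8}` at `T = 1` keep `{0, 1.8}`. The alternative
  symmetric rule ("no other peptide within T") would discard entire
  collision families including their representative — same-composition
  permutations, which always coincide in mass, would vanish without a
  trace — and is not what a designer wants from a deduplication step.
* *Order dependence.* The survivor set, and in chain configurations even
  its size, depends on the scan order: `{0, 0.95, 1.9}` keeps two peptides
  scanned in that order but only one when the scan starts from the chain
  midpoint. The package therefore pins the enumeration order (below) and
  exposes an `order = "reverse"` switch on `enumerate_library()` /
  `mass_table()` for reconciling counts computed under the opposite
  convention. Survivor counts quoted for chain-prone inputs are meaningful
  only together with that order.

**Unique by composition.** Two peptides are compositionally equal when
their sorted residue-token multisets coincide (`exclude_equal_composition()`).
An L residue and its D stereoisomer are *different* tokens — same mass,
different compound — so `"Aa"` and `"aA"` collide but `"AA"` does not.
Since equal compositions imply equal masses, for any `T > 0`
`unique_mass <= unique_composition <= total`, an invariant the test suite
checks on randomly generated designs.

**Enumeration order.** `enumerate_library()` uses the odometer with
position 1 cycling fastest (column-major linearisation of the
per-position grids), residues in the order the user listed them. The order
is part of the result definition because the filters keep the *first*
member of each collision set.

## The design search

A design is a choice of non-empty subset of each position's candidate set.
It is encoded as a bit-string genome of length `sum(m_i)` — one inclusion
bit per candidate per position — giving a search space of size
`2^(sum(m_i))` (about 10^9 for the pentapeptide example), far beyond
enumeration at realistic sizes. Genomes are scored by

* `ff1` — total permutations of the decoded design,
* `ff2` — peptides unique by mass at the specification's tolerance,
* `ff3` (three-objective mode) — peptides unique by composition,

computed exactly by the calculator pipeline (`evaluate_fitness()`), with
masses and composition keys built by per-position cross-sums rather than
string enumeration. Composition keys encode the residue-count vector as an
exact base-(r+1) integer in doubles (chunked to stay below 2^53), so key
equality is multiset equality with no hashing approximation.

### Objective orientation

`optimize_library()` minimises `ff1` while maximising the uniqueness
counts (direction `(-1, +1[, +1])`). This is a considered choice: under
joint maximisation of size and uniqueness the full specification weakly
dominates every fully mass-resolved design (it maximises `ff1` outright
and its `ff2` exceeds theirs), so the front would collapse to a handful of
huge, low-diversity designs and contain no 100%-diversity point at all.
The question a designer actually asks is the converse: *how small a
library buys a given number of uniquely addressable masses?* Minimising
size against maximising uniqueness yields exactly the trade-off curve from
minimal perfect designs (mass diversity 100%) through intermediate designs
with limited overlap down to the full library. Reported fitness values are
always the raw counts; the sign convention lives inside the engine, and
`direction` is exposed for users who want a different orientation
(`pareto_filter()`, the reusable dominance utility, defaults to
all-maximise).

### NSGA-II implementation

The engine is the standard elitist NSGA-II loop for bit-strings: fast
non-dominated sorting, crowding distance, binary tournament on
(rank, crowding), uniform crossover, per-bit flip mutation, and truncation
of the combined parent+child population. Defaults, all overridable via
`ga_control()`:

| setting | default | rationale |
|---|---|---|
| `population_size` | 500 | large enough to cover the 10^9-genome pentapeptide space reliably |
| `pareto_fraction` | 0.2 | cap on the best front's share of the truncated population; the surplus goes to later fronts, keeping exploration pressure |
| `crossover_rate` | 0.9 | standard uniform-crossover rate for bit-string NSGA-II |
| `mutation_rate` | 1/length | one expected flip per genome per generation |
| `max_generations` | 200 | hard stop |
| `stall_generations` | 50 | stop once the archive front is unchanged this long |
| `size_cap` | 1e6 | reject (not evaluate) designs enumerating more peptides |

Choices the algorithm statement leaves open were resolved as follows:

* **Infeasible genomes.** An all-zero position segment encodes an empty
  position. It is repaired at decode time by switching on one uniformly
  random bit of the segment (seeded RNG), before fitness evaluation, so
  every evaluated genome is feasible. A penalty objective was rejected
  because it would distort the reported two- and three-dimensional fronts.
* **External archive.** Population truncation (especially the
  Pareto-fraction cap) can evict non-dominated solutions, so the optimizer
  maintains an archive of every non-dominated design encountered and
  returns *its* non-dominated set. This makes the per-generation best
  values monotone (asserted by the tests on the run history) and the
  final front independent of truncation accidents. One representative
  design is kept per distinct fitness vector; alternative designs with
  identical counts can be recovered by re-running with another seed.
* **Fitness caching.** Evaluation is pure in the (repaired) genome, and
  populations revisit genomes constantly, so results are memoised by bit
  pattern; `evaluations` in the result reports distinct genomes evaluated.
* **Stopping.** The run stops at `max_generations` or when the archive
  front's fitness set has been unchanged for `stall_generations`
  generations, whichever comes first.
* **Determinism.** A single seed drives initialisation, selection,
  variation and repair; identical settings and seed reproduce the front
  byte-for-byte (tested).

## What the tests do and do not show

Deterministic claims are pinned against independent oracles built in the
test helpers: a literal quadratic implementation of the sequential removal
rule, a pairwise multiset-grouping loop, a private copy of the residue
table with string-based enumeration, and — for the optimizer — exhaustive
evaluation of every feasible genome on search spaces up to 2^12, whose
true non-dominated set seeded GA runs must reproduce. Randomised designs
for these checks stay at or below a few hundred peptides so the quadratic
references remain exact and fast; full-scale behaviour is exercised on the
7776-peptide pentapeptide input, and the population-500 acceptance runs
are the package's own reference problem size. GA performance claims beyond
those instances (e.g. front quality on much larger alphabets or longer
peptides) are extrapolations: NSGA-II carries no optimality guarantee, and
a practitioner should sanity-check any front point with
`pick_solution()` — which re-runs the exact calculator — before synthesis.

Two further limitations are worth stating. Survivor counts at tolerances
near characteristic residue-substitution mass gaps sit on chain
boundaries, so small changes to the mass table or the enumeration order
move them by a few percent (the pentapeptide count at `T = 1` ranges over
roughly 128-137 across candidate reorderings); counts at tolerances well
clear of the gap structure (such as the 32-peptide design, minimum gap
1.95 Da) are robust. And the filters model instrument resolution as a
fixed mass window, not ppm-relative accuracy or isotope-envelope overlap —
adequate for the 300-1000 Da peptides the tool targets, but a
simplification.
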