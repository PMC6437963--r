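# Internal fast fitness machinery shared by diversity_metrics() and the GA.
#
# A design (per-position subsets of the full specification) is evaluated
# without materialising sequence strings: per-peptide monoisotopic masses
# and composition keys are both additive over positions, so they are built
# by a cross-sum in canonical enumeration order (position 1 fastest).
#
# Composition keys encode the residue-count vector of a peptide as an exact
# integer in base (r+1): token t at any position contributes (r+1)^index(t),
# and since every count is <= r the digits never carry.  Tokens are split
# into chunks so each chunk's key stays below 2^53 and double arithmetic is
# exact; peptides share a key iff they share a residue multiset.

.design_context <- function(spec, tolerance = spec$tolerance) {
  masses <- .residue_masses("mono")
  water <- peptide_constants()$water_mono
  r <- length(spec$positions)
  tokens <- sort(unique(unlist(spec$positions)), method = "radix")
  base <- r + 1
  chunk_size <- max(1L, as.integer(floor(52 / log2(base))) - 1L)
  chunk_of <- ((seq_along(tokens) - 1L) %/% chunk_size) + 1L
  digit_of <- (seq_along(tokens) - 1L) %% chunk_size
  n_chunks <- max(chunk_of)
  weight_of <- as.numeric(base)^digit_of
  comp_weights <- lapply(seq_len(n_chunks), function(ch) {
    w <- ifelse(chunk_of == ch, weight_of, 0)
    names(w) <- tokens
    lapply(spec$positions, function(p) unname(w[p]))
  })
  list(pos_masses = lapply(spec$positions, function(p) unname(masses[p])),
       water = water,
       comp_weights = comp_weights,
       n_chunks = n_chunks,
       tolerance = as.numeric(tolerance))
}

.count_distinct_keys <- function(keys) {
  if (length(keys) == 1L) return(length(unique(keys[[1L]])))
  if (length(keys) == 2L)
    return(length(unique(complex(real = keys[[1L]], imaginary = keys[[2L]]))))
  nrow(unique(do.call(cbind, keys)))
}

# sel: list of integer index vectors (one per position, into the position's
# allowed set).  Returns c(ff1, ff2[, ff3]).
.fitness_from_selection <- function(sel, ctx, objectives = 2L,
                                    size_cap = 1e6) {
  sizes <- lengths(sel)
  ff1 <- prod(as.numeric(sizes))
  if (ff1 > size_cap)
    stop("design enumerates ", format(ff1, big.mark = ","),
         " peptides, above the evaluation cap of ",
         format(size_cap, big.mark = ","))
  masses <- round(.cross_sum(mapply(function(m, s) m[s], ctx$pos_masses, sel,
                                    SIMPLIFY = FALSE)) + ctx$water, 9L)
  ff2 <- sum(.greedy_mass_keep(masses, ctx$tolerance))
  if (objectives < 3L)
    return(c(ff1 = ff1, ff2 = ff2))
  keys <- lapply(ctx$comp_weights, function(wchunk)
    .cross_sum(mapply(function(w, s) w[s], wchunk, sel, SIMPLIFY = FALSE)))
  ff3 <- .count_distinct_keys(keys)
  c(ff1 = ff1, ff2 = ff2, ff3 = ff3)
}
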