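# Independent reference implementations used to cross-check the package.
# They deliberately avoid the package's internals: their own residue mass
# table, string-based enumeration via expand.grid, and literal quadratic
# filter loops.

ORACLE_MONO <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
                 V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
                 I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
                 K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
                 F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
ORACLE_WATER <- 18.010565

oracle_mono_mass <- function(sequence) {
  vapply(strsplit(sequence, "", fixed = TRUE), function(toks)
    sum(ORACLE_MONO[toupper(toks)]) + ORACLE_WATER, numeric(1L))
}

oracle_enumerate <- function(position_sets) {
  grid <- expand.grid(position_sets, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  do.call(paste0, grid)
}

# literal sequential removal: walk the (shrinking) list, and for each
# surviving entry delete every later entry within strictly < tol
oracle_greedy_keep_idx <- function(masses, tol) {
  idx <- seq_along(masses)
  i <- 1L
  while (i <= length(idx)) {
    m <- masses[idx[i]]
    later <- idx[-seq_len(i)]
    hit <- later[abs(masses[later] - m) < tol]
    if (length(hit)) idx <- setdiff(idx, hit)
    i <- i + 1L
  }
  idx
}

# quadratic multiset grouping: compare sorted token vectors pairwise
oracle_composition_keep_idx <- function(sequences) {
  toks <- lapply(strsplit(sequences, "", fixed = TRUE), sort)
  keep <- logical(length(sequences))
  for (i in seq_along(sequences)) {
    dup <- FALSE
    for (j in seq_len(i - 1L)) {
      if (keep[j] && identical(toks[[i]], toks[[j]])) { dup <- TRUE; break }
    }
    keep[i] <- !dup
  }
  which(keep)
}

# random positional library with at most `max_total` permutations
random_library_spec <- function(max_total = 200,
                                pool = c("s", "e", "r", "w", "a", "G",
                                         "i", "p", "y", "f"),
                                tolerance = 1) {
  repeat {
    r <- sample(2:4, 1L)
    sets <- replicate(r, sample(pool, sample(1:4, 1L)), simplify = FALSE)
    if (prod(lengths(sets)) <= max_total)
      return(library_spec(sets, tolerance = tolerance))
  }
}

# exhaustive non-dominated fitness set over every feasible genome of a
# small full specification, evaluated through the independent oracle path
oracle_true_front <- function(spec, objectives = 2L,
                              direction = c(-1, rep(1, objectives - 1L))) {
  L <- genome_length(spec)
  stopifnot(L <= 12L)
  ends <- cumsum(spec$counter)
  starts <- ends - spec$counter + 1L
  fits <- list()
  for (code in seq_len(2^L) - 1L) {
    bits <- as.integer(intToBits(code)[seq_len(L)])
    feasible <- all(vapply(seq_along(starts), function(i)
      any(bits[starts[i]:ends[i]] == 1L), logical(1L)))
    if (!feasible) next
    sets <- lapply(seq_along(starts), function(i)
      spec$positions[[i]][bits[starts[i]:ends[i]] == 1L])
    seqs <- oracle_enumerate(sets)
    masses <- oracle_mono_mass(seqs)
    ff <- c(length(seqs),
            length(oracle_greedy_keep_idx(masses, spec$tolerance)))
    if (objectives == 3L)
      ff <- c(ff, length(oracle_composition_keep_idx(seqs)))
    fits[[length(fits) + 1L]] <- ff
  }
  fit <- unique(do.call(rbind, fits))
  keep <- rep(TRUE, nrow(fit))
  for (i in seq_len(nrow(fit))) {
    for (j in seq_len(nrow(fit))) {
      if (i == j) next
      a <- fit[j, ] * direction
      b <- fit[i, ] * direction
      if (all(a >= b) && any(a > b)) { keep[i] <- FALSE; break }
    }
  }
  m <- fit[keep, , drop = FALSE]
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

fitness_set_strings <- function(fit) {
  sort(unique(apply(round(fit), 1L, paste, collapse = ",")))
}
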