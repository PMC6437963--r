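# Bit-string genomes: decoding to designs, fitness evaluation, dominance.

.check_bits <- function(bits, spec) {
  L <- genome_length(spec)
  if (is.logical(bits)) bits <- as.integer(bits)
  if (!is.numeric(bits) || length(bits) != L)
    stop("genome must be a 0/1 vector of length ", L,
         " (sum of per-position set sizes), got length ", length(bits))
  bits <- as.integer(bits)
  if (anyNA(bits) || any(bits != 0L & bits != 1L))
    stop("genome entries must be 0 or 1")
  bits
}

# Split a genome into per-position selections (integer indices into each
# position's allowed set).  An all-zero segment encodes an empty position,
# which cannot be enumerated; it is repaired by switching on one uniformly
# random bit of the segment (drawn from the current RNG stream) so every
# evaluated genome is feasible.  Returns list(sel, bits) with the possibly
# repaired bits.
.decode_bits <- function(bits, spec, repair = TRUE) {
  bits <- .check_bits(bits, spec)
  ends <- cumsum(spec$counter)
  starts <- ends - spec$counter + 1L
  sel <- vector("list", length(ends))
  for (i in seq_along(ends)) {
    seg <- bits[starts[i]:ends[i]]
    idx <- which(seg == 1L)
    if (length(idx) == 0L) {
      if (!repair)
        stop("position ", i, " has no amino acid selected (all-zero segment)")
      idx <- sample.int(spec$counter[i], 1L)
      bits[starts[i] + idx - 1L] <- 1L
    }
    sel[[i]] <- idx
  }
  list(sel = sel, bits = bits)
}

#' Decode a bit-string genome into a library design
#'
#' Each genome segment corresponds to one position of the full
#' specification; a 1-bit includes the corresponding candidate amino acid
#' (candidate order preserved).  An all-zero segment would encode an empty
#' position, so it is repaired by switching on one uniformly random bit of
#' that segment (this consumes the current RNG stream).
#'
#' @param bits 0/1 vector of length `genome_length(full_spec)`.
#' @param full_spec The full `library_spec` the genome refers to.
#' @param repair Repair all-zero segments (default TRUE); when FALSE such
#'   genomes are rejected.
#' @return The decoded design as a `library_spec` (tolerance inherited from
#'   `full_spec`).
#' @examples
#' full <- library_spec(rep("serwaG", 5))
#' read_genome(rep(1, 30), full)  # identity: the full specification
#' @export
read_genome <- function(bits, full_spec, repair = TRUE) {
  stopifnot(inherits(full_spec, "library_spec"))
  dec <- .decode_bits(bits, full_spec, repair = repair)
  library_spec(mapply(function(p, s) p[s], full_spec$positions, dec$sel,
                      SIMPLIFY = FALSE),
               tolerance = full_spec$tolerance)
}

#' Evaluate the fitness of a genome
#'
#' Decodes the genome (repairing all-zero segments) and computes the
#' objective counts of the resulting design: ff1 = total permutations,
#' ff2 = peptides unique by mass at the given tolerance, and, with three
#' objectives, ff3 = peptides unique by amino-acid composition.  For any
#' tolerance > 0, ff2 <= ff3 <= ff1.
#'
#' @inheritParams read_genome
#' @param objectives 2 or 3.
#' @param tolerance Mass tolerance in Da; defaults to the specification's.
#' @param size_cap Designs enumerating more peptides than this are rejected
#'   rather than evaluated (guards memory; default 1e6).
#' @return Named numeric vector `c(ff1, ff2[, ff3])`.
#' @examples
#' full <- library_spec(rep("serwaG", 5))
#' evaluate_fitness(rep(1, 30), full)
#' @export
evaluate_fitness <- function(bits, full_spec, objectives = 2,
                             tolerance = full_spec$tolerance,
                             size_cap = 1e6) {
  stopifnot(inherits(full_spec, "library_spec"))
  objectives <- as.integer(objectives)
  if (!objectives %in% c(2L, 3L))
    stop("`objectives` must be 2 or 3")
  dec <- .decode_bits(bits, full_spec, repair = TRUE)
  ctx <- .design_context(full_spec, tolerance = tolerance)
  .fitness_from_selection(dec$sel, ctx, objectives = objectives,
                          size_cap = size_cap)
}

#' Extract the non-dominated subset of a set of objective vectors
#'
#' A point dominates another when it is at least as good in every objective
#' and strictly better in at least one, "good" being decided per objective
#' by `direction` (+1 maximise, -1 minimise; all maximised by default).
#' Exact duplicate rows are kept once (first occurrence); the stable input
#' order is preserved.
#'
#' @param points Numeric matrix or data.frame, one row per point, one
#'   column per objective.
#' @param direction Numeric vector of +1/-1 per objective (recycled).
#' @return The non-dominated rows of `points`, with an attribute `"indices"`
#'   giving their row positions in the input.
#' @examples
#' pareto_filter(rbind(c(10, 5), c(8, 6), c(9, 4)))  # (10,5) and (8,6)
#' @export
pareto_filter <- function(points, direction = 1) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  if (!is.numeric(points) || nrow(points) < 1L)
    stop("`points` must be a numeric matrix with at least one row")
  direction <- rep_len(direction, ncol(points))
  if (!all(direction %in% c(-1, 1)))
    stop("`direction` entries must be +1 (maximise) or -1 (minimise)")
  scaled <- sweep(points, 2L, direction, `*`)
  keep <- !.dominated_rows(scaled) & !duplicated(scaled)
  out <- points[keep, , drop = FALSE]
  attr(out, "indices") <- which(keep)
  out
}

# rows of `scaled` (all-maximise orientation) that are strictly dominated
# by some other row
.dominated_rows <- function(scaled) {
  n <- nrow(scaled)
  if (n == 1L) return(FALSE)
  ge <- matrix(TRUE, n, n)
  gt <- matrix(FALSE, n, n)
  for (k in seq_len(ncol(scaled))) {
    v <- scaled[, k]
    dk <- outer(v, v, `-`)
    ge <- ge & (dk >= 0)
    gt <- gt | (dk > 0)
  }
  dom <- ge & gt   # dom[i, j]: row i dominates row j
  apply(dom, 2L, any)
}
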