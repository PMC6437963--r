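# Positional library specification and full enumeration.

#' Define a positional peptide library
#'
#' A library is an ordered list of positions, each with its own allowed set
#' of amino-acid tokens, plus a mass-discrimination tolerance used by the
#' unique-by-mass filter.  A fixed position is simply a position with a
#' single allowed residue.  The total number of peptide permutations is the
#' product of the per-position set sizes (m^r when all positions share m
#' candidates).
#'
#' @param positions Allowed residues per position: either a character vector
#'   whose i-th element holds the tokens of position i as one string (e.g.
#'   `c("serwaG", "serwaG", "p")`), or a list of character vectors of
#'   single-letter tokens.
#' @param tolerance Mass-discrimination tolerance T in Da (>= 0).  Two
#'   peptides collide when their monoisotopic masses differ by strictly
#'   less than T.  Default 1 Da.
#' @return Object of class `library_spec` with elements `positions` (list of
#'   token vectors), `counter` (per-position set sizes) and `tolerance`.
#' @examples
#' spec <- library_spec(rep("serwaG", 5))
#' library_size(spec)  # 6^5 = 7776
#' @export
library_spec <- function(positions, tolerance = 1) {
  if (is.character(positions))
    positions <- lapply(positions, function(p) strsplit(p, "", fixed = TRUE)[[1L]])
  if (!is.list(positions) || length(positions) == 0L)
    stop("`positions` must be a non-empty list of token vectors (r >= 1)")
  positions <- lapply(positions, as.character)
  known <- residue_table()$code
  for (i in seq_along(positions)) {
    p <- positions[[i]]
    if (length(p) == 0L)
      stop("position ", i, " has an empty amino-acid set")
    if (anyDuplicated(p))
      stop("position ", i, " lists duplicate token(s): ",
           paste(unique(p[duplicated(p)]), collapse = ", "))
    bad <- setdiff(p, known)
    if (length(bad))
      stop("position ", i, " uses unknown token '", bad[[1L]], "'")
  }
  if (!is.numeric(tolerance) || length(tolerance) != 1L || is.na(tolerance) ||
      tolerance < 0)
    stop("`tolerance` must be a single non-negative number (Da)")
  structure(
    list(positions = positions,
         counter = vapply(positions, length, integer(1L)),
         tolerance = as.numeric(tolerance)),
    class = "library_spec")
}

#' @export
print.library_spec <- function(x, ...) {
  r <- length(x$positions)
  cat("Peptide library specification\n")
  cat("  positions (N->C):", r, "\n")
  for (i in seq_len(r))
    cat(sprintf("    x%d: {%s}\n", i, paste(x$positions[[i]], collapse = ",")))
  cat("  total permutations:", format(library_size(x), big.mark = ","), "\n")
  cat("  tolerance T:", x$tolerance, "Da\n")
  invisible(x)
}

#' Number of positions of a library specification
#' @param spec A `library_spec`.
#' @return Integer r.
#' @export
n_positions <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  length(spec$positions)
}

#' Total number of peptide permutations of a library
#' @param spec A `library_spec`.
#' @return Product of per-position set sizes (as double, sizes can be large).
#' @export
library_size <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  prod(as.numeric(spec$counter))
}

#' Bit-string genome length of a library specification
#'
#' One bit per candidate amino acid per position: the sum of the
#' per-position set sizes.
#'
#' @param spec A `library_spec`.
#' @return Integer genome length.
#' @export
genome_length <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  sum(spec$counter)
}

#' Enumerate every peptide of a library
#'
#' Produces all permutations in the canonical odometer order with position 1
#' cycling fastest (column-major linearisation).  The order is deterministic
#' and matters downstream: the unique-by-mass and unique-by-composition
#' filters keep the first member of each collision set.
#'
#' @param spec A `library_spec`.
#' @param order `"forward"` (default; position 1 fastest, residues in their
#'   given order) or `"reverse"` (the fully reversed enumeration), exposed to
#'   reconcile results computed under the opposite convention.
#' @param max_peptides Guard against accidental huge enumerations; libraries
#'   with more permutations than this are rejected.
#' @return Character vector of length `library_size(spec)`, sequences N->C.
#' @examples
#' enumerate_library(library_spec(c("ae", "GS")))  # "aG" "eG" "aS" "eS"
#' @export
enumerate_library <- function(spec, order = c("forward", "reverse"),
                              max_peptides = 1e7) {
  stopifnot(inherits(spec, "library_spec"))
  order <- match.arg(order)
  n <- library_size(spec)
  if (n > max_peptides)
    stop("library has ", format(n, big.mark = ","),
         " permutations, above the limit of ",
         format(max_peptides, big.mark = ","),
         "; enumerate a smaller design or raise `max_peptides`")
  grid <- expand.grid(spec$positions, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  seqs <- do.call(paste0, grid)
  if (order == "reverse") rev(seqs) else seqs
}

# Cross-sum of per-position numeric contributions in canonical enumeration
# order (position 1 fastest).  Used to compute per-peptide masses and
# composition keys without materialising sequence strings.
.cross_sum <- function(values) {
  acc <- values[[1L]]
  for (i in seq_along(values)[-1L])
    acc <- as.vector(outer(acc, values[[i]], "+"))
  acc
}

# Monoisotopic (or average) masses of every enumerated peptide, in canonical
# order, via the cross-sum of residue masses plus one water.
.enumerated_masses <- function(spec, kind = "mono") {
  masses <- .residue_masses(kind)
  consts <- peptide_constants()
  water <- if (kind == "mono") consts$water_mono else consts$water_avg
  per_pos <- lapply(spec$positions, function(p) unname(masses[p]))
  # round to 9 decimals so permutations of the same residue multiset carry
  # bit-identical masses regardless of the order the residues were summed in
  round(.cross_sum(per_pos) + water, 9L)
}
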