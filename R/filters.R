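# Redundancy filters: unique by mass (tolerance-based greedy exclusion) and
# unique by amino-acid composition, plus the diversity metrics built on them.

.records_masses <- function(records) {
  if (is.numeric(records)) return(records)
  if (is.data.frame(records) && "monoisotopic_mass" %in% names(records))
    return(records$monoisotopic_mass)
  stop("`records` must be a mass-table data.frame (with a ",
       "`monoisotopic_mass` column) or a numeric mass vector")
}

.subset_records <- function(records, keep) {
  if (is.data.frame(records)) records[keep, , drop = FALSE] else records[keep]
}

#' Tolerance-based unique-by-mass exclusion
#'
#' Greedy forward scan over the records in their given (canonical
#' enumeration) order: a record survives iff its monoisotopic mass differs
#' by at least `tolerance` from every earlier surviving record; otherwise it
#' is removed.  The first member of each collision set is therefore the one
#' kept, and eliminated records do not themselves eliminate anything
#' (sequential chain semantics, not the symmetric "no neighbour within T"
#' rule, which would discard entire collision families including their
#' representative).  The comparison is strict, so `tolerance = 0` keeps
#' everything.
#'
#' @param records A mass-table data.frame (see [mass_table()]) or a numeric
#'   vector of monoisotopic masses, in canonical enumeration order.
#' @param tolerance Mass-discrimination tolerance T in Da (>= 0).
#' @return Object of class `unique_mass_result`: list with `kept` (surviving
#'   records, input order preserved), `removed_count` and `tolerance`.
#' @examples
#' r <- exclude_similar_mass(c(100.0, 100.5, 101.4), tolerance = 1)
#' r$kept  # 100.0 and 101.4; 100.5 was removed by 100.0
#' @export
exclude_similar_mass <- function(records, tolerance) {
  masses <- .records_masses(records)
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance < 0)
    stop("`tolerance` must be a single non-negative number (Da)")
  keep <- .greedy_mass_keep(as.numeric(masses), as.numeric(tolerance))
  structure(
    list(kept = .subset_records(records, keep),
         removed_count = sum(!keep),
         tolerance = as.numeric(tolerance)),
    class = "unique_mass_result")
}

#' @export
print.unique_mass_result <- function(x, ...) {
  n_kept <- if (is.data.frame(x$kept)) nrow(x$kept) else length(x$kept)
  cat("Unique-by-mass exclusion (T =", x$tolerance, "Da):",
      n_kept, "kept,", x$removed_count, "removed\n")
  invisible(x)
}

# composition key: the sequence's tokens sorted (C locale), collapsed.
# L and D tokens are distinct compositions even though their masses agree.
.composition_keys <- function(sequences) {
  vapply(strsplit(sequences, "", fixed = TRUE),
         function(toks) paste(sort(toks, method = "radix"), collapse = ""),
         character(1L))
}

#' Unique-by-composition exclusion
#'
#' Two peptides share a composition when their sorted residue-token
#' multisets are equal (so "ae" and "ea" collide, while an L/D pair such as
#' "A"/"a" does not).  The first record of each distinct multiset, in the
#' given order, is kept.
#'
#' @param records A mass-table data.frame (see [mass_table()]) or a
#'   character vector of sequences, in canonical enumeration order.
#' @return Object of class `unique_composition_result`: list with `kept`
#'   and `removed_count`.
#' @examples
#' exclude_equal_composition(c("ae", "ea", "aa"))$kept  # "ae", "aa"
#' @export
exclude_equal_composition <- function(records) {
  sequences <- if (is.character(records)) records
    else if (is.data.frame(records) && "sequence" %in% names(records))
      records$sequence
    else stop("`records` must be a mass-table data.frame or a character ",
              "vector of sequences")
  keep <- !duplicated(.composition_keys(sequences))
  structure(
    list(kept = .subset_records(records, keep),
         removed_count = sum(!keep)),
    class = "unique_composition_result")
}

#' @export
print.unique_composition_result <- function(x, ...) {
  n_kept <- if (is.data.frame(x$kept)) nrow(x$kept) else length(x$kept)
  cat("Unique-by-composition exclusion:", n_kept, "kept,",
      x$removed_count, "removed\n")
  invisible(x)
}

#' Diversity metrics of a library design
#'
#' Enumerates the library, applies the unique-by-mass filter (and the
#' unique-by-composition filter when requested) and reports counts together
#' with the two diversity percentages: mass diversity = 100 * unique_mass /
#' total, sequence diversity = 100 * unique_composition / total.
#'
#' @param spec A `library_spec`.
#' @param with_composition Also compute the composition-based metrics
#'   (default TRUE).
#' @param tolerance Override of `spec$tolerance`, in Da.
#' @return Object of class `diversity_metrics`: list with `total`,
#'   `unique_mass`, `unique_composition` (or NA), `mass_diversity_pct`,
#'   `seq_diversity_pct` (or NA) and `tolerance`.
#' @examples
#' diversity_metrics(library_spec(c("FASRE", "FASRE")))
#' @export
diversity_metrics <- function(spec, with_composition = TRUE,
                              tolerance = spec$tolerance) {
  stopifnot(inherits(spec, "library_spec"))
  ctx <- .design_context(spec, tolerance = tolerance)
  sel <- lapply(spec$counter, seq_len)
  ff <- .fitness_from_selection(sel, ctx,
                                objectives = if (with_composition) 3L else 2L)
  total <- ff[["ff1"]]
  um <- ff[["ff2"]]
  uc <- if (with_composition) ff[["ff3"]] else NA_real_
  structure(
    list(total = total,
         unique_mass = um,
         unique_composition = uc,
         mass_diversity_pct = 100 * um / total,
         seq_diversity_pct = if (with_composition) 100 * uc / total
                             else NA_real_,
         tolerance = as.numeric(tolerance)),
    class = "diversity_metrics")
}

#' @export
print.diversity_metrics <- function(x, ...) {
  cat("Library diversity (T =", x$tolerance, "Da)\n")
  cat(sprintf("  total permutations:    %d\n", as.integer(x$total)))
  cat(sprintf("  unique by mass:        %d  (%.1f%%)\n",
              as.integer(x$unique_mass), x$mass_diversity_pct))
  if (!is.na(x$unique_composition))
    cat(sprintf("  unique by composition: %d  (%.1f%%)\n",
                as.integer(x$unique_composition), x$seq_diversity_pct))
  invisible(x)
}
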