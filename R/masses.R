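# Peptide mass arithmetic and the calculator's mass table.

#' Compute peptide masses
#'
#' The mass of a peptide is the sum of its residue masses plus one water
#' (equivalently, the sum of the free amino-acid masses minus r-1 waters of
#' condensation).  Ion species follow the usual m/z convention:
#' \[M+H\]+ = M + p and \[M+2H\]2+ = (M + 2p)/2 with p the proton mass.
#'
#' @param sequence Character vector of peptide strings (N->C, one token per
#'   residue).
#' @param kind One of `"mono"` (monoisotopic, default), `"avg"` (average),
#'   `"mh"` (\[M+H\]+) or `"m2h"` (\[M+2H\]2+ m/z); the ion species are
#'   derived from the monoisotopic mass.
#' @return Numeric vector of masses in Da (m/z for `"m2h"`).
#' @examples
#' peptide_mass("aGpGery")                # 748.3504
#' peptide_mass(c("G", "GG"), "mono")
#' @export
peptide_mass <- function(sequence, kind = c("mono", "avg", "mh", "m2h")) {
  kind <- match.arg(kind)
  if (!is.character(sequence) || length(sequence) == 0L)
    stop("`sequence` must be a character vector")
  consts <- peptide_constants()
  base_kind <- if (kind == "avg") "avg" else "mono"
  masses <- .residue_masses(base_kind)
  water <- if (kind == "avg") consts$water_avg else consts$water_mono
  res <- vapply(sequence, function(s) {
    toks <- parse_sequence(s)
    m <- masses[toks]
    if (anyNA(m))
      stop("unknown amino-acid token '", toks[which(is.na(m))[1L]],
           "' in sequence '", s, "'")
    # same 9-decimal convention as the enumerated tables: permutations of
    # one residue multiset report bit-identical masses
    round(sum(m) + water, 9L)
  }, numeric(1L), USE.NAMES = FALSE)
  switch(kind,
         mono = ,
         avg  = res,
         mh   = res + consts$proton,
         m2h  = (res + 2 * consts$proton) / 2)
}

#' Mass table of a full library
#'
#' Enumerates the library in canonical order and returns one row per
#' peptide with the four mass values reported for mass-spectrometry
#' analysis.
#'
#' @param spec A `library_spec`.
#' @inheritParams enumerate_library
#' @return A data.frame with columns `sequence`, `average_mass`,
#'   `monoisotopic_mass`, `MH_plus`, `M2H_2plus`, in enumeration order.
#' @examples
#' head(mass_table(library_spec(c("ae", "ae"))))
#' @export
mass_table <- function(spec, order = c("forward", "reverse"),
                       max_peptides = 1e7) {
  stopifnot(inherits(spec, "library_spec"))
  order <- match.arg(order)
  seqs <- enumerate_library(spec, order = order, max_peptides = max_peptides)
  consts <- peptide_constants()
  mono <- .enumerated_masses(spec, "mono")
  avg <- .enumerated_masses(spec, "avg")
  if (order == "reverse") {
    mono <- rev(mono)
    avg <- rev(avg)
  }
  data.frame(sequence = seqs,
             average_mass = avg,
             monoisotopic_mass = mono,
             MH_plus = mono + consts$proton,
             M2H_2plus = (mono + 2 * consts$proton) / 2,
             stringsAsFactors = FALSE)
}

#' Write a mass table to CSV
#'
#' Masses are printed with 4 decimal places; comma-separated, LF line
#' endings, header `sequence,average_mass,monoisotopic_mass,MH_plus,M2H_2plus`.
#'
#' @param records A mass-table data.frame (see [mass_table()]).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_mass_csv <- function(records, file) {
  cols <- c("sequence", "average_mass", "monoisotopic_mass", "MH_plus",
            "M2H_2plus")
  missing <- setdiff(cols, names(records))
  if (length(missing))
    stop("`records` lacks column(s): ", paste(missing, collapse = ", "))
  out <- records[cols]
  for (col in cols[-1L]) out[[col]] <- sprintf("%.4f", out[[col]])
  utils::write.table(out, file = file, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(file)
}
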