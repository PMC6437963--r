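# Amino-acid alphabet and residue mass tables.
#
# Single-letter tokens follow the L/D case convention used throughout the
# package: uppercase = L stereoisomer, lowercase = D stereoisomer, and
# achiral glycine is always "G".  A chiral pair shares its residue masses.

.pkg_env <- new.env(parent = emptyenv())

#' Physical constants used in peptide mass arithmetic
#'
#' Monoisotopic and average masses of water (the condensation partner of the
#' peptide bond) and the mass added per charge when forming protonated ion
#' species.
#'
#' @return Named list with elements `water_mono`, `water_avg` and `proton`,
#'   all in Da.
#' @examples
#' peptide_constants()$water_mono
#' @export
peptide_constants <- function() {
  list(water_mono = 18.010565, water_avg = 18.01528, proton = 1.007276)
}

.validate_residue_table <- function(tab, source = "residue table") {
  needed <- c("code", "chirality", "mono_mass", "avg_mass", "polarity_class")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop(source, " lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(tab$code))
    stop(source, " contains duplicated residue code(s): ",
         paste(unique(tab$code[duplicated(tab$code)]), collapse = ", "))
  if (any(nchar(tab$code) != 1L))
    stop(source, " codes must be single characters")
  if (!all(tab$chirality %in% c("L", "D", "achiral")))
    stop(source, " chirality must be one of L, D, achiral")
  if (any(tab$mono_mass <= 0) || any(tab$avg_mass <= 0))
    stop(source, " masses must be positive")
  tab
}

#' The registered residue table
#'
#' Returns the table of amino-acid building blocks: one row per registered
#' single-letter code with its chirality, monoisotopic and average residue
#' masses (Da) and polarity class.  The default table holds the 20
#' proteinogenic amino acids in both L (uppercase) and D (lowercase) form,
#' with a single achiral glycine entry "G" (39 rows).  It is shipped as a
#' plain-text file so users can extend it with non-natural residues via
#' `set_residue_table()`.
#'
#' @param file Optional path to a tab-separated table with columns
#'   `code`, `chirality`, `mono_mass`, `avg_mass`, `polarity_class`.
#'   When `NULL` the currently registered table is returned.
#' @return A data.frame of residues.
#' @seealso [set_residue_table()], [lookup_residue()]
#' @export
residue_table <- function(file = NULL) {
  if (!is.null(file))
    return(.validate_residue_table(
      utils::read.delim(file, stringsAsFactors = FALSE), file))
  if (is.null(.pkg_env$residues)) {
    path <- system.file("extdata", "residue_masses.tsv",
                        package = "peplibdesign", mustWork = TRUE)
    .pkg_env$residues <- .validate_residue_table(
      utils::read.delim(path, stringsAsFactors = FALSE))
  }
  .pkg_env$residues
}

#' Register a custom residue table
#'
#' Replaces the table used by all mass and parsing functions, e.g. to add
#' non-natural building blocks.  Pass `NULL` to restore the shipped default.
#'
#' @param table A data.frame with the `residue_table()` columns, a path to a
#'   tab-separated file with those columns, or `NULL`.
#' @return The registered table, invisibly.
#' @export
set_residue_table <- function(table = NULL) {
  if (is.null(table)) {
    .pkg_env$residues <- NULL
    return(invisible(residue_table()))
  }
  if (is.character(table) && length(table) == 1L)
    table <- residue_table(file = table)
  .pkg_env$residues <- .validate_residue_table(as.data.frame(table))
  invisible(.pkg_env$residues)
}

# fast named lookup vectors, rebuilt on demand
.residue_masses <- function(kind = c("mono", "avg")) {
  kind <- match.arg(kind)
  tab <- residue_table()
  stats::setNames(if (kind == "mono") tab$mono_mass else tab$avg_mass,
                  tab$code)
}

#' Look up a single residue
#'
#' Case-sensitive lookup (case encodes chirality): `"A"` is L-alanine,
#' `"a"` is D-alanine; both carry identical masses.
#'
#' @param code A single registered one-character token.
#' @return A list with fields `code`, `chirality`, `mono_mass`, `avg_mass`
#'   and `polarity_class`.
#' @examples
#' lookup_residue("G")$mono_mass
#' @export
lookup_residue <- function(code) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 1L)
    stop("`code` must be a single one-character token")
  tab <- residue_table()
  i <- match(code, tab$code)
  if (is.na(i))
    stop("unknown amino-acid token '", code, "'")
  as.list(tab[i, c("code", "chirality", "mono_mass", "avg_mass",
                   "polarity_class")])
}

#' Split a peptide string into residue tokens
#'
#' Sequences are written N- to C-terminus, one character per residue.
#'
#' @param text Non-empty character scalar of registered tokens.
#' @return Character vector of tokens in N-to-C order.
#' @examples
#' parse_sequence("aGpGery")
#' @export
parse_sequence <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      nchar(text) == 0L)
    stop("`text` must be a non-empty character scalar")
  toks <- strsplit(text, "", fixed = TRUE)[[1L]]
  known <- residue_table()$code
  bad <- setdiff(toks, known)
  if (length(bad))
    stop("unknown amino-acid token '", bad[[1L]], "' in sequence '",
         text, "'")
  toks
}
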