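# Sequence-logo frequency matrices (the canonical, plot-free logo artifact).

#' Per-position residue frequency matrix of a peptide set
#'
#' The numerical content of a sequence logo: for each position (N->C) the
#' relative frequency of every residue token observed in the peptide set.
#' Frequencies at each position sum to 1.
#'
#' @param peptides Non-empty character vector of equal-length sequences.
#' @return Numeric matrix, rows = tokens (sorted), columns = positions
#'   (`pos1` ... `posr`); column sums are 1.
#' @examples
#' logo_matrix(c("aG", "Ga"))
#' @export
logo_matrix <- function(peptides) {
  if (!is.character(peptides) || length(peptides) == 0L)
    stop("`peptides` must be a non-empty character vector")
  lens <- nchar(peptides)
  if (any(lens == 0L))
    stop("`peptides` must not contain empty sequences")
  if (length(unique(lens)) != 1L)
    stop("all peptides must have the same length (got lengths ",
         paste(sort(unique(lens)), collapse = ", "), ")")
  r <- lens[[1L]]
  toks <- do.call(rbind, strsplit(peptides, "", fixed = TRUE))
  alphabet <- sort(unique(as.vector(toks)), method = "radix")
  out <- matrix(0, nrow = length(alphabet), ncol = r,
                dimnames = list(alphabet, paste0("pos", seq_len(r))))
  for (j in seq_len(r)) {
    counts <- table(factor(toks[, j], levels = alphabet))
    out[, j] <- as.numeric(counts) / length(peptides)
  }
  out
}

#' Write a logo frequency matrix to CSV
#'
#' Rows are residue tokens, columns positions; a leading `token` column
#' carries the row names.
#'
#' @param logo Matrix from [logo_matrix()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_logo_csv <- function(logo, file) {
  df <- data.frame(token = rownames(logo), logo, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file = file, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(file)
}
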