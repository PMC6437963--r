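# Run configuration (YAML) and the two top-level entry points used by the
# command-line wrapper: run_calc() and run_optimize().

#' Build a run configuration
#'
#' A run configuration captures everything needed to reproduce a calculator
#' or optimizer run and round-trips losslessly through YAML.
#'
#' @param mode `"calc"` or `"optimize"`.
#' @param positions Per-position token strings, e.g.
#'   `c("serwaG", "serwaG", "p")`; a fixed position is a single-token
#'   string.
#' @param tolerance Mass tolerance in Da. In calc mode this may be a vector,
#'   in which case the unique-by-mass exclusion is run once per value (a
#'   tolerance sweep).
#' @param objectives 2 or 3 (optimize mode).
#' @param seed Optional integer seed (optimize mode).
#' @param output_dir Directory where CSV outputs are written.
#' @param ga Named list of [ga_control()] overrides (optimize mode).
#' @param write_composition In calc mode, also write the
#'   unique-by-composition CSV (default; always written with 3 objectives).
#' @param export Front row indices for which [run_optimize()] writes the
#'   detailed per-solution calculator outputs and logo matrix.
#' @return Object of class `run_config`.
#' @export
run_config <- function(mode = c("calc", "optimize"), positions,
                       tolerance = 1, objectives = 2, seed = NULL,
                       output_dir = ".", ga = list(),
                       write_composition = FALSE, export = integer(0)) {
  mode <- match.arg(mode)
  if (!is.character(positions) || length(positions) == 0L)
    stop("`positions` must be a non-empty character vector of token strings")
  # validates tokens / emptiness early
  library_spec(positions, tolerance = tolerance[[1L]])
  if (!is.numeric(tolerance) || length(tolerance) < 1L || any(tolerance < 0))
    stop("`tolerance` must be one or more non-negative numbers (Da)")
  if (mode == "optimize" && length(tolerance) != 1L)
    stop("optimize mode takes a single tolerance")
  objectives <- as.integer(objectives)
  if (!objectives %in% c(2L, 3L))
    stop("`objectives` must be 2 or 3")
  if (!is.list(ga))
    stop("`ga` must be a named list of ga_control() settings")
  if (length(ga)) do.call(ga_control, ga)  # validate overrides
  structure(list(mode = mode,
                 positions = as.character(positions),
                 tolerance = as.numeric(tolerance),
                 objectives = objectives,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 output_dir = as.character(output_dir),
                 ga = ga,
                 write_composition = isTRUE(write_composition),
                 export = as.integer(export)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path Path to a YAML file with the [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c("mode", "positions", "tolerance", "objectives", "seed",
               "output_dir", "ga", "write_composition", "export")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown config field(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  raw$positions <- as.character(unlist(raw$positions))
  if (!is.null(raw$tolerance)) raw$tolerance <- as.numeric(unlist(raw$tolerance))
  if (!is.null(raw$export)) raw$export <- as.integer(unlist(raw$export))
  do.call(run_config, raw)
}

#' Write a run configuration to a YAML file
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config)
  out <- out[!vapply(out, is.null, logical(1L))]
  if (!length(out$ga)) out$ga <- NULL
  if (!length(out$export)) out$export <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}

.as_spec <- function(config, tolerance = config$tolerance[[1L]]) {
  library_spec(config$positions, tolerance = tolerance)
}

.tol_suffix <- function(tolerance) {
  gsub("\\.", "p", format(tolerance, trim = TRUE, scientific = FALSE))
}

#' Run the combinatorial peptide mass calculator
#'
#' Enumerates the configured library, writes the full permutation CSV and
#' one unique-by-mass CSV per configured tolerance (plus the
#' unique-by-composition CSV when requested), and returns a summary of the
#' counts and diversity percentages.
#'
#' @param config A `run_config` in calc mode (or a path to one).
#' @param quiet Suppress the printed summary.
#' @return Invisibly, a data.frame with one row per tolerance: `tolerance`,
#'   `total`, `unique_mass`, `mass_diversity_pct` and (when composition is
#'   requested) `unique_composition`, `seq_diversity_pct`.
#' @export
run_calc <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (config$mode != "calc")
    stop("`config` is not a calc-mode configuration")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- .as_spec(config)
  tab <- mass_table(spec)
  write_mass_csv(tab, file.path(config$output_dir, "permutations.csv"))
  with_comp <- config$write_composition || config$objectives == 3L
  comp <- if (with_comp) exclude_equal_composition(tab) else NULL
  if (with_comp)
    write_mass_csv(comp$kept,
                   file.path(config$output_dir, "unique_by_composition.csv"))
  rows <- lapply(config$tolerance, function(tol) {
    if (tol == 0)
      warning("tolerance 0 never triggers the strict mass comparison; ",
              "all permutations are kept", call. = FALSE)
    um <- exclude_similar_mass(tab, tol)
    suffix <- if (length(config$tolerance) > 1L)
      paste0("_T", .tol_suffix(tol)) else ""
    write_mass_csv(um$kept, file.path(config$output_dir,
                                      paste0("unique_by_mass", suffix,
                                             ".csv")))
    n_kept <- nrow(um$kept)
    row <- data.frame(tolerance = tol, total = nrow(tab),
                      unique_mass = n_kept,
                      mass_diversity_pct = 100 * n_kept / nrow(tab))
    if (with_comp) {
      row$unique_composition <- nrow(comp$kept)
      row$seq_diversity_pct <- 100 * nrow(comp$kept) / nrow(tab)
    }
    row
  })
  summary <- do.call(rbind, rows)
  if (!quiet) {
    cat("Peptide mass calculator\n")
    for (i in seq_len(nrow(summary)))
      cat(sprintf("  T = %g Da: total %d, unique-by-mass %d (%.1f%%)%s\n",
                  summary$tolerance[i], summary$total[i],
                  summary$unique_mass[i], summary$mass_diversity_pct[i],
                  if (with_comp)
                    sprintf(", unique-by-composition %d (%.1f%%)",
                            summary$unique_composition[i],
                            summary$seq_diversity_pct[i]) else ""))
  }
  invisible(summary)
}

#' Run the NSGA-II library design optimization
#'
#' Runs [optimize_library()] on the configured input and writes the Pareto
#' front CSV (`pareto_front.csv`: per-position subsets, fitness counts and
#' diversity percentages), a front diversity table (`front_diversity.csv`:
#' the scatter data of library size against mass and sequence diversity),
#' and, for every front index listed in `config$export`, a per-solution
#' directory with the full calculator outputs and the logo frequency
#' matrix.
#'
#' @param config A `run_config` in optimize mode (or a path to one).
#' @param quiet Suppress the printed summary.
#' @return Invisibly, the `pareto_front` object.
#' @export
run_optimize <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (config$mode != "optimize")
    stop("`config` is not an optimize-mode configuration")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- .as_spec(config)
  control <- do.call(ga_control, config$ga)
  res <- optimize_library(spec, objectives = config$objectives,
                          control = control, seed = config$seed)
  fr <- res$front
  front_path <- file.path(config$output_dir, "pareto_front.csv")
  utils::write.table(fr, front_path, sep = ",", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  div <- fr[, c("ff1", "ff2", "mass_diversity_pct")]
  if (config$objectives == 3L) {
    div$ff3 <- fr$ff3
    div$seq_diversity_pct <- fr$seq_diversity_pct
  } else {
    # sequence diversity of each front design, computed post hoc for the
    # scatter table even when it was not an objective
    seq_pct <- vapply(res$designs, function(d)
      diversity_metrics(d)$seq_diversity_pct, numeric(1L))
    div$seq_diversity_pct <- seq_pct
  }
  utils::write.table(div, file.path(config$output_dir, "front_diversity.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE, eol = "\n")
  for (i in config$export) {
    sol <- pick_solution(res, i)
    dir_i <- file.path(config$output_dir, sprintf("solution_%03d", i))
    dir.create(dir_i, recursive = TRUE, showWarnings = FALSE)
    write_mass_csv(sol$table, file.path(dir_i, "permutations.csv"))
    write_mass_csv(sol$unique_mass$kept,
                   file.path(dir_i, "unique_by_mass.csv"))
    write_mass_csv(sol$unique_composition$kept,
                   file.path(dir_i, "unique_by_composition.csv"))
    write_logo_csv(sol$logo, file.path(dir_i, "logo_matrix.csv"))
  }
  if (!quiet) print(res)
  invisible(res)
}
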