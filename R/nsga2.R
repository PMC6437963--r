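# NSGA-II over bit-string genomes: fast non-dominated sorting, crowding
# distance, binary tournament selection, uniform crossover, per-bit
# mutation, elitist truncation with a configurable cap on the best front's
# population share, and an external archive of every non-dominated design
# encountered.

#' Genetic-algorithm settings
#'
#' @param population_size Individuals per generation (>= 4). Default 500.
#' @param pareto_fraction Maximum fraction of the population occupied by the
#'   best front when truncating the combined parent+child population (the
#'   surplus is redistributed to later fronts, keeping selection pressure on
#'   the interior of the search space). Default 0.2.
#' @param crossover_rate Probability that a mating pair undergoes uniform
#'   crossover. Default 0.9.
#' @param mutation_rate Per-bit flip probability; `NULL` (default) means
#'   1/genome length.
#' @param max_generations Hard generation limit. Default 200.
#' @param stall_generations Stop early when the archive front has not
#'   changed for this many consecutive generations. Default 50.
#' @param size_cap Designs enumerating more peptides than this are rejected
#'   at evaluation (memory guard). Default 1e6.
#' @return Object of class `ga_control`.
#' @export
ga_control <- function(population_size = 500, pareto_fraction = 0.2,
                       crossover_rate = 0.9, mutation_rate = NULL,
                       max_generations = 200, stall_generations = 50,
                       size_cap = 1e6) {
  population_size <- as.integer(population_size)
  if (is.na(population_size) || population_size < 4L)
    stop("`population_size` must be an integer >= 4")
  if (!is.numeric(pareto_fraction) || pareto_fraction <= 0 ||
      pareto_fraction > 1)
    stop("`pareto_fraction` must lie in (0, 1]")
  if (!is.numeric(crossover_rate) || crossover_rate < 0 || crossover_rate > 1)
    stop("`crossover_rate` must lie in [0, 1]")
  if (!is.null(mutation_rate) &&
      (!is.numeric(mutation_rate) || mutation_rate < 0 || mutation_rate > 1))
    stop("`mutation_rate` must lie in [0, 1] or be NULL")
  max_generations <- as.integer(max_generations)
  stall_generations <- as.integer(stall_generations)
  if (is.na(max_generations) || max_generations < 1L)
    stop("`max_generations` must be a positive integer")
  if (is.na(stall_generations) || stall_generations < 1L)
    stop("`stall_generations` must be a positive integer")
  structure(list(population_size = population_size,
                 pareto_fraction = as.numeric(pareto_fraction),
                 crossover_rate = as.numeric(crossover_rate),
                 mutation_rate = mutation_rate,
                 max_generations = max_generations,
                 stall_generations = stall_generations,
                 size_cap = as.numeric(size_cap)),
            class = "ga_control")
}

# ---- non-dominated sorting and crowding -----------------------------------

# fronts of `scaled` (all-maximise orientation); returns list(rank, fronts)
.nds_fronts <- function(scaled) {
  n <- nrow(scaled)
  ge <- matrix(TRUE, n, n)
  gt <- matrix(FALSE, n, n)
  for (k in seq_len(ncol(scaled))) {
    dk <- outer(scaled[, k], scaled[, k], `-`)
    ge <- ge & (dk >= 0)
    gt <- gt | (dk > 0)
  }
  dom <- ge & gt                       # dom[i, j]: i dominates j
  ndom <- colSums(dom)                 # how many dominate each point
  rank <- integer(n)
  fronts <- list()
  f <- 0L
  active <- ndom == 0
  while (any(active)) {
    f <- f + 1L
    cur <- which(active)
    rank[cur] <- f
    fronts[[f]] <- cur
    ndom <- ndom - colSums(dom[cur, , drop = FALSE])
    ndom[cur] <- NA_real_
    active <- !is.na(ndom) & ndom == 0
  }
  list(rank = rank, fronts = fronts)
}

# crowding distance of the rows `idx` of `scaled`
.crowding <- function(scaled, idx) {
  m <- length(idx)
  if (m <= 2L) return(rep(Inf, m))
  d <- numeric(m)
  for (k in seq_len(ncol(scaled))) {
    v <- scaled[idx, k]
    o <- order(v)
    rng <- v[o[m]] - v[o[1L]]
    d[o[c(1L, m)]] <- Inf
    if (rng > 0)
      d[o[2:(m - 1L)]] <- d[o[2:(m - 1L)]] +
        (v[o[3:m]] - v[o[1:(m - 2L)]]) / rng
  }
  d
}

# elitist truncation of the combined population to N survivors, capping the
# share of front 1 at ceiling(pareto_fraction * N) (chosen by crowding);
# unused slots fall through to later fronts, and back to front-1 leftovers
# if the later fronts cannot fill them.
.environmental_select <- function(scaled, N, pareto_fraction) {
  nd <- .nds_fronts(scaled)
  cap1 <- min(N, max(2L, as.integer(ceiling(pareto_fraction * N))))
  chosen <- integer(0)
  leftover <- integer(0)
  for (f in seq_along(nd$fronts)) {
    front <- nd$fronts[[f]]
    room <- N - length(chosen)
    if (room <= 0L) break
    limit <- if (f == 1L) min(room, cap1) else room
    if (length(front) <= limit) {
      chosen <- c(chosen, front)
    } else {
      o <- order(.crowding(scaled, front), decreasing = TRUE)
      chosen <- c(chosen, front[o[seq_len(limit)]])
      leftover <- c(leftover, front[o[-seq_len(limit)]])
    }
  }
  if (length(chosen) < N)
    chosen <- c(chosen, leftover[seq_len(N - length(chosen))])
  chosen
}

# ---- evaluation with caching ----------------------------------------------

.genome_key <- function(bits) intToUtf8(bits + 48L)

# evaluates the rows of `pop`, repairing all-zero segments in place;
# returns list(pop, fit) with `fit` a numeric matrix
.eval_population <- function(pop, spec, ctx, objectives, cache, size_cap) {
  n <- nrow(pop)
  fit <- matrix(0, n, objectives)
  for (i in seq_len(n)) {
    key <- .genome_key(pop[i, ])
    hit <- get0(key, envir = cache, inherits = FALSE)
    if (is.null(hit)) {
      dec <- .decode_bits(pop[i, ], spec, repair = TRUE)
      if (!identical(dec$bits, pop[i, ])) {
        pop[i, ] <- dec$bits
        key <- .genome_key(dec$bits)
        hit <- get0(key, envir = cache, inherits = FALSE)
      }
      if (is.null(hit)) {
        hit <- .fitness_from_selection(dec$sel, ctx, objectives, size_cap)
        assign(key, hit, envir = cache)
      }
    }
    fit[i, ] <- hit
  }
  list(pop = pop, fit = fit)
}

# ---- the optimizer --------------------------------------------------------

#' Optimize a peptide library design with NSGA-II
#'
#' Searches per-position amino-acid subsets of `full_spec`, encoded as
#' bit-string genomes (one bit per candidate amino acid per position), for
#' Pareto-optimal trade-offs between library size and diversity.  The
#' objective counts are ff1 = total permutations, ff2 = peptides unique by
#' mass at the specification's tolerance and, with `objectives = 3`,
#' ff3 = peptides unique by amino-acid composition.
#'
#' By default ff1 is minimised while the uniqueness counts are maximised
#' (`direction = c(-1, 1[, 1])`): the trade-off of interest runs from small
#' fully mass-resolved designs (100% diversity) to large designs with
#' extensive mass overlap, which is the front on which the reported best
#' solutions (e.g. a 32-peptide design with all 32 masses unique) live.
#' Under plain maximisation of both counts the full specification dominates
#' every fully-resolved design and that trade-off disappears.  Reported
#' fitness values are always the raw counts regardless of direction.
#'
#' The returned front is the non-dominated subset of an external archive of
#' every design evaluated, deduplicated by decoded design, so it never
#' loses solutions to population truncation.  The run stops at
#' `max_generations` or once the archive front has been unchanged for
#' `stall_generations` generations.  Given the same seed and settings the
#' result is fully reproducible.
#'
#' @param full_spec A `library_spec`: the full per-position candidate sets
#'   and the mass tolerance.
#' @param objectives 2 (size, unique-by-mass) or 3 (plus
#'   unique-by-composition).
#' @param control A [ga_control()] object.
#' @param seed Optional integer seed for the run's RNG.
#' @param direction Optimisation direction per objective (+1 maximise,
#'   -1 minimise); default `c(-1, 1)` / `c(-1, 1, 1)`.
#' @param verbose Print per-generation progress every 10 generations.
#' @return Object of class `pareto_front`; see Details.  Key elements:
#'   `front` (data.frame: per-position subsets, fitness counts and diversity
#'   percentages), `genomes`, `designs` (list of `library_spec`), `fitness`
#'   (matrix), `history` (per-generation archive statistics), `generations`,
#'   `evaluations`, `converged`.
#' @examples
#' spec <- library_spec(rep("ser", 2))
#' fr <- optimize_library(spec, control = ga_control(population_size = 20,
#'                        max_generations = 20, stall_generations = 10),
#'                        seed = 1)
#' fr$front
#' @export
optimize_library <- function(full_spec, objectives = 2,
                             control = ga_control(), seed = NULL,
                             direction = NULL, verbose = FALSE) {
  stopifnot(inherits(full_spec, "library_spec"),
            inherits(control, "ga_control"))
  objectives <- as.integer(objectives)
  if (!objectives %in% c(2L, 3L))
    stop("`objectives` must be 2 or 3")
  if (is.null(direction))
    direction <- c(-1, rep(1, objectives - 1L))
  direction <- rep_len(direction, objectives)
  if (!all(direction %in% c(-1, 1)))
    stop("`direction` entries must be +1 (maximise) or -1 (minimise)")
  if (!is.null(seed)) set.seed(as.integer(seed))

  L <- genome_length(full_spec)
  N <- control$population_size
  mut_rate <- if (is.null(control$mutation_rate)) 1 / L
              else control$mutation_rate
  ctx <- .design_context(full_spec)
  cache <- new.env(hash = TRUE, parent = emptyenv())

  pop <- matrix(as.integer(stats::runif(N * L) < 0.5), N, L)
  ev <- .eval_population(pop, full_spec, ctx, objectives, cache,
                         control$size_cap)
  pop <- ev$pop
  fit <- ev$fit

  # archive of all non-dominated designs seen so far (dedup by genome)
  arch_keys <- character(0)
  arch_bits <- list()
  arch_fit <- matrix(numeric(0), 0L, objectives)
  update_archive <- function(new_pop, new_fit) {
    keys <- apply(new_pop, 1L, .genome_key)
    fresh <- !duplicated(keys) & !(keys %in% arch_keys)
    if (any(fresh)) {
      arch_keys <<- c(arch_keys, keys[fresh])
      arch_bits <<- c(arch_bits,
                      lapply(which(fresh), function(i) new_pop[i, ]))
      arch_fit <<- rbind(arch_fit, new_fit[fresh, , drop = FALSE])
    }
    nd <- pareto_filter(arch_fit, direction = direction)
    keep <- attr(nd, "indices")
    arch_keys <<- arch_keys[keep]
    arch_bits <<- arch_bits[keep]
    arch_fit <<- arch_fit[keep, , drop = FALSE]
  }
  archive_signature <- function() {
    paste(sort(apply(arch_fit, 1L, paste, collapse = ",")), collapse = ";")
  }
  update_archive(pop, fit)

  history <- vector("list", control$max_generations + 1L)
  record <- function(gen) {
    best <- vapply(seq_len(objectives), function(k) {
      v <- arch_fit[, k]
      if (direction[k] > 0) max(v) else min(v)
    }, numeric(1L))
    history[[gen + 1L]] <<- c(generation = gen, front_size = nrow(arch_fit),
                              stats::setNames(best, paste0("best_ff",
                                                           seq_len(objectives))))
  }
  record(0L)

  sig <- archive_signature()
  stall <- 0L
  gen <- 0L
  while (gen < control$max_generations) {
    gen <- gen + 1L
    scaled <- sweep(fit, 2L, direction, `*`)
    nd <- .nds_fronts(scaled)
    crowd <- numeric(N)
    for (f in nd$fronts) crowd[f] <- .crowding(scaled, f)

    # binary tournament on (rank, crowding)
    a <- sample.int(N, N, replace = TRUE)
    b <- sample.int(N, N, replace = TRUE)
    better <- nd$rank[a] < nd$rank[b] |
      (nd$rank[a] == nd$rank[b] & crowd[a] >= crowd[b])
    parents <- ifelse(better, a, b)

    # uniform crossover + per-bit mutation
    half <- N %/% 2L
    i1 <- parents[seq_len(half)]
    i2 <- parents[half + seq_len(half)]
    A <- pop[i1, , drop = FALSE]
    B <- pop[i2, , drop = FALSE]
    swap <- matrix(stats::runif(half * L) < 0.5, half, L)
    swap[stats::runif(half) >= control$crossover_rate, ] <- FALSE
    C1 <- A; C1[swap] <- B[swap]
    C2 <- B; C2[swap] <- A[swap]
    children <- rbind(C1, C2)
    if (nrow(children) < N)
      children <- rbind(children, pop[parents[N], , drop = FALSE])
    flip <- matrix(stats::runif(N * L) < mut_rate, N, L)
    children[flip] <- 1L - children[flip]

    ev <- .eval_population(children, full_spec, ctx, objectives, cache,
                           control$size_cap)
    children <- ev$pop
    child_fit <- ev$fit
    update_archive(children, child_fit)
    record(gen)

    comb_pop <- rbind(pop, children)
    comb_fit <- rbind(fit, child_fit)
    sel <- .environmental_select(sweep(comb_fit, 2L, direction, `*`), N,
                                 control$pareto_fraction)
    pop <- comb_pop[sel, , drop = FALSE]
    fit <- comb_fit[sel, , drop = FALSE]

    new_sig <- archive_signature()
    if (identical(new_sig, sig)) stall <- stall + 1L else stall <- 0L
    sig <- new_sig
    if (verbose && gen %% 10L == 0L)
      message(sprintf("generation %d: archive front %d solutions", gen,
                      nrow(arch_fit)))
    if (stall >= control$stall_generations) break
  }

  history <- do.call(rbind, history[!vapply(history, is.null, logical(1L))])
  .build_pareto_front(full_spec, objectives, direction, control, seed,
                      arch_bits, arch_fit, gen, length(ls(cache)),
                      stall >= control$stall_generations,
                      as.data.frame(history))
}

.build_pareto_front <- function(full_spec, objectives, direction, control,
                                seed, bits, fit, generations, evaluations,
                                converged, history) {
  colnames(fit) <- paste0("ff", seq_len(objectives))
  ord <- do.call(order, c(as.data.frame(fit),
                          list(vapply(bits, .genome_key, character(1L)))))
  bits <- bits[ord]
  fit <- fit[ord, , drop = FALSE]
  designs <- lapply(bits, function(b) read_genome(b, full_spec,
                                                  repair = FALSE))
  subsets <- vapply(designs, function(d)
    vapply(d$positions, paste, character(1L), collapse = ""),
    character(length(full_spec$positions)))
  if (is.null(dim(subsets))) subsets <- matrix(subsets, nrow = 1L)
  front <- as.data.frame(t(subsets), stringsAsFactors = FALSE)
  names(front) <- paste0("pos", seq_len(nrow(subsets)))
  front <- cbind(front, as.data.frame(fit))
  front$mass_diversity_pct <- 100 * fit[, 2L] / fit[, 1L]
  if (objectives == 3L)
    front$seq_diversity_pct <- 100 * fit[, 3L] / fit[, 1L]
  rownames(front) <- NULL
  structure(list(front = front, genomes = bits, designs = designs,
                 fitness = fit, spec = full_spec, objectives = objectives,
                 direction = direction, control = control, seed = seed,
                 generations = generations, evaluations = evaluations,
                 converged = converged, history = history),
            class = "pareto_front")
}

#' @export
print.pareto_front <- function(x, ...) {
  cat("NSGA-II peptide library optimization (", x$objectives,
      " objectives)\n", sep = "")
  cat("  generations:", x$generations,
      if (x$converged) "(stalled)" else "(generation limit)", "\n")
  cat("  genomes evaluated:", x$evaluations, "\n")
  cat("  Pareto front:", nrow(x$front), "designs\n")
  cat("  mass diversity range: ",
      sprintf("%.1f%% - %.1f%%", min(x$front$mass_diversity_pct),
              max(x$front$mass_diversity_pct)), "\n")
  invisible(x)
}

#' @export
summary.pareto_front <- function(object, ...) {
  print(object)
  cat("\nFront (one row per design):\n")
  print(utils::head(object$front, 15L))
  if (nrow(object$front) > 15L)
    cat("... and", nrow(object$front) - 15L, "more rows\n")
  invisible(object$front)
}

#' @export
as.data.frame.pareto_front <- function(x, ...) x$front

#' Plot a Pareto front
#'
#' Scatter of library size against mass diversity percentage (and, for
#' three-objective runs, sequence diversity as open symbols).
#'
#' @param x A `pareto_front`.
#' @param log Plot size on a log axis (default TRUE).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.pareto_front <- function(x, log = TRUE, ...) {
  fr <- x$front
  graphics::plot(fr$mass_diversity_pct, fr$ff1, pch = 19,
                 log = if (log) "y" else "",
                 xlab = "mass diversity (%)",
                 ylab = "library size (permutations)", ...)
  if (!is.null(fr$seq_diversity_pct))
    graphics::points(fr$seq_diversity_pct, fr$ff1, pch = 1)
  invisible(x)
}

#' Detailed report for one Pareto-front design
#'
#' Re-runs the calculator for the selected front row: full mass table,
#' unique-by-mass records, unique-by-composition records and the
#' sequence-logo frequency matrix.
#'
#' @param x A `pareto_front`.
#' @param index Front row number.
#' @return List with `design` (a `library_spec`), `fitness`, `metrics`,
#'   `table` (mass table), `unique_mass`, `unique_composition` and `logo`.
#' @export
pick_solution <- function(x, index) {
  stopifnot(inherits(x, "pareto_front"))
  index <- as.integer(index)
  if (is.na(index) || index < 1L || index > nrow(x$front))
    stop("`index` must be a front row number between 1 and ", nrow(x$front))
  design <- x$designs[[index]]
  tab <- mass_table(design)
  list(design = design,
       fitness = x$fitness[index, ],
       metrics = diversity_metrics(design),
       table = tab,
       unique_mass = exclude_similar_mass(tab, design$tolerance),
       unique_composition = exclude_equal_composition(tab),
       logo = logo_matrix(tab$sequence))
}
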