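test_that("run configurations round-trip through YAML", {
  cfg <- run_config("optimize", positions = rep("serwaG", 5),
                    tolerance = 1, objectives = 2, seed = 42,
                    output_dir = "out",
                    ga = list(population_size = 50L, max_generations = 20L))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  expect_equal(read_run_config(path), cfg)
  sweep <- run_config("calc", positions = c("FASRE", "FASRE"),
                      tolerance = c(2.5, 1, 0.5))
  write_run_config(sweep, path)
  expect_equal(read_run_config(path), sweep)
})

test_that("invalid configurations are rejected", {
  expect_error(run_config("calc", positions = character(0)), "non-empty")
  expect_error(run_config("calc", positions = "aXc"), "'X'")
  expect_error(run_config("optimize", positions = "ae",
                          tolerance = c(1, 2)), "single tolerance")
  expect_error(run_config("calc", positions = "ae", objectives = 4),
               "objectives")
})

test_that("the calculator run writes CSVs whose row counts match its summary", {
  cfg_path <- system.file("extdata", "configs", "fig1_pentapeptide.yaml",
                          package = "peplibdesign")
  cfg <- read_run_config(cfg_path)
  out <- withr::local_tempdir()
  cfg$output_dir <- out
  cfg$write_composition <- TRUE
  summary <- run_calc(cfg, quiet = TRUE)
  expect_equal(summary$total, 7776)
  full <- utils::read.csv(file.path(out, "permutations.csv"))
  expect_equal(nrow(full), summary$total)
  um <- utils::read.csv(file.path(out, "unique_by_mass.csv"))
  expect_equal(nrow(um), summary$unique_mass)
  uc <- utils::read.csv(file.path(out, "unique_by_composition.csv"))
  expect_equal(nrow(uc), summary$unique_composition)
  expect_equal(summary$mass_diversity_pct,
               100 * summary$unique_mass / summary$total)
})

test_that("the dipeptide representative run reports 25 permutations and 15 unique", {
  cfg <- read_run_config(system.file("extdata", "configs",
                                     "dipeptide_representatives.yaml",
                                     package = "peplibdesign"))
  cfg$output_dir <- withr::local_tempdir()
  summary <- run_calc(cfg, quiet = TRUE)
  expect_equal(summary$total, 25)
  expect_equal(summary$unique_mass, 15)
})

test_that("a tolerance sweep writes one unique-by-mass CSV per tolerance", {
  out <- withr::local_tempdir()
  cfg <- run_config("calc", positions = c("FASRE", "FASRE"),
                    tolerance = c(2.5, 1, 0.5), output_dir = out)
  summary <- run_calc(cfg, quiet = TRUE)
  expect_equal(nrow(summary), 3L)
  expect_true(all(diff(summary$unique_mass) >= 0))  # T decreasing
  expect_true(file.exists(file.path(out, "unique_by_mass_T2p5.csv")))
  expect_true(file.exists(file.path(out, "unique_by_mass_T1.csv")))
  expect_true(file.exists(file.path(out, "unique_by_mass_T0p5.csv")))
})

test_that("tolerance zero warns that nothing can collide", {
  cfg <- run_config("calc", positions = "ae", tolerance = 0,
                    output_dir = withr::local_tempdir())
  expect_warning(run_calc(cfg, quiet = TRUE), "tolerance 0")
})

test_that("logo matrices hold per-position frequencies", {
  expect_equal(logo_matrix(c("aG", "Ga"))["a", "pos1"], 0.5)
  expect_equal(logo_matrix(c("aG", "Ga"))["G", "pos1"], 0.5)
  single <- logo_matrix("aGy")
  expect_true(all(single %in% c(0, 1)))
  expect_equal(unname(colSums(single)), rep(1, 3))
  # a balanced two-way cartesian product shows 0.5/0.5 at every position
  bs1 <- enumerate_library(library_spec(c("aG", "wa", "rG", "er", "sr")))
  logo <- logo_matrix(bs1)
  expect_equal(unname(colSums(logo > 0)), rep(2, 5))
  expect_true(all(logo[logo > 0] == 0.5))
  expect_equal(unname(colSums(logo)), rep(1, 5))
  # permutation invariance over the peptide list
  expect_identical(logo, logo_matrix(rev(bs1)))
  expect_error(logo_matrix(c("aG", "aGy")), "same length")
  expect_error(logo_matrix(character(0)), "non-empty")
})

test_that("optimizer runs write a deterministic Pareto front CSV", {
  base <- withr::local_tempdir()
  cfg <- run_config("optimize", positions = c("ser", "wa", "Gi"),
                    tolerance = 1, seed = 11,
                    output_dir = file.path(base, "a"),
                    ga = list(population_size = 30L, max_generations = 25L,
                              stall_generations = 15L),
                    export = 1L)
  res <- run_optimize(cfg, quiet = TRUE)
  front_a <- file.path(base, "a", "pareto_front.csv")
  expect_true(file.exists(front_a))
  fr <- utils::read.csv(front_a, stringsAsFactors = FALSE)
  expect_equal(nrow(fr), nrow(res$front))
  expect_true(all(fr$ff2 <= fr$ff1))
  # detailed export for the picked solution
  sol_dir <- file.path(base, "a", "solution_001")
  expect_true(file.exists(file.path(sol_dir, "permutations.csv")))
  expect_true(file.exists(file.path(sol_dir, "unique_by_mass.csv")))
  expect_true(file.exists(file.path(sol_dir, "logo_matrix.csv")))
  # byte-identical on re-run with the same seed
  cfg$output_dir <- file.path(base, "b")
  run_optimize(cfg, quiet = TRUE)
  expect_identical(readLines(front_a),
                   readLines(file.path(base, "b", "pareto_front.csv")))
  # the diversity scatter table accompanies the front
  div <- utils::read.csv(file.path(base, "a", "front_diversity.csv"))
  expect_equal(nrow(div), nrow(fr))
  expect_true(all(div$seq_diversity_pct >= div$mass_diversity_pct - 1e-9))
})

test_that("picked solutions re-run the full calculator", {
  spec <- library_spec(c("ser", "wa"), tolerance = 1)
  res <- optimize_library(spec, control = ga_control(population_size = 20,
                                                     max_generations = 15,
                                                     stall_generations = 10),
                          seed = 3)
  sol <- pick_solution(res, 1)
  expect_s3_class(sol$design, "library_spec")
  expect_equal(nrow(sol$table), sol$fitness[["ff1"]])
  expect_equal(nrow(sol$unique_mass$kept), sol$fitness[["ff2"]])
  expect_equal(unname(colSums(sol$logo)), rep(1, 2))
  expect_error(pick_solution(res, 0), "row number")
})
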