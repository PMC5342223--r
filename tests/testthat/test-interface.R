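test_that("the bundled worked-example configuration loads with its settings", {
  cfg <- load_config(system.file("extdata", "three_tier_example.yaml",
                                 package = "motifsim"))
  expect_s3_class(cfg, "analysis_config")
  expect_equal(cfg$motif, "three_species_food_web")
  expect_equal(cfg$parameters$D, 0.1)
  expect_equal(cfg$parameters$S1_in, 5)
  expect_equal(unname(cfg$initial_conditions), rep(0.1, 6))
  expect_equal(cfg$solver$t_end, 100)
  expect_equal(cfg$solver$atol, 1e-6)
  expect_equal(cfg$solver$rtol, 1e-3)
  m <- attr(cfg, "motif")
  expect_s3_class(m, "motif")
  expect_equal(m$n_states, 6L)
})

test_that("validation failures name the offending field", {
  cfg <- yaml::read_yaml(system.file("extdata", "three_tier_example.yaml",
                                     package = "motifsim"))
  tmp <- tempfile(fileext = ".yaml")

  bad <- cfg; bad$parameters$Y2 <- NULL
  yaml::write_yaml(bad, tmp)
  expect_error(load_config(tmp), "Y2")

  bad <- cfg; bad$typo_key <- 1
  yaml::write_yaml(bad, tmp)
  expect_error(load_config(tmp), "typo_key")

  bad <- cfg; bad$analysis <- "multi_point"   # no grid section
  yaml::write_yaml(bad, tmp)
  expect_error(load_config(tmp), "grid")

  expect_error(load_config(tempfile()), "not found")
})

test_that("configurations round-trip through write_config", {
  cfg <- load_config(system.file("extdata", "three_tier_example.yaml",
                                 package = "motifsim"))
  tmp <- tempfile(fileext = ".yaml")
  write_config(cfg, tmp)
  cfg2 <- load_config(tmp)
  expect_equal(cfg2$parameters, cfg$parameters)
  expect_equal(cfg2$solver, cfg$solver)
  expect_equal(cfg2$initial_conditions, cfg$initial_conditions)
  expect_equal(cfg2$analysis, cfg$analysis)
})

test_that("single-point analysis writes a deterministic result bundle", {
  # cheap decoupled-pair system keeps the run fast
  cfg_list <- list(
    motif = "no_common_metabolites",
    analysis = "single_point",
    parameters = chemostat_pair_params(D = 0.1, kdec = 0),
    initial_conditions = 0.1,
    solver = list(t_end = 50),
    fixed_points = list(n_starts = 40))
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg_list, tmp)
  out1 <- file.path(tempdir(), "run1"); out2 <- file.path(tempdir(), "run2")
  r1 <- run_analysis(load_config(tmp), outdir = out1)
  expect_true(file.exists(file.path(out1, "trajectory.csv")))
  expect_true(file.exists(file.path(out1, "fixed_points.csv")))
  expect_true(file.exists(file.path(out1, "run_metadata.json")))
  fp_tab <- utils::read.csv(file.path(out1, "fixed_points.csv"))
  expect_equal(nrow(fp_tab), 4L)
  expect_true(all(c("stability", "steady_state") %in% names(fp_tab)))
  # byte-identical rerun
  run_analysis(load_config(tmp), outdir = out2)
  for (f in c("trajectory.csv", "fixed_points.csv"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
})

test_that("the worked-example fixed-point table prints the expected stability column", {
  cfg <- load_config(system.file("extdata", "three_tier_example.yaml",
                                 package = "motifsim"))
  out <- file.path(tempdir(), "three_tier_run")
  res <- run_analysis(cfg, outdir = out)
  tab <- utils::read.csv(file.path(out, "fixed_points.csv"))
  expect_equal(nrow(tab), 4L)
  expect_equal(sort(tab$stability),
               sort(c("Stable node", "Unstable", "Unstable", "Stable node")))
  expect_equal(sum(tab$stability == "Stable node"), 2L)
})

test_that("basin and portrait analyses are dispatched from config", {
  cfg_list <- list(
    motif = "no_common_metabolites",
    analysis = "basin",
    parameters = chemostat_pair_params(D = 1.5),  # single attractor
    initial_conditions = 0.1,
    grid = list(axis1 = list(name = "X1", from = 0.05, to = 0.15, step = 0.1),
                axis2 = list(name = "X2", from = 0.05, to = 0.15, step = 0.1)),
    basin = list(horizon = 300),
    fixed_points = list(n_starts = 20))
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg_list, tmp)
  out <- file.path(tempdir(), "basin_run")
  run_analysis(load_config(tmp), outdir = out)
  expect_true(file.exists(file.path(out, "basin.csv")))
  expect_true(file.exists(file.path(out, "basin_legend.json")))
  b <- utils::read.csv(file.path(out, "basin.csv"))
  expect_equal(nrow(b), 4L)
  expect_length(unique(b$label), 1L)
})

test_that("the thermodynamics analysis is dispatched and reports the inhibition factor", {
  cfg_list <- list(
    motif = "food_chain",
    analysis = "thermo",
    parameters = list(D = 0.05, S1_in = 3, S2_in = 0, Y1 = 0.2, Y2 = 0.25,
                      kdec1 = 0.01, kdec2 = 0.01, gamma0 = 0.9,
                      km1 = 4, KS1 = 0.4, km2 = 5, KS2 = 0.3),
    thermo = list(temperature = 298.15, dG0 = -30,
                  reactants = list(A = 1), products = list(B = 1),
                  activities = list(A = 1, B = 1)))
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg_list, tmp)
  out <- file.path(tempdir(), "thermo_run")
  res <- run_analysis(load_config(tmp), outdir = out)
  expect_true(file.exists(file.path(out, "thermo.json")))
  th <- jsonlite::read_json(file.path(out, "thermo.json"))
  # unit activities: dG_rxn = dG0; I_th = 1 - exp(dG0 / RT)
  expect_equal(th$dG_rxn, -30)
  expect_equal(th$I_th, 1 - exp(-30 / (8.31446e-3 * 298.15)),
               tolerance = 1e-10)
})
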