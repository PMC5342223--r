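test_that("a degenerate one-cell sweep equals single-point analysis", {
  m <- build_motif("no_common_metabolites", chemostat_pair_params(D = 0.1))
  rmap <- operating_diagram(m, grid_axis("D", 0.1, 0.1, 1),
                            grid_axis("S1_in", 2, 2, 1), n_starts = 60)
  expect_equal(nrow(rmap$cells), 1L)
  fps <- fixed_points(m, n_starts = 60)
  expect_equal(unname(rmap$legend[["J1"]]), motifsim:::cell_signature(fps))
})

test_that("sweep cells replay independent single-point analyses", {
  m <- build_motif("no_common_metabolites", chemostat_pair_params(D = 0.1))
  ax1 <- grid_axis("D", 0.05, 0.25, 0.1)
  ax2 <- grid_axis("S1_in", 1, 3, 1)
  rmap <- operating_diagram(m, ax1, ax2, n_starts = 40)
  expect_equal(nrow(rmap$cells), 9L)
  for (i in seq_len(9)) {
    mi <- set_params(m, D = rmap$cells$D[i], S1_in = rmap$cells$S1_in[i])
    sig <- motifsim:::cell_signature(fixed_points(mi, n_starts = 40))
    expect_equal(rmap$cells$signature[i], sig, info = paste("cell", i))
  }
  # region ids are numbered by first appearance and the legend covers all
  expect_true(all(rmap$cells$region %in% names(rmap$legend)))
  expect_equal(rmap$cells$region[1], "J1")
})

test_that("sweep axes must name nonnegative motif parameters", {
  m <- build_motif("no_common_metabolites", chemostat_pair_params())
  expect_error(operating_diagram(m, grid_axis("bogus", 0, 1, 0.5),
                                 grid_axis("S1_in", 1, 2, 1)), "bogus")
  expect_error(grid_axis("D", 1, 0, 0.1))   # reversed range
  expect_error(grid_axis("D", 0, 1, -0.1))  # nonpositive step
})

test_that("a single-attractor system yields a one-label basin map", {
  # high dilution: washout is the only equilibrium and attracts everything
  m <- build_motif("no_common_metabolites", chemostat_pair_params(D = 1.5))
  bm <- basin_of_attraction(m, grid_axis("X1", 0.05, 0.25, 0.1),
                            grid_axis("X2", 0.05, 0.25, 0.1),
                            fixed_ics = c(2, 0.1, 3, 0.1),
                            horizon = 400)
  labs <- unique(bm$cells$fixed_point)
  expect_length(labs, 1L)
  expect_false(labs %in% c("none", "failed"))
})

test_that("basin cells replay direct integrations plus nearest-point matching", {
  m <- build_motif("no_common_metabolites",
                   chemostat_pair_params(D = 0.1, kdec = 0))
  fps <- fixed_points(m, n_starts = 60)
  bm <- basin_of_attraction(m, grid_axis("X1", 0, 0.2, 0.1),
                            grid_axis("X2", 0, 0.2, 0.1),
                            fixed_ics = c(2, 0, 3, 0), horizon = 600,
                            fps = fps)
  s <- solver_settings(t_end = 600)
  for (i in seq_len(nrow(bm$cells))) {
    x0 <- c(2, bm$cells$X1[i], 3, bm$cells$X2[i])
    tr <- integrate_motif(m, x0, s, times = c(0, 600))
    xe <- tr$states[nrow(tr$states), ]
    d <- vapply(fps, function(f) sqrt(sum((xe - f$state)^2)), numeric(1))
    expect_equal(bm$cells$fixed_point[i], fps[[which.min(d)]]$fp_id)
  }
  # a cell whose IC is exactly a stable fixed point maps to that point
  stable <- Filter(function(f) f$stability$is_stable, fps)
  f0 <- stable[[1]]
  bm0 <- basin_of_attraction(m, grid_axis("X1", f0$state[["X1"]],
                                          f0$state[["X1"]], 1),
                             grid_axis("X2", f0$state[["X2"]],
                                       f0$state[["X2"]], 1),
                             fixed_ics = f0$state, horizon = 200, fps = fps)
  expect_equal(bm0$cells$fixed_point, f0$fp_id)
})

test_that("boundary bisection refines a known threshold to tolerance", {
  # synthetic classifier with an exact boundary at ratio 2
  cls <- function(r) if (r >= 2) "A" else "B"
  r <- motifsim:::bisect_boundary(cls, c(0.5, 8), tol = 1e-4)
  expect_equal(r, 2, tolerance = 1e-3)
  expect_error(motifsim:::bisect_boundary(function(r) "A", c(0.5, 8)),
               "same label")
})
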