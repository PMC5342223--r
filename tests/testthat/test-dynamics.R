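test_that("a trajectory started at the washout equilibrium stays constant", {
  m <- build_motif("no_common_metabolites", chemostat_pair_params(D = 0.2))
  w <- washout_state(m)
  traj <- integrate_motif(m, w, solver_settings(t_end = 50))
  expect_true(traj$success)
  dev <- sweep(traj$states, 2L, w)
  expect_lt(max(abs(dev)), 1e-6)
})

test_that("biomass washes out when dilution exceeds the maximal net growth rate", {
  # pair 1: Y km = 0.4 < D = 0.5 -> X1 must decay to ~0 by large t
  p <- chemostat_pair_params(D = 0.5)
  m <- build_motif("no_common_metabolites", p)
  traj <- integrate_motif(m, c(2, 0.5, 3, 0.5), solver_settings(t_end = 400))
  expect_true(traj$success)
  x1 <- traj$states[, "X1"]
  expect_lt(x1[length(x1)], 1e-6)
  # monotone decrease after an initial transient
  expect_true(all(diff(x1[traj$times > 20]) <= 1e-10))
})

test_that("settling time recovers the closed-form exponential relaxation", {
  # x(t) = x* + exp(-t): with a relative band of exp(-5)/x* the earliest
  # in-band time is t = 5
  times <- seq(0, 30, by = 0.01)
  xstar <- 1
  st <- structure(list(times = times,
                       states = matrix(xstar + exp(-times), ncol = 1,
                                       dimnames = list(NULL, "x")),
                       x0 = xstar + 1,
                       settings = solver_settings(atol = 1e-300,
                                                  t_end = 30),
                       success = TRUE, diagnostics = "ok"),
                  class = "motif_trajectory")
  t5 <- settling_time(st, rel_band = exp(-5) / xstar, abs_floor = 1e-300)
  expect_equal(t5, 5, tolerance = 0.02)
  # a constant trajectory settles immediately
  cst <- st; cst$states[] <- xstar
  expect_equal(settling_time(cst, rel_band = 0.01), 0)
})

test_that("phase portraits enumerate the grid row-major and replay single runs exactly", {
  m <- build_motif("no_common_metabolites", chemostat_pair_params(D = 0.1))
  s <- solver_settings(t_end = 20)
  # degenerate single-point grid reproduces integrate_motif exactly
  pp1 <- phase_portrait(m, varied = c("X1", "X2"),
                        ranges = list(c(0.3, 0.3, 1), c(0.4, 0.4, 1)),
                        fixed_x0 = c(2, 0, 3, 0), settings = s)
  expect_length(pp1$trajectories, 1L)
  direct <- integrate_motif(m, c(2, 0.3, 3, 0.4), s)
  expect_identical(pp1$trajectories[[1]]$states, direct$states)

  pp <- phase_portrait(m, varied = c("X1", "X2"),
                       ranges = list(c(0.1, 0.3, 0.1), c(0.2, 0.4, 0.1)),
                       fixed_x0 = c(2, 0, 3, 0), settings = s)
  expect_length(pp$trajectories, 9L)
  # row-major: X1 is the outer axis
  expect_equal(pp$grid$X1, rep(c(0.1, 0.2, 0.3), each = 3))
  expect_equal(pp$grid$X2, rep(c(0.2, 0.3, 0.4), times = 3))
  for (i in seq_len(9)) {
    x0 <- c(2, pp$grid$X1[i], 3, pp$grid$X2[i])
    expect_identical(pp$trajectories[[i]]$states,
                     integrate_motif(m, x0, s)$states)
  }
})

test_that("integration tolerances are honoured: halving rtol barely moves the endpoint", {
  m <- build_three_tier()
  fin <- function(rtol) {
    tr <- integrate_motif(m, rep(0.1, 6),
                          solver_settings(rtol = rtol, t_end = 100))
    tr$states[nrow(tr$states), ]
  }
  a <- fin(1e-3); b <- fin(5e-4)
  expect_lt(max(abs(a - b) / pmax(abs(a), 1e-6)), 1e-3)
})

test_that("trajectories from the nonnegative orthant stay essentially nonnegative", {
  set.seed(12)
  for (nm in c("syntrophy", "waste_product_inhibition",
               "three_species_food_web")) {
    m <- random_motif(nm)
    s <- solver_settings(t_end = 150)
    traj <- integrate_motif(m, runif(m$n_states, 0, 2), s)
    expect_true(traj$success, info = nm)
    expect_gt(min(traj$states), -10 * s$atol)
  }
})

test_that("dimension and negativity of initial states are rejected", {
  m <- build_three_tier()
  expect_error(integrate_motif(m, rep(0.1, 5)), "dimension")
  expect_error(integrate_motif(m, c(-0.1, rep(0.1, 5))), "nonnegative")
})
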