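test_that("temperature adjustment is an exact quadratic interpolator", {
  # constant reference values: any temperature returns the constant
  e <- list(ref_T = c(280, 300, 320), ref_dG = c(-50, -50, -50))
  expect_equal(gibbs_at_temperature(e, 291.3), -50)
  # values on a known quadratic are reproduced exactly between references
  q <- function(T) 2 - 0.01 * T + 3e-5 * T^2
  e2 <- list(ref_T = c(273.15, 298.15, 323.15, 348.15),
             ref_dG = q(c(273.15, 298.15, 323.15, 348.15)))
  expect_equal(gibbs_at_temperature(e2, 310), q(310), tolerance = 1e-9)
  # three arbitrary points: the quadratic interpolates each reference,
  # cross-checked by a Vandermonde solve
  set.seed(4)
  Tr <- c(275, 300, 330); g <- rnorm(3, -100, 20)
  co <- solve(cbind(1, Tr, Tr^2), g)
  e3 <- list(ref_T = Tr, ref_dG = g)
  for (i in 1:3) {
    expect_equal(gibbs_at_temperature(e3, Tr[i]), g[i], tolerance = 1e-8)
    expect_equal(gibbs_at_temperature(e3, Tr[i]),
                 unname(co[1] + co[2] * Tr[i] + co[3] * Tr[i]^2),
                 tolerance = 1e-8)
  }
  expect_error(gibbs_at_temperature(e3, 400), "window")
  expect_error(gibbs_at_temperature(list(ref_T = c(1, 2),
                                         ref_dG = c(1, 2)), 1.5), "3")
})

test_that("the bundled compound table parses and evaluates", {
  tab <- read_compound_table(system.file("extdata", "compounds_gibbs.tsv",
                                         package = "motifsim"))
  expect_setequal(names(tab), c("H2", "CO2", "CH4", "acetate", "H2O"))
  expect_equal(tab$CH4$phase, "gas")
  expect_equal(gibbs_at_temperature(tab$CH4, 298.15), -50.72,
               tolerance = 1e-6)
  expect_gt(tab$acetate$molar_mass, 0)
})

test_that("the reaction free energy follows dG0 + RT ln Q", {
  rxn <- reaction_thermo(c(A = 1, B = 2), c(C = 1), temperature = 298.15,
                         dG0 = -40)
  # unit activities: quotient 1, dG = dG0
  expect_equal(gibbs_reaction(rxn, c(A = 1, B = 1, C = 1)), -40)
  # quotient e at 298.15 K adds RT = 2.4788 kJ/mol
  expect_equal(gibbs_reaction(rxn, c(A = 1, B = 1, C = exp(1))),
               -40 + 2.4788, tolerance = 1e-3)
  # swapping reactants and products with sign-flipped dG0 negates dG
  rev <- reaction_thermo(c(C = 1), c(A = 1, B = 2), temperature = 298.15,
                         dG0 = 40)
  acts <- c(A = 0.3, B = 0.07, C = 1.9)
  expect_equal(gibbs_reaction(rev, acts), -gibbs_reaction(rxn, acts),
               tolerance = 1e-12)
  expect_error(gibbs_reaction(rxn, c(A = 1, B = 0, C = 1)), "quotient")
})

test_that("reaction free energies are additive over reaction composition", {
  # A -> B and B -> C compose to A -> C
  r1 <- reaction_thermo(c(A = 1), c(B = 1), 310, dG0 = -12)
  r2 <- reaction_thermo(c(B = 1), c(C = 1), 310, dG0 = 7)
  r12 <- reaction_thermo(c(A = 1), c(C = 1), 310, dG0 = -5)
  acts <- c(A = 0.4, B = 0.9, C = 2.2)
  expect_equal(gibbs_reaction(r1, acts) + gibbs_reaction(r2, acts),
               gibbs_reaction(r12, acts), tolerance = 1e-12)
})

test_that("COD units convert aqueous activities through molar mass", {
  tab <- read_compound_table(system.file("extdata", "compounds_gibbs.tsv",
                                         package = "motifsim"))
  rmol <- reaction_thermo(c(acetate = 1), c(CH4 = 1), 298.15, dG0 = -31,
                          units = "molar", compounds = tab)
  rcod <- reaction_thermo(c(acetate = 1), c(CH4 = 1), 298.15, dG0 = -31,
                          units = "COD", compounds = tab)
  acts <- c(acetate = 0.5, CH4 = 0.2)
  # acetate is aqueous: its activity is divided by the molar mass; CH4 is
  # gas and enters unchanged
  acts_conv <- c(acetate = 0.5 / tab$acetate$molar_mass, CH4 = 0.2)
  expect_equal(gibbs_reaction(rcod, acts), gibbs_reaction(rmol, acts_conv),
               tolerance = 1e-12)
})

test_that("the thermodynamic inhibition factor has the documented limits", {
  expect_equal(thermo_inhibition(0, 298.15), 0)
  expect_equal(thermo_inhibition(-1e6, 298.15), 1)
  RT <- 8.31446e-3 * 298.15
  expect_equal(thermo_inhibition(RT * log(2), 298.15, clamp = FALSE), -1,
               tolerance = 1e-12)
  expect_equal(thermo_inhibition(RT * log(2), 298.15, clamp = TRUE), 0)
  # strictly decreasing in dG and bounded in [0, 1] when clamped
  dg <- seq(-50, 50, length.out = 101)
  v <- thermo_inhibition(dg, 310)
  expect_true(all(v >= 0 & v <= 1))
  expect_true(all(diff(v[v > 0 & v < 1]) <= 0))
})

test_that("a neutral extension leaves the motif's analysis unchanged", {
  m <- build_motif("food_chain",
    params = list(D = 0.05, S1_in = 3, S2_in = 0, Y1 = 0.2, Y2 = 0.25,
                  kdec1 = 0.01, kdec2 = 0.01, gamma0 = 0.9,
                  km1 = 4, KS1 = 0.4, km2 = 5, KS2 = 0.3))
  ext <- extend_motif(m, target = "X2", rxn = NULL, mu_new = 1)
  expect_equal(ext$n_states, m$n_states)
  set.seed(8)
  for (rep in 1:5) {
    x <- runif(4, 0, 3)
    expect_equal(unname(motif_rhs(ext, x)), unname(motif_rhs(m, x)),
                 tolerance = 1e-12)
  }
  f0 <- fixed_points(m, n_starts = 40)
  f1 <- fixed_points(ext, n_starts = 40)
  expect_equal(length(f0), length(f1))
  for (i in seq_along(f0)) {
    expect_equal(unname(f1[[i]]$state), unname(f0[[i]]$state),
                 tolerance = 1e-8)
    expect_equal(f1[[i]]$stability$is_stable, f0[[i]]$stability$is_stable)
  }
})

test_that("reaction extensions append decaying product states and keep washout", {
  m <- build_motif("food_chain",
    params = list(D = 0.05, S1_in = 3, S2_in = 0, Y1 = 0.2, Y2 = 0.25,
                  kdec1 = 0.01, kdec2 = 0.01, gamma0 = 0.9,
                  km1 = 4, KS1 = 0.4, km2 = 5, KS2 = 0.3))
  rxn <- reaction_thermo(c(S2 = 1), c(P = 1), temperature = 298.15,
                         dG0 = -30)
  ext <- extend_motif(m, target = "X2", rxn = rxn, new_products = "P",
                      gamma_new = 0.5)
  expect_equal(ext$n_states, 5L)
  expect_equal(ext$jac_method, "finite_difference")
  expect_error(extend_motif(m, target = "X2", new_products = "S1"),
               "collide")
  expect_error(extend_motif(m, target = "S1"), "biomass")
  # all-zero biomass, substrates at inflow, a positive amount of P:
  # original states balance; P decays at -D P
  x <- c(3, 0, 0, 0, 0.7)
  r <- motif_rhs(ext, x)
  expect_equal(unname(r[1:4]), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(r[5]), -0.05 * 0.7, tolerance = 1e-12)
  # fixed-point enumeration still finds the (extended) washout state
  fps <- fixed_points(ext, n_starts = 30)
  w <- c(3, 0, 0, 0, 0)
  d <- vapply(fps, function(f) max(abs(f$state - w)), numeric(1))
  expect_lt(min(d), 1e-10)
})

test_that("thermodynamic inhibition throttles growth in an extended motif", {
  m <- build_motif("food_chain",
    params = list(D = 0.05, S1_in = 3, S2_in = 0, Y1 = 0.2, Y2 = 0.25,
                  kdec1 = 0.01, kdec2 = 0.01, gamma0 = 0.9,
                  km1 = 4, KS1 = 0.4, km2 = 5, KS2 = 0.3))
  # strongly endergonic reaction: I_th clamps to 0 and the target biomass
  # equation reduces to pure washout + decay
  rxn_bad <- reaction_thermo(c(S2 = 1), c(P = 1), 298.15, dG0 = 50)
  ext <- extend_motif(m, target = "X2", rxn = rxn_bad, new_products = "P")
  x <- c(1, 0.2, 0.8, 0.3, 0.1)
  r <- motif_rhs(ext, x)
  expect_equal(unname(r[["X2"]]), -(0.05 + 0.01) * 0.3, tolerance = 1e-12)
  # strongly exergonic: I_th ~ 1 recovers the unextended growth rate
  rxn_good <- reaction_thermo(c(S2 = 1), c(P = 1), 298.15, dG0 = -500)
  ext2 <- extend_motif(m, target = "X2", rxn = rxn_good, new_products = "P")
  r2 <- motif_rhs(ext2, x)
  r0 <- motif_rhs(m, x[1:4])
  expect_equal(unname(r2[["X2"]]), unname(r0[["X2"]]), tolerance = 1e-6)
})
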