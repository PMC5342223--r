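# Shared fixtures: parameter sets and independently hand-coded oracles.

# Three-tier food-web parameters (chlorophenol/phenol/hydrogen community,
# COD units); the worked-example operating point is D = 0.1, S1_in = 5.
three_tier_params <- function(D = 0.1, S1_in = 5) {
  list(D = D, S1_in = S1_in, S2_in = 0, S3_in = 0,
       km1 = 29.12, KS1 = 5.2e-5, Y1 = 0.019, kdec1 = 0.02,
       km2 = 26,    KS2 = 0.302,  Y2 = 0.04,  kdec2 = 0.02,
       km3 = 35,    KS3 = 2.5e-5, Y3 = 0.06,  kdec3 = 0.02,
       Ki3 = 3.5e-6, KS3c = 1e-6,
       gamma0 = 1.0769, gamma1 = 0.1429, gamma2 = 0.0769)
}

build_three_tier <- function(D = 0.1, S1_in = 5, ...) {
  build_motif("three_species_food_web", three_tier_params(D, S1_in), ...)
}

# printed fixed-point table for the worked example (2-3 significant
# figures) with the unit-in-last-displayed-digit of each entry, used to
# compare at displayed precision
three_tier_printed_fps <- function() {
  rbind(
    FP_washout  = c(5,        0,       0,    0,       0,       0),
    FP_partial1 = c(4.91,     1.37e-3, 0.04, 1.62e-3, 2.77e-7, 0),
    FP_partial2 = c(1.51e-5,  0.08,    2.48, 0.09,    2.35e-5, 0),
    FP_coexist  = c(2.93e-5,  0.08,    0.06, 0.17,    1.52e-6, 0.02))
}

three_tier_printed_ulp <- function() {
  rbind(
    FP_washout  = c(0.01,  0,    0,    0,    0,     0),
    FP_partial1 = c(0.01,  1e-5, 0.01, 1e-5, 1e-9,  0),
    FP_partial2 = c(1e-7,  0.01, 0.01, 0.01, 1e-7,  0),
    FP_coexist  = c(1e-7,  0.01, 0.01, 0.01, 1e-8,  0.01))
}

# independently hand-coded three-tier right-hand side (direct transcription
# of the documented equations; used to re-verify residuals)
three_tier_rhs_oracle <- function(x, p) {
  S1 <- x[1]; X1 <- x[2]; S2 <- x[3]; X2 <- x[4]; S3 <- x[5]; X3 <- x[6]
  f1 <- p$km1 * S1 / (p$KS1 + S1) * S3 / (p$KS3c + S3)
  f2 <- p$km2 * S2 / (p$KS2 + S2)
  f3 <- p$km3 * S3 / (p$KS3 + S3)
  I3 <- 1 / (1 + S3 / p$Ki3)
  c(p$D * (p$S1_in - S1) - f1 * X1,
    -p$D * X1 + p$Y1 * f1 * X1 - p$kdec1 * X1,
    p$D * (p$S2_in - S2) + p$gamma0 * (1 - p$Y1) * f1 * X1 - f2 * X2 * I3,
    -p$D * X2 + p$Y2 * f2 * X2 * I3 - p$kdec2 * X2,
    p$D * (p$S3_in - S3) + p$gamma1 * (1 - p$Y2) * f2 * X2 * I3 -
      f3 * X3 - p$gamma2 * f1 * X1,
    -p$D * X3 + p$Y3 * f3 * X3 - p$kdec3 * X3)
}

# hand-coded commensal food-chain right-hand side (oracle)
food_chain_rhs_oracle <- function(x, p) {
  S1 <- x[1]; X1 <- x[2]; S2 <- x[3]; X2 <- x[4]
  f1 <- p$km1 * S1 / (p$KS1 + S1)
  f2 <- p$km2 * S2 / (p$KS2 + S2)
  c(p$D * (p$S1_in - S1) - f1 * X1,
    (-p$D + p$Y1 * f1 - p$kdec1) * X1,
    p$D * (p$S2_in - S2) + p$gamma0 * (1 - p$Y1) * f1 * X1 - f2 * X2,
    (-p$D + p$Y2 * f2 - p$kdec2) * X2)
}

# decoupled two-pair chemostat; closed-form interior equilibrium per pair
# (Monod, no decay): S* = KS D / (Y km - D), X* = Y (S_in - S*)
chemostat_pair_params <- function(D = 0.1, kdec = 0) {
  list(D = D, S1_in = 2, S2_in = 3, Y1 = 0.2, Y2 = 0.3,
       kdec1 = kdec, kdec2 = kdec,
       km1 = 2, KS1 = 0.5, km2 = 3, KS2 = 0.4)
}

# random valid parameter set for any motif (seeded by caller)
random_params <- function(motif_name) {
  p <- list(D = runif(1, 0.01, 0.4),
            S1_in = runif(1, 0.5, 10), S2_in = runif(1, 0, 5),
            S3_in = runif(1, 0, 2),
            Y1 = runif(1, 0.05, 0.6), Y2 = runif(1, 0.05, 0.6),
            Y3 = runif(1, 0.05, 0.6),
            kdec1 = runif(1, 0, 0.1), kdec2 = runif(1, 0, 0.1),
            kdec3 = runif(1, 0, 0.1),
            km1 = runif(1, 1, 40), KS1 = runif(1, 1e-3, 1),
            km2 = runif(1, 1, 40), KS2 = runif(1, 1e-3, 1),
            km3 = runif(1, 1, 40), KS3 = runif(1, 1e-3, 1),
            Ki1 = runif(1, 1e-3, 1), Ki2 = runif(1, 1e-3, 1),
            Ki3 = runif(1, 1e-3, 1), KS3c = runif(1, 1e-4, 0.1),
            gamma0 = runif(1, 0.2, 2), gamma1 = runif(1, 0.2, 2),
            gamma2 = runif(1, 0.05, 0.5))
  p
}

all_motif_names <- function() list_motifs()$name

# build a motif with random valid parameters (extra parameters are ignored
# by build_motif's required-symbol filter)
random_motif <- function(name) build_motif(name, random_params(name))
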