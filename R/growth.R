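#' Growth-kinetics catalogue
#'
#' Construct a specific growth (or substrate-uptake) rate function of the
#' limiting substrate concentration. Seven forms are available:
#'
#' \describe{
#'   \item{monod}{\code{k_m * S / (K_S + S)} -- saturating Monod kinetics,
#'     the default throughout the package.}
#'   \item{haldane}{\code{k_m * S / (K_S + S + S^2/K_i)} -- Andrews/Haldane
#'     substrate inhibition; maximal at \code{S = sqrt(K_S * K_i)}.}
#'   \item{contois}{\code{k_m * S / (K_S * X + S)} -- biomass-dependent
#'     half saturation.}
#'   \item{tessier}{\code{k_m * (1 - exp(-S/K_S))}.}
#'   \item{moser}{\code{k_m * S^n / (K_S + S^n)}.}
#'   \item{hill}{\code{k_m * S^n / (K_S^n + S^n)}.}
#'   \item{monod_thermo}{Monod kinetics scaled by a thermodynamic
#'     inhibition factor \code{I_th} (see \code{\link{thermo_inhibition}});
#'     as a standalone kinetic form \code{I_th} is a fixed multiplier,
#'     while \code{\link{extend_motif}} re-evaluates it from the reaction
#'     state at every step.}
#' }
#'
#' All rate and saturation constants must be strictly positive. Every form
#' evaluates to 0 at \code{S = 0} and (except Haldane) is nondecreasing
#' in \code{S}.
#'
#' @param form kinetic form, one of the seven names above.
#' @param k_m maximum specific growth/uptake rate (per day, substrate per
#'   biomass).
#' @param K_S half-saturation (or shape) constant, concentration units.
#' @param K_i inhibition constant (Haldane only), concentration units.
#' @param n exponent (Moser and Hill only), dimensionless, > 0.
#' @param I_th fixed thermodynamic factor in \code{[0, 1]}
#'   (\code{monod_thermo} only), default 1.
#' @return an object of class \code{"growth_kinetics"}.
#' @examples
#' g <- growth_kinetics("monod", k_m = 35, K_S = 2.5e-5)
#' evaluate_growth(g, S = 2.5e-5)  # half of k_m at S = K_S
#' @export
growth_kinetics <- function(form = c("monod", "haldane", "contois", "tessier",
                                     "moser", "hill", "monod_thermo"),
                            k_m, K_S, K_i = NULL, n = NULL, I_th = 1) {
  form <- match.arg(form)
  stopifnot(is.numeric(k_m), length(k_m) == 1L,
            is.numeric(K_S), length(K_S) == 1L)
  if (!(k_m > 0)) stop("'k_m' must be strictly positive", call. = FALSE)
  if (!(K_S > 0)) stop("'K_S' must be strictly positive", call. = FALSE)
  extra <- list()
  if (form == "haldane") {
    if (is.null(K_i) || !(K_i > 0))
      stop("haldane kinetics require a strictly positive 'K_i'", call. = FALSE)
    extra$K_i <- K_i
  }
  if (form %in% c("moser", "hill")) {
    if (is.null(n) || !(n > 0))
      stop(sprintf("%s kinetics require a strictly positive exponent 'n'", form),
           call. = FALSE)
    extra$n <- n
  }
  if (form == "monod_thermo") {
    if (!is.numeric(I_th) || I_th < 0 || I_th > 1)
      stop("'I_th' must lie in [0, 1]", call. = FALSE)
    extra$I_th <- I_th
  }
  structure(list(form = form, k_m = k_m, K_S = K_S, extra = extra),
            class = "growth_kinetics")
}

#' Evaluate a growth-kinetics form
#'
#' @param g a \code{\link{growth_kinetics}} object.
#' @param S substrate concentration(s), must be nonnegative.
#' @param X biomass concentration (used by the Contois form only), default 1.
#' @return specific rate value(s), same length as \code{S}.
#' @export
evaluate_growth <- function(g, S, X = 1) {
  stopifnot(inherits(g, "growth_kinetics"))
  if (any(S < 0)) stop("substrate concentration 'S' must be nonnegative",
                       call. = FALSE)
  km <- g$k_m; KS <- g$K_S
  switch(g$form,
    monod   = km * S / (KS + S),
    haldane = km * S / (KS + S + S^2 / g$extra$K_i),
    contois = km * S / (KS * X + S),
    tessier = km * (1 - exp(-S / KS)),
    moser   = km * S^g$extra$n / (KS + S^g$extra$n),
    hill    = km * S^g$extra$n / (KS^g$extra$n + S^g$extra$n),
    monod_thermo = g$extra$I_th * km * S / (KS + S))
}

#' @export
print.growth_kinetics <- function(x, ...) {
  ex <- if (length(x$extra))
    paste0(", ", paste(names(x$extra), unlist(x$extra), sep = " = ",
                       collapse = ", ")) else ""
  cat(sprintf("<growth_kinetics: %s (k_m = %g, K_S = %g%s)>\n",
              x$form, x$k_m, x$K_S, ex))
  invisible(x)
}

# Symbolic expression (as a string) for a growth form, used when motif
# right-hand sides are assembled; `svar`/`xvar` are state-variable names and
# `i` the species index used to name the kinetic parameters (km1, KS1, ...).
growth_expr <- function(form, i, svar, xvar) {
  km <- paste0("km", i); KS <- paste0("KS", i)
  switch(form,
    monod   = sprintf("%s*%s/(%s + %s)", km, svar, KS, svar),
    haldane = sprintf("%s*%s/(%s + %s + %s^2/Kih%d)", km, svar, KS, svar, svar, i),
    contois = sprintf("%s*%s/(%s*%s + %s)", km, svar, KS, xvar, svar),
    tessier = sprintf("%s*(1 - exp(-%s/%s))", km, svar, KS),
    moser   = sprintf("%s*%s^n%d/(%s + %s^n%d)", km, svar, i, KS, svar, i),
    hill    = sprintf("%s*%s^n%d/(%s^n%d + %s^n%d)", km, svar, i, KS, i, svar, i),
    monod_thermo = sprintf("Ith%d*%s*%s/(%s + %s)", i, km, svar, KS, svar),
    stop("unknown growth form: ", form, call. = FALSE))
}
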