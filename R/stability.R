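#' Classify local stability from a Jacobian spectrum
#'
#' Maps the eigenvalue spectrum at a fixed point onto the standard local
#' phase-portrait taxonomy. Real spectra give nodes or saddles; spectra with
#' complex pairs give spirals (or a center when every real part vanishes).
#' A saddle-focus (complex pair with real parts of mixed sign) is folded
#' into \code{saddle}. Eigenvalues whose real part lies within
#' \code{zero_tol} of zero alongside others make the point \code{marginal}
#' (nonhyperbolic), and are not typed further.
#'
#' @param eigenvalues complex (or numeric) vector of Jacobian eigenvalues.
#' @param zero_tol threshold below which a real (or imaginary) part is
#'   treated as zero; default \code{1e-9}.
#' @return an object of class \code{"stability_class"}: list with
#'   \code{label} (one of \code{stable_node}, \code{unstable_node},
#'   \code{saddle}, \code{stable_spiral}, \code{unstable_spiral},
#'   \code{center}, \code{marginal}), \code{is_stable}, and \code{method}.
#' @examples
#' classify_eigenvalues(c(-1, -2))                   # stable node
#' classify_eigenvalues(c(-0.5 + 1.2i, -0.5 - 1.2i)) # stable spiral
#' classify_eigenvalues(c(1i, -1i))                  # center
#' @export
classify_eigenvalues <- function(eigenvalues, zero_tol = 1e-9) {
  stopifnot(length(eigenvalues) > 0)
  ev <- as.complex(eigenvalues)
  re <- Re(ev)
  has_complex <- any(abs(Im(ev)) > zero_tol)
  all_zero <- all(abs(re) <= zero_tol)
  label <-
    if (all_zero) {
      if (has_complex) "center" else "marginal"
    } else if (any(abs(re) <= zero_tol)) {
      "marginal"
    } else if (!has_complex) {
      if (all(re < 0)) "stable_node"
      else if (all(re > 0)) "unstable_node"
      else "saddle"
    } else {
      if (all(re < 0)) "stable_spiral"
      else if (all(re > 0)) "unstable_spiral"
      else "saddle"  # saddle-focus folded into saddle
    }
  new_stability(label, method = "eigenvalue")
}

new_stability <- function(label, method, extra = list()) {
  structure(c(list(label = label,
                   is_stable = label %in% c("stable_node", "stable_spiral"),
                   method = method), extra),
            class = "stability_class")
}

#' @export
print.stability_class <- function(x, ...) {
  cat(sprintf("<stability: %s (%s method)%s>\n",
              if (is.na(x$label)) if (x$is_stable) "stable" else "unstable"
              else x$label,
              x$method,
              if (!is.na(x$label)) paste0(", ",
                if (x$is_stable) "stable" else "not stable") else ""))
  invisible(x)
}

#' Display label for a stability class
#'
#' Formats a \code{stability_class} the way fixed-point tables print it:
#' typed labels for stable points (\code{"Stable node"},
#' \code{"Stable spiral"}), the aggregate \code{"Unstable"} otherwise
#' (unless \code{typed = TRUE}), and \code{"Center"}/\code{"Marginal"} for
#' nonhyperbolic spectra.
#'
#' @param x a \code{stability_class}.
#' @param typed if \code{TRUE}, unstable points keep their type
#'   (e.g. \code{"Saddle"}) rather than the aggregate \code{"Unstable"}.
#' @return a character label.
#' @export
stability_label <- function(x, typed = FALSE) {
  stopifnot(inherits(x, "stability_class"))
  lab <- c(stable_node = "Stable node", stable_spiral = "Stable spiral",
           unstable_node = "Unstable node", unstable_spiral = "Unstable spiral",
           saddle = "Saddle", center = "Center", marginal = "Marginal")
  if (is.na(x$label)) return(if (x$is_stable) "Stable" else "Unstable")
  if (!typed && x$label %in% c("unstable_node", "unstable_spiral", "saddle"))
    return("Unstable")
  unname(lab[x$label])
}

#' Routh-Hurwitz stability test
#'
#' Decides whether every root of a real polynomial has strictly negative
#' real part, using the Hurwitz determinant sequence on the coefficients --
#' no root extraction is performed.
#'
#' @param coeffs real polynomial coefficients in descending degree order,
#'   leading coefficient first (it must be nonzero; a negative leading
#'   coefficient is normalised away).
#' @return \code{TRUE} iff all roots lie strictly in the left half-plane.
#' @examples
#' routh_hurwitz_stable(c(1, 3, 2))  # lambda^2 + 3 lambda + 2: roots -1, -2
#' routh_hurwitz_stable(c(1, 0, -1)) # lambda^2 - 1: root at +1
#' @export
routh_hurwitz_stable <- function(coeffs) {
  coeffs <- as.numeric(coeffs)
  if (length(coeffs) < 2L) stop("polynomial must have degree >= 1", call. = FALSE)
  if (coeffs[1] == 0) stop("zero leading coefficient", call. = FALSE)
  a <- coeffs / coeffs[1]
  n <- length(a) - 1L
  # necessary condition: all coefficients strictly positive
  if (any(a <= 0)) return(FALSE)
  # Hurwitz matrix H[i, j] = a_{2j - i} (a_0 = 1, a_k = 0 outside range)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    k <- 2L * j - i
    if (k >= 0L && k <= n) H[i, j] <- a[k + 1L]
  }
  minors <- vapply(seq_len(n),
                   function(k) det(H[seq_len(k), seq_len(k), drop = FALSE]),
                   numeric(1))
  all(minors > 0)
}

#' Perturbation-based linear stability check
#'
#' Implements the simulation route to stability: the fixed point is
#' displaced by a small random perturbation restricted to the nonnegative
#' orthant, the system is integrated over a horizon, and the point is
#' declared stable when the trajectory has returned to within \code{eps}
#' of it. Only a stable/unstable verdict is produced (no node/spiral type).
#'
#' @param motif a \code{\link{build_motif}} object.
#' @param state fixed-point state vector (or a row of
#'   \code{\link{fixed_points}} output).
#' @param q perturbation magnitude; default
#'   \code{1e-3 * max(1, norm(state))}.
#' @param horizon integration horizon in days (default 200).
#' @param eps return tolerance on the Euclidean distance (default
#'   \code{1e-4}).
#' @param seed seed for the random perturbation direction (default 1).
#' @param settings optional \code{\link{solver_settings}}.
#' @return a \code{stability_class} with \code{label = NA}, the verdict in
#'   \code{is_stable}, and the terminal distance in \code{distance}; if the
#'   integration fails the verdict is \code{NA} (classification "unknown").
#' @export
classify_perturbation <- function(motif, state, q = NULL, horizon = 200,
                                  eps = 1e-4, seed = 1, settings = NULL) {
  stopifnot(inherits(motif, "motif"))
  state <- as.numeric(state)
  if (is.null(q)) q <- 1e-3 * max(1, sqrt(sum(state^2)))
  if (!(q > 0)) stop("'q' must be strictly positive", call. = FALSE)
  if (is.null(settings)) settings <- solver_settings(t_end = horizon)
  settings$t_end <- horizon
  u <- with_seed(seed, {
    v <- abs(stats::rnorm(length(state)))
    v / sqrt(sum(v^2))
  })
  x0 <- pmax(state + q * u, 0)
  traj <- integrate_motif(motif, x0, settings,
                          times = c(0, horizon))
  if (!traj$success)
    return(new_stability(NA_character_, "perturbation",
                         list(is_stable = NA, distance = NA_real_,
                              diagnostics = traj$diagnostics)))
  xe <- traj$states[nrow(traj$states), ]
  d <- sqrt(sum((xe - state)^2))
  out <- new_stability(NA_character_, "perturbation", list(distance = d))
  out$is_stable <- d < eps
  out
}

# evaluate an expression under a temporary RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
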