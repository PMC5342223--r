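#' Solver settings for motif integration
#'
#' @param method \code{"stiff"} (default; backward-differentiation via
#'   \code{deSolve}) or \code{"nonstiff"} (Adams).
#' @param atol absolute error tolerance (default \code{1e-6}).
#' @param rtol relative error tolerance (default \code{1e-3}).
#' @param t_end integration horizon in days (default 100).
#' @param use_analytic_jacobian supply the motif's analytic Jacobian to the
#'   stiff solver when available (default \code{TRUE}).
#' @return an object of class \code{"solver_settings"}.
#' @export
solver_settings <- function(method = c("stiff", "nonstiff"),
                            atol = 1e-6, rtol = 1e-3, t_end = 100,
                            use_analytic_jacobian = TRUE) {
  method <- match.arg(method)
  stopifnot(atol > 0, rtol > 0, t_end > 0)
  structure(list(method = method, atol = atol, rtol = rtol, t_end = t_end,
                 use_analytic_jacobian = use_analytic_jacobian),
            class = "solver_settings")
}

#' Integrate a motif trajectory
#'
#' Solves the motif ODE system from an initial state over \code{[0, t_end]}.
#' The state passed to the kinetic terms is clipped at zero inside the
#' derivative function, so small solver excursions below zero (within the
#' error tolerance) cannot destabilise the rational kinetics; the reported
#' states are the solver's own.
#'
#' @param motif a \code{\link{build_motif}} object.
#' @param x0 nonnegative initial state, length \code{motif$n_states}.
#' @param settings a \code{\link{solver_settings}} object.
#' @param times optional explicit output times (default: 501 equispaced
#'   points over \code{[0, t_end]}).
#' @return an object of class \code{"motif_trajectory"}: list with
#'   \code{times}, \code{states} (matrix, one row per time), \code{x0},
#'   \code{settings}, \code{success}, and solver \code{diagnostics}.
#' @export
integrate_motif <- function(motif, x0, settings = solver_settings(),
                            times = NULL) {
  stopifnot(inherits(motif, "motif"), inherits(settings, "solver_settings"))
  x0 <- as.numeric(x0)
  if (length(x0) != motif$n_states)
    stop("initial state length ", length(x0),
         " does not match motif dimension ", motif$n_states, call. = FALSE)
  if (any(x0 < 0))
    stop("initial state must be nonnegative componentwise", call. = FALSE)
  if (is.null(times))
    times <- seq(0, settings$t_end, length.out = 501L)

  rhs <- motif$rhs_fn
  dfun <- function(t, y, parms) list(rhs(pmax(y, 0)))
  jfun <- NULL
  if (settings$use_analytic_jacobian && !is.null(motif$jac_fn)) {
    jac <- motif$jac_fn
    jfun <- function(t, y, parms) jac(pmax(y, 0))
  }
  method <- if (settings$method == "stiff") "bdf" else "adams"

  out <- tryCatch(
    deSolve::ode(y = x0, times = times, func = dfun, parms = NULL,
                 method = method, atol = settings$atol, rtol = settings$rtol,
                 jacfunc = jfun,
                 jactype = if (is.null(jfun)) "fullint" else "fullusr",
                 maxsteps = 20000),
    error = function(e) e, warning = function(w) w)

  if (inherits(out, "condition")) {
    return(structure(list(times = times, states = NULL, x0 = x0,
                          settings = settings, success = FALSE,
                          diagnostics = conditionMessage(out)),
                     class = "motif_trajectory"))
  }
  states <- unname(out[, -1L, drop = FALSE])
  colnames(states) <- motif$state_names
  success <- nrow(states) == length(times) && all(is.finite(states)) &&
    min(states) > -10 * max(settings$atol, settings$rtol)
  structure(list(times = out[, 1L], states = states, x0 = x0,
                 settings = settings, success = success,
                 diagnostics = if (success) "ok" else
                   "integration incomplete or state left the admissible region"),
            class = "motif_trajectory")
}

#' @export
print.motif_trajectory <- function(x, ...) {
  cat(sprintf("<motif_trajectory: %s, t in [%g, %g], %d points>\n",
              if (x$success) "ok" else "FAILED",
              min(x$times), max(x$times),
              if (is.null(x$states)) 0L else nrow(x$states)))
  if (x$success) {
    cat("final state:\n")
    print(signif(x$states[nrow(x$states), ], 4))
  }
  invisible(x)
}

#' @export
as.data.frame.motif_trajectory <- function(x, ...) {
  stopifnot(x$success)
  data.frame(time = x$times, x$states, check.names = FALSE)
}

#' @export
plot.motif_trajectory <- function(x, log = "", ...) {
  stopifnot(x$success)
  graphics::matplot(x$times, x$states, type = "l", lty = 1,
                    xlab = "time (days)", ylab = "concentration", log = log, ...)
  graphics::legend("topright", legend = colnames(x$states),
                   col = seq_len(ncol(x$states)), lty = 1, bty = "n")
  invisible(x)
}

#' Time at which a trajectory settles into its final state
#'
#' Returns the earliest time \code{t*} such that every state component stays
#' within a relative band (with an absolute floor) of its value at the final
#' time for all \code{t >= t*}; \code{NA} if no such time exists before the
#' end of the trajectory (i.e. the final point alone is in-band, which is
#' reported as \code{NA} only when even the penultimate point is outside).
#'
#' @param traj a successful \code{\link{integrate_motif}} trajectory.
#' @param rel_band relative settling band (default 0.01, i.e. 1\%).
#' @param abs_floor absolute tolerance floor; default: the trajectory's
#'   solver \code{atol}.
#' @return settling time (same units as \code{traj$times}), or \code{NA}.
#' @export
settling_time <- function(traj, rel_band = 0.01, abs_floor = NULL) {
  stopifnot(inherits(traj, "motif_trajectory"), traj$success)
  if (is.null(abs_floor)) abs_floor <- traj$settings$atol
  S <- traj$states
  final <- S[nrow(S), ]
  tol <- pmax(rel_band * abs(final), abs_floor)
  inband <- sweep(abs(sweep(S, 2L, final)), 2L, tol, "<=")
  ok <- apply(inband, 1L, all)
  bad <- which(!ok)                 # rows outside the band
  if (length(bad) == 0L) return(traj$times[1L])
  if (max(bad) >= nrow(S) - 1L) return(NA_real_)  # never settles before t_end
  traj$times[max(bad) + 1L]
}

#' Phase-portrait trajectory bundle
#'
#' Integrates the motif from a grid of initial conditions obtained by
#' varying two or three state components over ranges \code{a..b} in steps
#' \code{s} (row-major order of the varied indices), holding the remaining
#' components fixed.
#'
#' @param motif a \code{\link{build_motif}} object.
#' @param varied state names or indices to vary (length 2 or 3).
#' @param ranges list (per varied state) of \code{c(a, b, s)}: lower bound,
#'   upper bound, step.
#' @param fixed_x0 full-length state vector supplying the unvaried
#'   components (values at varied positions are overwritten).
#' @param settings a \code{\link{solver_settings}}.
#' @return an object of class \code{"motif_portrait"}: list of trajectories
#'   plus the grid of initial conditions; failed integrations are kept and
#'   flagged, they do not abort the bundle.
#' @export
phase_portrait <- function(motif, varied, ranges, fixed_x0,
                           settings = solver_settings()) {
  stopifnot(inherits(motif, "motif"))
  if (is.character(varied)) varied <- match(varied, motif$state_names)
  stopifnot(length(varied) %in% 2:3, !anyNA(varied),
            length(ranges) == length(varied))
  axes <- lapply(ranges, function(r) {
    stopifnot(length(r) == 3L, r[1] <= r[2], r[3] > 0)
    seq(r[1], r[2], by = r[3])
  })
  # row-major: last axis varies fastest
  grid <- expand.grid(rev(axes))[, rev(seq_along(axes)), drop = FALSE]
  names(grid) <- motif$state_names[varied]
  trajs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    x0 <- as.numeric(fixed_x0)
    x0[varied] <- as.numeric(grid[i, ])
    trajs[[i]] <- integrate_motif(motif, x0, settings)
  }
  structure(list(trajectories = trajs, grid = grid, varied = varied,
                 motif_name = motif$name),
            class = "motif_portrait")
}

#' @export
print.motif_portrait <- function(x, ...) {
  nfail <- sum(!vapply(x$trajectories, `[[`, logical(1), "success"))
  cat(sprintf("<motif_portrait: %d trajectories (%d failed) over %s>\n",
              length(x$trajectories), nfail,
              paste(names(x$grid), collapse = " x ")))
  invisible(x)
}

#' @export
plot.motif_portrait <- function(x, dims = x$varied[1:2], ...) {
  okt <- Filter(function(tr) tr$success, x$trajectories)
  stopifnot(length(okt) > 0)
  rng <- function(k) range(unlist(lapply(okt, function(tr) tr$states[, k])))
  plot(NA, xlim = rng(dims[1]), ylim = rng(dims[2]),
       xlab = colnames(okt[[1]]$states)[dims[1]],
       ylab = colnames(okt[[1]]$states)[dims[2]], ...)
  for (tr in okt) graphics::lines(tr$states[, dims[1]], tr$states[, dims[2]],
                                  col = grDevices::grey(0.4))
  invisible(x)
}

#' Export a trajectory to CSV
#'
#' Writes a tidy table (time, one column per state) and, alongside it, a
#' JSON metadata file with the solver settings and initial conditions.
#'
#' @param traj a successful trajectory.
#' @param path output CSV path.
#' @param digits significant digits used in formatting (default 6).
#' @return invisibly, the paths written.
#' @export
export_trajectory <- function(traj, path, digits = 6) {
  df <- as.data.frame(traj)
  df[] <- lapply(df, format_sci, digits = digits)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(initial_conditions = traj$x0,
               settings = unclass(traj$settings),
               success = traj$success)
  mpath <- sub("\\.csv$", "_meta.json", path)
  jsonlite::write_json(meta, mpath, auto_unbox = TRUE, digits = NA)
  invisible(c(path, mpath))
}

# fixed-width numeric formatting: 6 significant digits, scientific notation
# below 1e-3 (matching the fixed-point table presentation)
format_sci <- function(x, digits = 6) {
  if (!is.numeric(x)) return(as.character(x))
  vapply(x, function(v) {
    if (!is.finite(v)) return(as.character(v))
    if (v != 0 && abs(v) < 1e-3) sprintf("%.*e", digits - 1L, v)
    else formatC(signif(v, digits), digits = digits, format = "g")
  }, character(1))
}
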