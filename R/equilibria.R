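#' Characteristic polynomial coefficients of a matrix
#'
#' Computes the coefficients of \code{det(lambda I - A)} in descending
#' degree order (leading coefficient 1) by the Faddeev-LeVerrier recursion.
#'
#' @param A a square numeric matrix.
#' @return numeric vector of length \code{nrow(A) + 1}.
#' @export
char_poly <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  n <- nrow(A)
  co <- numeric(n + 1L); co[1L] <- 1
  M <- matrix(0, n, n)
  for (k in seq_len(n)) {
    M <- A %*% M + diag(co[k], n)
    co[k + 1L] <- -sum(diag(A %*% M)) / k
  }
  co
}

#' Jacobian and spectrum at a state
#'
#' Evaluates the motif Jacobian at a (fixed-point) state and returns both
#' its spectrum and the characteristic-polynomial coefficients. Two spectrum
#' estimators are available: \code{"direct"} (the default) uses dense
#' eigendecomposition, which is backward stable; \code{"charpoly"} extracts
#' the eigenvalues as roots of the characteristic polynomial, the route the
#' single-point analysis algorithm historically prescribes. The polynomial
#' route is reliable only for spectra of moderate dynamic range: on stiff
#' chemostat fixed points whose eigenvalues span several orders of
#' magnitude, the coefficient representation destroys the small eigenvalues
#' (their sign can flip), and at defective points with repeated eigenvalues
#' (e.g. total washout, where the Jacobian is diagonal with multiplicities)
#' it splits repeated real roots into tight complex clusters -- both visible
#' in the stability label (see the package vignette).
#'
#' @param motif a \code{\link{build_motif}} object.
#' @param state state vector at which to evaluate.
#' @param spectrum \code{"direct"} or \code{"charpoly"}.
#' @return list with \code{jacobian}, \code{eigenvalues} (complex),
#'   \code{char_poly} (descending coefficients), and \code{spectrum} (the
#'   estimator used).
#' @export
jacobian_at <- function(motif, state, spectrum = c("direct", "charpoly")) {
  spectrum <- match.arg(spectrum)
  J <- motif_jacobian(motif, state)
  co <- char_poly(J)
  ev <- if (spectrum == "charpoly") sort_complex(polyroot(rev(co)))
        else sort_complex(eigen(J, only.values = TRUE)$values)
  list(jacobian = J, eigenvalues = ev, char_poly = co, spectrum = spectrum)
}

sort_complex <- function(z) {
  z <- as.complex(z)
  z[order(Re(z), Im(z))]
}

# Damped (backtracking line-search) Newton iteration for F(x) = 0 restricted
# to the coordinates in `active`; inactive coordinates are pinned at their
# value in `x0` (zero biomass subsets). Active biomass coordinates
# (`bio_active`) are iterated in log space, so each washout subset converges
# only to roots with its "on" biomasses strictly positive -- boundary roots
# belong to smaller subsets and are never rediscovered here. Returns the
# full-length root or NULL.
newton_root <- function(rhs, jac, x0, active, bio_active = integer(0),
                        tol = 1e-12, maxit = 80L) {
  is_log <- active %in% bio_active
  to_x <- function(u) { v <- u; v[is_log] <- exp(u[is_log]); v }
  x <- x0
  u <- x[active]
  if (any(u[is_log] <= 0)) return(NULL)
  u[is_log] <- log(u[is_log])
  for (it in seq_len(maxit)) {
    x[active] <- to_x(u)
    Fx <- rhs(x)
    if (!all(is.finite(Fx))) return(NULL)
    fa <- Fx[active]
    nf <- sqrt(sum(fa^2))
    if (nf < tol * max(1, sqrt(sum(x^2)))) return(x)
    Ja <- jac(x)[active, active, drop = FALSE]
    # chain rule for the log-parametrised columns: dF/du = dF/dX * X
    if (any(is_log))
      Ja[, is_log] <- Ja[, is_log, drop = FALSE] *
        rep(x[active][is_log], each = nrow(Ja))
    du <- tryCatch(solve(Ja, -fa), error = function(e) NULL)
    if (is.null(du) || !all(is.finite(du))) {
      # near-singular Jacobian (e.g. close to a fold): take a regularised
      # Gauss-Newton (Levenberg-Marquardt) step instead of giving up
      A <- crossprod(Ja)
      lam <- 1e-8 * max(diag(A), 1e-300)
      du <- tryCatch(solve(A + diag(lam, nrow(A)), -crossprod(Ja, fa)),
                     error = function(e) NULL)
      if (is.null(du) || !all(is.finite(du))) return(NULL)
      du <- as.numeric(du)
    }
    step <- 1
    repeat {
      un <- u + step * du
      # a biomass collapsing to 0 or blowing up: no interior root this way
      if (any(un[is_log] < -60) || any(un[is_log] > 60)) return(NULL)
      xn <- x
      xn[active] <- to_x(un)
      Fn <- rhs(xn)
      if (all(is.finite(Fn)) && sqrt(sum(Fn[active]^2)) < nf) { u <- un; break }
      step <- step / 2
      if (step < 1e-10) return(NULL)
    }
  }
  NULL
}

#' Enumerate the nonnegative fixed points of a motif
#'
#' Systematically enumerates equilibria by exploiting the washout structure
#' of chemostat models: every equilibrium has some subset of biomasses
#' exactly zero. For each of the \code{2^k} biomass on/off subsets the
#' reduced algebraic system is solved by damped-Newton iteration from
#' \code{n_starts} multistart points (log-uniform over
#' \code{[1e-8, 10 * max(S_in)]} per unknown, seeded); converged nonnegative
#' roots are kept, de-duplicated, and sorted by survivor-pattern cardinality
#' then lexicographically by state. The total-washout point (substrates at
#' inflow, all biomasses zero) is always included exactly. Each point is
#' classified by \code{\link{classify_eigenvalues}} on the spectrum from
#' \code{\link{jacobian_at}}.
#'
#' Components in \code{(-1e-10, 0)} are snapped to zero; a biomass is
#' counted as a survivor when it exceeds \code{1e-6 * max(1, max(S_in))}.
#' Subsets where no start converges are recorded in
#' \code{attr(, "unconverged_subsets")} (such subsets may genuinely carry no
#' equilibrium).
#'
#' @param motif a \code{\link{build_motif}} object.
#' @param n_starts multistart count per biomass subset (default 200; chosen
#'   so that equilibria with small Newton basins -- invasion-threshold
#'   saddles sit in basins hit by only a few percent of random starts --
#'   are still found with high probability).
#' @param seed RNG seed for the multistart cloud (default 1729).
#' @param dedup_tol relative tolerance for merging duplicate roots
#'   (default \code{1e-6}).
#' @param spectrum spectrum estimator passed to \code{\link{jacobian_at}}.
#' @param zero_tol eigenvalue zero threshold for classification.
#' @param extra_starts optional list of full-length states used as
#'   additional deterministic Newton starts (each applied to the biomass
#'   subset given by its own positive-biomass pattern); parameter sweeps
#'   pass neighbouring-cell roots here so equilibria are continued across
#'   the grid.
#' @return an object of class \code{"motif_fps"}: a list of fixed points,
#'   each with \code{state}, \code{residual_norm}, \code{eigenvalues},
#'   \code{char_poly}, \code{stability} and \code{survivors}, plus the
#'   assigned steady-state ids (\code{ss_id}; points sharing a survivor
#'   pattern share an id).
#' @examples
#' m <- build_motif("no_common_metabolites",
#'   params = list(D = 0.1, S1_in = 2, S2_in = 3, Y1 = 0.2, Y2 = 0.3,
#'                 kdec1 = 0, kdec2 = 0, km1 = 2, KS1 = 0.5, km2 = 3,
#'                 KS2 = 0.4))
#' fixed_points(m, n_starts = 20)
#' @export
fixed_points <- function(motif, n_starts = 200L, seed = 1729L,
                         dedup_tol = 1e-6, spectrum = c("direct", "charpoly"),
                         zero_tol = 1e-9, extra_starts = NULL) {
  stopifnot(inherits(motif, "motif"))
  spectrum <- match.arg(spectrum)
  n <- motif$n_states
  bio <- motif$biomass_idx
  k <- length(bio)
  smax <- max(1, unlist(motif$params[grep("_in$", names(motif$params))]), 0)
  rhs <- motif$rhs_fn
  jfast <- motif$jac_fn
  jac <- if (!is.null(jfast)) jfast else
    function(x) fd_jacobian(rhs, x)

  roots <- list(washout_state(motif))
  root_masks <- 0L
  unconverged <- character(0)
  masks <- order(vapply(seq_len(2^k - 1L), popcount, integer(1)))
  for (mask in masks) {
    on <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0)
    active <- sort(c(motif$substrate_idx, bio[on]))
    # warm starts: every root already found for a biomass sub-subset, with
    # the newly active biomasses set to a small invading inoculum and the
    # subset-reduced dynamics relaxed for a short transient before Newton
    # polishing (the succession structure of chemostat equilibria: states
    # with one more survivor are reached by invasion of those they
    # destabilise; off-subset biomasses stay exactly zero under the flow)
    warm <- list()
    for (j in seq_along(roots)) {
      if (bitwAnd(root_masks[j], mask) != root_masks[j] ||
          root_masks[j] == mask) next
      for (inoc in c(1e-5, 1e-2) * smax) {
        w <- roots[[j]]
        newbio <- setdiff(bio[on], bio[as.logical(
          bitwAnd(root_masks[j], 2^(seq_len(k) - 1L)) > 0)])
        w[newbio] <- inoc
        w[active] <- pmax(w[active], 1e-10)
        warm[[length(warm) + 1L]] <- w
        warm[[length(warm) + 1L]] <- relax_state(rhs, w, jac = jfast)
      }
    }
    if (!is.null(extra_starts)) for (s_ in extra_starts) {
      smask <- sum(2^(which(s_[bio] > 0) - 1L))
      if (smask == mask) {
        w <- s_
        w[active] <- pmax(w[active], 1e-12)
        warm[[length(warm) + 1L]] <- w
      }
    }
    # chained seeding: subset mask offsets the stream so that increasing
    # n_starts never changes earlier start points
    starts <- with_seed(seed + mask, {
      matrix(exp(stats::runif(n_starts * length(active),
                              log(1e-8), log(10 * smax))),
             nrow = n_starts)
    })
    rand <- lapply(seq_len(n_starts), function(s) {
      x0 <- numeric(n)
      x0[active] <- starts[s, ]
      x0
    })
    found_any <- FALSE
    for (x0 in c(warm, rand)) {
      r <- newton_root(rhs, jac, x0, active, bio_active = bio[on])
      if (is.null(r)) next
      if (any(r < -1e-10)) next
      r[r < 0] <- 0
      found_any <- TRUE
      dup <- any(vapply(roots, function(q)
        all(abs(q - r) <= dedup_tol * pmax(abs(q), 1)), logical(1)))
      if (!dup) {
        roots[[length(roots) + 1L]] <- r
        rmask <- sum(2^(which(r[bio] > 0) - 1L))
        root_masks <- c(root_masks, as.integer(rmask))
      }
    }
    if (!found_any)
      unconverged <- c(unconverged,
                       paste(motif$state_names[bio[on]], collapse = "+"))
  }

  surv_thresh <- 1e-6 * smax
  fps <- lapply(roots, function(r) {
    res <- sqrt(sum(rhs(r)^2))
    ja <- jacobian_at(motif, r, spectrum)
    surv <- motif$state_names[bio][r[bio] > surv_thresh]
    list(state = stats::setNames(r, motif$state_names),
         residual_norm = res,
         eigenvalues = ja$eigenvalues, char_poly = ja$char_poly,
         stability = classify_eigenvalues(ja$eigenvalues, zero_tol),
         survivors = surv)
  })
  # sort by survivor cardinality, then lexicographically by state
  ord <- order_fps(fps)
  fps <- fps[ord]
  # steady-state ids by survivor pattern (washout pattern is SS1)
  pats <- vapply(fps, function(f) paste(f$survivors, collapse = "+"), "")
  upat <- unique(pats)   # fps already sorted, so patterns appear in order
  ss <- match(pats, upat)
  for (i in seq_along(fps)) {
    fps[[i]]$fp_id <- paste0("FP", i)
    fps[[i]]$ss_id <- paste0("SS", ss[i])
  }
  structure(fps, class = "motif_fps", motif_name = motif$name,
            unconverged_subsets = unconverged, spectrum = spectrum)
}

popcount <- function(x) sum(bitwAnd(x, 2^(0:29)) > 0)

# short transient relaxation used to seed Newton from invasion states
relax_state <- function(rhs, x0, t_relax = 250, jac = NULL) {
  out <- tryCatch(
    deSolve::ode(y = pmax(x0, 0), times = c(0, t_relax),
                 func = function(t, y, p) list(rhs(pmax(y, 0))),
                 parms = NULL, method = "bdf", atol = 1e-8, rtol = 1e-6,
                 jacfunc = if (!is.null(jac))
                   function(t, y, p) jac(pmax(y, 0)),
                 jactype = if (is.null(jac)) "fullint" else "fullusr",
                 maxsteps = 3000),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(out) || nrow(out) < 2L) return(x0)
  pmax(out[nrow(out), -1L], 0)
}

order_fps <- function(fps) {
  card <- vapply(fps, function(f) length(f$survivors), integer(1))
  states <- do.call(rbind, lapply(fps, `[[`, "state"))
  do.call(order, c(list(card), lapply(seq_len(ncol(states)),
                                      function(j) states[, j])))
}

#' @export
print.motif_fps <- function(x, ...) {
  cat(sprintf("<motif_fps: %d nonnegative fixed point(s) of '%s'>\n",
              length(x), attr(x, "motif_name")))
  print(as.data.frame(x), digits = 3)
  uc <- attr(x, "unconverged_subsets")
  if (length(uc))
    cat("no root found for biomass subset(s):", paste(uc, collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.motif_fps <- function(x, ..., typed = TRUE) {
  states <- do.call(rbind, lapply(x, `[[`, "state"))
  data.frame(fixed_point = vapply(x, `[[`, "", "fp_id"),
             steady_state = vapply(x, `[[`, "", "ss_id"),
             states,
             residual = vapply(x, `[[`, numeric(1), "residual_norm"),
             stability = vapply(x, function(f)
               stability_label(f$stability, typed = typed), ""),
             row.names = NULL, check.names = FALSE)
}

#' Export a fixed-point table to CSV
#'
#' One row per fixed point: state components, residual norm, eigenvalues
#' (semicolon-separated complex values) and the stability label.
#'
#' @param fps a \code{\link{fixed_points}} object.
#' @param path output CSV path.
#' @param typed keep typed labels for unstable points (default \code{FALSE}:
#'   print the aggregate \code{"Unstable"}).
#' @param digits significant digits (default 6).
#' @return invisibly, \code{path}.
#' @export
export_fixed_points <- function(fps, path, typed = FALSE, digits = 6) {
  df <- as.data.frame(fps, typed = typed)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], format_sci, digits = digits)
  df$eigenvalues <- vapply(fps, function(f)
    paste(format(f$eigenvalues, digits = 6), collapse = ";"), "")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
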