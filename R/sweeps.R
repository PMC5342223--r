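#' Two-parameter grid specification
#'
#' @param name parameter (or state) identifier.
#' @param from,to range endpoints, \code{from <= to}.
#' @param step step size, > 0. The axis has
#'   \code{floor((to - from)/step) + 1} points.
#' @return a \code{"grid_axis"} object.
#' @export
grid_axis <- function(name, from, to, step) {
  stopifnot(is.character(name), length(name) == 1L, from <= to, step > 0)
  structure(list(name = name, from = from, to = to, step = step,
                 points = seq(from, to, by = step)),
            class = "grid_axis")
}

#' Operating diagram: steady-state existence and stability over a parameter plane
#'
#' For every point of a 2-D grid over two motif parameters, enumerates the
#' nonnegative fixed points, classifies their stability, identifies steady
#' states by their positive-biomass pattern, and labels the grid cell by the
#' combination of (steady state, stability) pairs present. Cells sharing a
#' combination share a region id; regions are numbered \code{J1, J2, ...}
#' by first appearance in row-major order (axis 1 outer, axis 2 inner).
#'
#' @param motif a \code{\link{build_motif}} object.
#' @param axis1,axis2 \code{\link{grid_axis}} objects over valid parameter
#'   names with nonnegative ranges.
#' @param n_starts,seed multistart options passed to
#'   \code{\link{fixed_points}}.
#' @param spectrum spectrum estimator (see \code{\link{jacobian_at}}).
#' @param progress print percent-complete lines (default \code{FALSE}).
#' @return an object of class \code{"region_map"}: data frame \code{cells}
#'   (axis values, cell signature, region label), \code{legend} mapping each
#'   region to its steady-state/stability combination, and the axes.
#' @export
operating_diagram <- function(motif, axis1, axis2, n_starts = 200L,
                              seed = 1729L, spectrum = "direct",
                              progress = FALSE) {
  stopifnot(inherits(motif, "motif"),
            inherits(axis1, "grid_axis"), inherits(axis2, "grid_axis"))
  for (ax in list(axis1, axis2)) {
    if (!ax$name %in% names(motif$params))
      stop("'", ax$name, "' is not a parameter of this motif", call. = FALSE)
    if (ax$from < 0)
      stop("parameter range for '", ax$name, "' must be nonnegative",
           call. = FALSE)
  }
  p1 <- axis1$points; p2 <- axis2$points
  ncell <- length(p1) * length(p2)
  sig <- character(ncell); ok <- logical(ncell)
  v1 <- numeric(ncell); v2 <- numeric(ncell)
  cell <- 0L; last_pct <- -1L
  # continuation: roots found in the previous cell and in the same column
  # of the previous row seed the next enumeration, so equilibria are
  # followed smoothly across the grid
  row_roots <- vector("list", length(p2))
  prev_roots <- NULL
  for (i1 in seq_along(p1)) for (i2 in seq_along(p2)) {
    a <- p1[i1]; b <- p2[i2]
    cell <- cell + 1L
    v1[cell] <- a; v2[cell] <- b
    m <- set_params(motif, stats::setNames(list(a, b),
                                           c(axis1$name, axis2$name)))
    extra <- c(if (i2 > 1L) prev_roots, row_roots[[i2]])
    fps <- tryCatch(fixed_points(m, n_starts = n_starts, seed = seed,
                                 spectrum = spectrum,
                                 extra_starts = extra),
                    error = function(e) NULL)
    if (is.null(fps)) { sig[cell] <- "failed"; prev_roots <- NULL; next }
    ok[cell] <- TRUE
    sig[cell] <- cell_signature(fps)
    prev_roots <- lapply(fps, function(f) unname(f$state))
    row_roots[[i2]] <- prev_roots
    if (progress) {
      pct <- floor(100 * cell / ncell)
      if (pct > last_pct) { message(sprintf("sweep: %d%%", pct)); last_pct <- pct }
    }
  }
  usig <- unique(sig[ok])           # first-appearance order, row-major
  region <- ifelse(ok, paste0("J", match(sig, usig)), "failed")
  cells <- data.frame(v1, v2, signature = sig, region = region)
  names(cells)[1:2] <- c(axis1$name, axis2$name)
  legend <- stats::setNames(usig, paste0("J", seq_along(usig)))
  structure(list(cells = cells, legend = legend, axis1 = axis1, axis2 = axis2,
                 motif_name = motif$name),
            class = "region_map")
}

# canonical signature: per steady state, the multiset of stability verdicts
# of its fixed points, e.g. "SS1:stable|SS2:stable+unstable|SS3:stable"
cell_signature <- function(fps) {
  ss <- vapply(fps, `[[`, "", "ss_id")
  st <- vapply(fps, function(f)
    if (f$stability$is_stable) "stable" else "unstable", "")
  parts <- vapply(split(st, ss), function(v)
    paste(sort(v), collapse = "+"), "")
  paste(paste0(names(parts), ":", parts), collapse = "|")
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("<region_map: '%s' over (%s, %s), %d cells, %d region(s)>\n",
              x$motif_name, x$axis1$name, x$axis2$name, nrow(x$cells),
              length(x$legend)))
  for (j in names(x$legend)) cat(sprintf("  %s = %s\n", j, x$legend[[j]]))
  invisible(x)
}

#' @export
plot.region_map <- function(x, ...) {
  z <- matrix(match(x$cells$region, names(x$legend)),
              nrow = length(x$axis1$points), byrow = TRUE)
  graphics::image(x$axis1$points, x$axis2$points, z,
                  xlab = x$axis1$name, ylab = x$axis2$name, ...)
  invisible(x)
}

#' Basin of attraction over two initial conditions
#'
#' Integrates the motif to a long horizon from every point of a 2-D grid of
#' initial conditions over two state variables (the remaining components
#' held at \code{fixed_ics}), and labels each cell by the enumerated fixed
#' point nearest to the trajectory endpoint -- provided the distance is
#' below \code{eps}, else \code{"none"}. Failed integrations are labelled
#' \code{"failed"} without aborting the map.
#'
#' @param motif a \code{\link{build_motif}} object.
#' @param axis1,axis2 \code{\link{grid_axis}} objects over state names.
#' @param fixed_ics full-length nonnegative state vector supplying the
#'   unswept initial conditions.
#' @param eps attractor-matching tolerance; default
#'   \code{1e-3 * max(1, norm(fp))} per fixed point.
#' @param horizon integration horizon in days (default 1000; basin cells
#'   near saddles converge slowly).
#' @param settings \code{\link{solver_settings}} for the cell integrations.
#' @param fps optionally, a precomputed \code{\link{fixed_points}} object.
#' @param progress print percent-complete lines.
#' @return an object of class \code{"basin_map"}: data frame \code{cells}
#'   with the two ICs, the matched fixed-point id, steady-state id and
#'   distance; plus the fixed points used.
#' @export
basin_of_attraction <- function(motif, axis1, axis2, fixed_ics, eps = NULL,
                                horizon = 1000, settings = solver_settings(),
                                fps = NULL, progress = FALSE) {
  stopifnot(inherits(motif, "motif"),
            inherits(axis1, "grid_axis"), inherits(axis2, "grid_axis"))
  i1 <- match(axis1$name, motif$state_names)
  i2 <- match(axis2$name, motif$state_names)
  if (anyNA(c(i1, i2)))
    stop("basin axes must be state variables of the motif", call. = FALSE)
  stopifnot(all(fixed_ics >= 0), length(fixed_ics) == motif$n_states)
  if (is.null(fps)) fps <- fixed_points(motif)
  fpstates <- lapply(fps, `[[`, "state")
  fpeps <- if (is.null(eps))
    vapply(fpstates, function(s) 1e-3 * max(1, sqrt(sum(s^2))), numeric(1))
  else rep_len(eps, length(fpstates))
  settings$t_end <- horizon

  p1 <- axis1$points; p2 <- axis2$points
  ncell <- length(p1) * length(p2)
  lab <- character(ncell); ss <- character(ncell); dist <- numeric(ncell)
  v1 <- numeric(ncell); v2 <- numeric(ncell)
  cell <- 0L; last_pct <- -1L
  for (a in p1) for (b in p2) {
    cell <- cell + 1L
    v1[cell] <- a; v2[cell] <- b
    x0 <- as.numeric(fixed_ics)
    x0[c(i1, i2)] <- c(a, b)
    traj <- integrate_motif(motif, x0, settings, times = c(0, horizon))
    if (!traj$success) { lab[cell] <- "failed"; ss[cell] <- "failed"; next }
    xe <- traj$states[nrow(traj$states), ]
    d <- vapply(fpstates, function(s) sqrt(sum((xe - s)^2)), numeric(1))
    j <- which.min(d)
    dist[cell] <- d[j]
    if (d[j] < fpeps[j]) {
      lab[cell] <- fps[[j]]$fp_id; ss[cell] <- fps[[j]]$ss_id
    } else {
      lab[cell] <- "none"; ss[cell] <- "none"
    }
    if (progress) {
      pct <- floor(100 * cell / ncell)
      if (pct > last_pct) { message(sprintf("basin: %d%%", pct)); last_pct <- pct }
    }
  }
  cells <- data.frame(v1, v2, fixed_point = lab, steady_state = ss,
                      distance = dist)
  names(cells)[1:2] <- c(axis1$name, axis2$name)
  structure(list(cells = cells, fixed_points = fps, axis1 = axis1,
                 axis2 = axis2, fixed_ics = fixed_ics, horizon = horizon,
                 motif_name = motif$name),
            class = "basin_map")
}

#' @export
print.basin_map <- function(x, ...) {
  tb <- table(x$cells$fixed_point)
  cat(sprintf("<basin_map: '%s' over (%s(0), %s(0)), %d cells>\n",
              x$motif_name, x$axis1$name, x$axis2$name, nrow(x$cells)))
  print(tb)
  invisible(x)
}

#' @export
plot.basin_map <- function(x, ...) {
  labs <- sort(unique(x$cells$fixed_point))
  z <- matrix(match(x$cells$fixed_point, labs),
              nrow = length(x$axis1$points), byrow = TRUE)
  graphics::image(x$axis1$points, x$axis2$points, z,
                  xlab = paste0(x$axis1$name, "(0)"),
                  ylab = paste0(x$axis2$name, "(0)"), ...)
  invisible(x)
}

#' Critical initial-condition ratio on a basin boundary
#'
#' Bisects along the ray \code{x_i(0)/x_j(0) = r} at fixed Euclidean norm of
#' the two swept initial conditions, refining the ratio bracket until it is
#' narrower than \code{tol}; the midpoint estimates the boundary between two
#' basins of attraction. Endpoint classification integrates to
#' \code{horizon} and assigns the nearest enumerated fixed point.
#'
#' @param motif a \code{\link{build_motif}} object.
#' @param axes length-2 character vector of state names \code{(i, j)}; the
#'   ratio is \code{i / j}.
#' @param fixed_ics full-length state vector for the unswept components.
#' @param norm Euclidean norm of the swept IC pair along the ray
#'   (default 0.1).
#' @param bracket initial ratio bracket, the two endpoints must attract to
#'   different fixed points.
#' @param tol bracket width at which bisection stops (default \code{1e-3}).
#' @param horizon,settings integration controls (defaults 1000 days, stiff).
#' @param fps optional precomputed fixed points.
#' @return the boundary ratio (bracket midpoint).
#' @export
basin_boundary_ratio <- function(motif, axes, fixed_ics, norm = 0.1,
                                 bracket = c(0.1, 10), tol = 1e-3,
                                 horizon = 1000,
                                 settings = solver_settings(), fps = NULL) {
  stopifnot(inherits(motif, "motif"), length(axes) == 2L)
  i1 <- match(axes[1], motif$state_names)
  i2 <- match(axes[2], motif$state_names)
  stopifnot(!anyNA(c(i1, i2)))
  if (is.null(fps)) fps <- fixed_points(motif)
  fpstates <- lapply(fps, `[[`, "state")
  settings$t_end <- horizon
  classify <- function(r) {
    x0 <- as.numeric(fixed_ics)
    x0[i1] <- norm * r / sqrt(1 + r^2)
    x0[i2] <- norm / sqrt(1 + r^2)
    traj <- integrate_motif(motif, x0, settings, times = c(0, horizon))
    if (!traj$success) return(NA_character_)
    xe <- traj$states[nrow(traj$states), ]
    d <- vapply(fpstates, function(s) sqrt(sum((xe - s)^2)), numeric(1))
    fps[[which.min(d)]]$fp_id
  }
  bisect_boundary(classify, bracket, tol)
}

# generic bisection on a 1-D labelled classifier; the two bracket endpoints
# must receive different labels
bisect_boundary <- function(classify, bracket, tol = 1e-3) {
  lo <- bracket[1]; hi <- bracket[2]
  stopifnot(lo < hi, tol > 0)
  llo <- classify(lo); lhi <- classify(hi)
  if (is.na(llo) || is.na(lhi))
    stop("bracket endpoint classification failed", call. = FALSE)
  if (identical(llo, lhi))
    stop("bracket endpoints attract to the same label ('", llo,
         "'): no boundary to bisect", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    lm <- classify(mid)
    if (identical(lm, lhi)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Export a region or basin map to CSV + JSON legend
#'
#' Long-format CSV (axis1, axis2, label) plus a JSON legend file.
#'
#' @param map a \code{region_map} or \code{basin_map}.
#' @param path output CSV path.
#' @param digits significant digits (default 6).
#' @return invisibly, the paths written.
#' @export
export_map <- function(map, path, digits = 6) {
  if (inherits(map, "region_map")) {
    df <- map$cells[, c(1, 2, 4)]
    names(df)[3] <- "label"
    legend <- as.list(map$legend)
  } else if (inherits(map, "basin_map")) {
    df <- map$cells[, c(1, 2, 4)]
    names(df)[3] <- "label"
    legend <- lapply(split(map$fixed_points,
                           vapply(map$fixed_points, `[[`, "", "ss_id")),
                     function(g) vapply(g, `[[`, "", "fp_id"))
  } else stop("not a region_map or basin_map", call. = FALSE)
  df[1:2] <- lapply(df[1:2], format_sci, digits = digits)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  lpath <- sub("\\.csv$", "_legend.json", path)
  jsonlite::write_json(legend, lpath, auto_unbox = TRUE, digits = NA)
  invisible(c(path, lpath))
}
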