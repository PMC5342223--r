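#' Load and validate an analysis configuration
#'
#' Reads a YAML configuration describing a motif, its parameters, the
#' analysis to run and the solver/grid options, validates it completely
#' (unknown keys are rejected by name, the motif build checks parameter
#' completeness), and fills documented defaults: Monod growth, stiff solver
#' with tolerances \code{1e-6}/\code{1e-3}, horizon 100 days, multistart
#' count 200, seed 1729.
#'
#' Top-level keys: \code{motif}, \code{analysis} (one of
#' \code{single_point}, \code{multi_point}, \code{basin}, \code{portrait},
#' \code{thermo}), \code{parameters}, \code{growth}, \code{i2},
#' \code{initial_conditions} (scalar or per-state map), \code{solver}
#' (\code{method}, \code{atol}, \code{rtol}, \code{t_end}),
#' \code{fixed_points} (\code{n_starts}, \code{seed}, \code{spectrum}),
#' \code{grid} (\code{axis1}/\code{axis2}: \code{name}, \code{from},
#' \code{to}, \code{step}), \code{basin} (\code{horizon},
#' \code{fixed_initial_conditions}, \code{eps}), \code{thermo}
#' (\code{compounds}, \code{temperature}, \code{dG0}, \code{units},
#' \code{reactants}, \code{products}, \code{activities}), \code{units},
#' \code{output_dir}, \code{seed}.
#'
#' @param path path to the YAML file.
#' @return an object of class \code{"analysis_config"}.
#' @examples
#' cfg <- load_config(system.file("extdata", "three_tier_example.yaml",
#'                                package = "motifsim"))
#' cfg$parameters$D
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- c("motif", "analysis", "parameters", "growth", "i2",
             "initial_conditions", "solver", "fixed_points", "grid", "basin",
             "thermo", "units", "output_dir", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (k in c("motif", "analysis", "parameters"))
    if (is.null(raw[[k]])) stop("config key '", k, "' is required",
                                call. = FALSE)
  if (!raw$analysis %in% c("single_point", "multi_point", "basin",
                           "portrait", "thermo"))
    stop("unknown analysis type: '", raw$analysis, "'", call. = FALSE)

  cfg <- raw
  cfg$solver <- utils::modifyList(
    list(method = "stiff", atol = 1e-6, rtol = 1e-3, t_end = 100),
    if (is.null(raw$solver)) list() else raw$solver)
  cfg$fixed_points <- utils::modifyList(
    list(n_starts = 200L, seed = 1729L, spectrum = "direct"),
    if (is.null(raw$fixed_points)) list() else raw$fixed_points)
  if (is.null(cfg$seed)) cfg$seed <- 1729L
  if (is.null(cfg$output_dir)) cfg$output_dir <- "motifsim_out"
  if (is.null(cfg$i2)) cfg$i2 <- "i3"

  # build the motif now: validates parameter completeness and positivity
  motif <- build_motif(cfg$motif, cfg$parameters,
                       growth = if (is.null(cfg$growth)) NULL
                                else unlist(cfg$growth),
                       i2 = cfg$i2)

  if (cfg$analysis %in% c("single_point", "portrait", "basin")) {
    ic <- cfg$initial_conditions
    if (is.null(ic) && cfg$analysis != "basin")
      stop("'initial_conditions' required for ", cfg$analysis, call. = FALSE)
    if (!is.null(ic)) cfg$initial_conditions <- expand_ics(ic, motif)
  }
  if (cfg$analysis %in% c("multi_point", "basin", "portrait")) {
    if (is.null(cfg$grid) || is.null(cfg$grid$axis1) ||
        is.null(cfg$grid$axis2))
      stop("'grid' with axis1 and axis2 is required for ", cfg$analysis,
           call. = FALSE)
    cfg$grid <- lapply(cfg$grid[c("axis1", "axis2")], function(ax) {
      need <- setdiff(c("name", "from", "to", "step"), names(ax))
      if (length(need))
        stop("grid axis missing field(s): ", paste(need, collapse = ", "),
             call. = FALSE)
      grid_axis(ax$name, ax$from, ax$to, ax$step)
    })
  }
  if (cfg$analysis == "basin") {
    cfg$basin <- utils::modifyList(list(horizon = 1000),
      if (is.null(raw$basin)) list() else raw$basin)
    fic <- cfg$basin$fixed_initial_conditions
    if (is.null(fic)) fic <- cfg$initial_conditions
    if (is.null(fic))
      stop("basin analysis needs 'initial_conditions' or ",
           "'basin: fixed_initial_conditions'", call. = FALSE)
    cfg$basin$fixed_initial_conditions <- expand_ics(fic, motif)
  }
  structure(cfg, class = "analysis_config", motif = motif)
}

expand_ics <- function(ic, motif) {
  if (is.numeric(ic) && length(ic) == 1L && is.null(names(ic)))
    return(stats::setNames(rep(ic, motif$n_states), motif$state_names))
  ic <- unlist(ic)
  miss <- setdiff(motif$state_names, names(ic))
  if (length(miss))
    stop("initial condition(s) missing for state(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(ic), motif$state_names)
  if (length(extra))
    stop("initial condition(s) for unknown state(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  ic[motif$state_names]
}

#' Write a configuration back to YAML
#'
#' Inverse of \code{\link{load_config}} up to default filling: a written
#' config re-loads to an identical object.
#'
#' @param cfg an \code{"analysis_config"}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "analysis_config"))
  out <- unclass(cfg)
  attr(out, "motif") <- NULL
  out$initial_conditions <- as.list(out$initial_conditions)
  if (!is.null(out$grid))
    out$grid <- lapply(out$grid, function(ax)
      ax[c("name", "from", "to", "step")])
  if (!is.null(out$basin) && !is.null(out$basin$fixed_initial_conditions))
    out$basin$fixed_initial_conditions <-
      as.list(out$basin$fixed_initial_conditions)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat(sprintf("<analysis_config: %s on '%s'>\n", x$analysis, x$motif))
  invisible(x)
}

#' Run a configured analysis and write its result bundle
#'
#' Dispatches on the configured analysis type and writes, per type:
#' \describe{
#'   \item{single_point}{\code{trajectory.csv} (+ settings JSON) and
#'     \code{fixed_points.csv} (one row per equilibrium, stability labels).}
#'   \item{multi_point}{\code{regions.csv} + \code{regions_legend.json}.}
#'   \item{basin}{\code{basin.csv} + \code{basin_legend.json}.}
#'   \item{portrait}{\code{portrait_<i>.csv} per grid trajectory.}
#'   \item{thermo}{\code{thermo.json} with dG0', dG_rxn and I_th.}
#' }
#' plus \code{run_metadata.json} (package version, seed, tolerances, wall
#' time) in every case. Number formatting uses 6 significant digits with
#' scientific notation below \code{1e-3}, so identical configurations give
#' byte-identical outputs.
#'
#' @param cfg an \code{\link{load_config}} object (or path to one).
#' @param outdir output directory; default: the config's \code{output_dir}.
#' @param progress print percent-complete lines on long sweeps.
#' @return invisibly, a named list of written file paths and the in-memory
#'   results.
#' @export
run_analysis <- function(cfg, outdir = NULL, progress = FALSE) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  stopifnot(inherits(cfg, "analysis_config"))
  motif <- attr(cfg, "motif")
  if (is.null(outdir)) outdir <- cfg$output_dir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  settings <- solver_settings(method = cfg$solver$method,
                              atol = cfg$solver$atol, rtol = cfg$solver$rtol,
                              t_end = cfg$solver$t_end)
  files <- character(0)
  results <- list()

  if (cfg$analysis == "single_point") {
    traj <- integrate_motif(motif, cfg$initial_conditions, settings)
    if (!traj$success) stop("integration failed: ", traj$diagnostics,
                            call. = FALSE)
    files <- c(files, export_trajectory(traj, file.path(outdir,
                                                        "trajectory.csv")))
    fps <- fixed_points(motif, n_starts = cfg$fixed_points$n_starts,
                        seed = cfg$fixed_points$seed,
                        spectrum = cfg$fixed_points$spectrum)
    files <- c(files, export_fixed_points(fps,
                                          file.path(outdir,
                                                    "fixed_points.csv")))
    results <- list(trajectory = traj, fixed_points = fps)
  } else if (cfg$analysis == "multi_point") {
    rm_ <- operating_diagram(motif, cfg$grid$axis1, cfg$grid$axis2,
                             n_starts = cfg$fixed_points$n_starts,
                             seed = cfg$fixed_points$seed,
                             spectrum = cfg$fixed_points$spectrum,
                             progress = progress)
    files <- c(files, export_map(rm_, file.path(outdir, "regions.csv")))
    results <- list(region_map = rm_)
  } else if (cfg$analysis == "basin") {
    bm <- basin_of_attraction(motif, cfg$grid$axis1, cfg$grid$axis2,
                              fixed_ics = cfg$basin$fixed_initial_conditions,
                              eps = cfg$basin$eps,
                              horizon = cfg$basin$horizon,
                              settings = settings, progress = progress)
    files <- c(files, export_map(bm, file.path(outdir, "basin.csv")))
    results <- list(basin_map = bm)
  } else if (cfg$analysis == "portrait") {
    ax <- cfg$grid
    pp <- phase_portrait(motif,
                         varied = c(ax$axis1$name, ax$axis2$name),
                         ranges = list(c(ax$axis1$from, ax$axis1$to,
                                         ax$axis1$step),
                                       c(ax$axis2$from, ax$axis2$to,
                                         ax$axis2$step)),
                         fixed_x0 = cfg$initial_conditions,
                         settings = settings)
    for (i in seq_along(pp$trajectories))
      if (pp$trajectories[[i]]$success)
        files <- c(files, export_trajectory(pp$trajectories[[i]],
          file.path(outdir, sprintf("portrait_%03d.csv", i))))
    results <- list(portrait = pp)
  } else if (cfg$analysis == "thermo") {
    th <- cfg$thermo
    if (is.null(th)) stop("'thermo' section required", call. = FALSE)
    cmp <- if (!is.null(th$compounds)) read_compound_table(th$compounds)
    rxn <- reaction_thermo(unlist(th$reactants), unlist(th$products),
                           temperature = th$temperature, dG0 = th$dG0,
                           units = if (is.null(th$units)) "molar" else th$units,
                           compounds = cmp)
    acts <- unlist(th$activities)
    dg <- gibbs_reaction(rxn, acts)
    ith <- thermo_inhibition(dg, th$temperature)
    res <- list(dG0 = rxn$dG0, dG_rxn = dg, I_th = ith,
                temperature = th$temperature)
    p <- file.path(outdir, "thermo.json")
    jsonlite::write_json(res, p, auto_unbox = TRUE, digits = NA)
    files <- c(files, p)
    results <- res
  }

  meta <- list(package = "motifsim",
               version = as.character(utils::packageVersion("motifsim")),
               motif = cfg$motif, analysis = cfg$analysis, seed = cfg$seed,
               solver = cfg$solver, fixed_point_options = cfg$fixed_points,
               wall_time_s = round(proc.time()[["elapsed"]] - t0, 3))
  mp <- file.path(outdir, "run_metadata.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA)
  files <- c(files, mp)
  invisible(list(files = files, results = results))
}
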