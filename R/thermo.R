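# universal gas constant, kJ mol^-1 K^-1
.R_GAS <- 8.31446e-3

#' Read a compound Gibbs-energy table
#'
#' Reads a delimited text table of standard Gibbs energies of formation at
#' reference temperatures. Each row is
#' \code{name <tab> phase <tab> molar_mass <tab> T1:dG1 <tab> T2:dG2 ...}
#' with temperatures in kelvin and energies in kJ/mol; lines starting with
#' \code{#} are comments. At least three reference temperatures per
#' compound are required (the temperature adjustment fits an order-2
#' polynomial).
#'
#' A small bundled table (H2, CO2, CH4, acetate, H2O at four temperatures,
#' derived from standard-reference formation energies and enthalpies via
#' the Gibbs-Helmholtz relation) ships at
#' \code{system.file("extdata", "compounds_gibbs.tsv", package = "motifsim")}.
#'
#' @param path path to the table.
#' @return a \code{"compound_table"}: named list of entries, each with
#'   \code{name}, \code{phase}, \code{molar_mass}, \code{ref_T},
#'   \code{ref_dG}.
#' @export
read_compound_table <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  entries <- lapply(lines, function(ln) {
    f <- strsplit(ln, "[\t,] *")[[1]]
    if (length(f) < 6L)
      stop("compound row needs name, phase, molar_mass and >= 3 T:dG pairs: ",
           ln, call. = FALSE)
    phase <- match.arg(f[2], c("solid", "liquid", "aqueous", "gas"))
    mm <- as.numeric(f[3])
    if (!is.finite(mm) || mm <= 0)
      stop("molar mass must be positive for compound '", f[1], "'",
           call. = FALSE)
    pairs <- do.call(rbind, lapply(f[-(1:3)], function(p) {
      v <- as.numeric(strsplit(p, ":")[[1]])
      if (length(v) != 2L || anyNA(v)) stop("malformed T:dG pair: ", p,
                                            call. = FALSE)
      v
    }))
    list(name = f[1], phase = phase, molar_mass = mm,
         ref_T = pairs[, 1], ref_dG = pairs[, 2])
  })
  names(entries) <- vapply(entries, `[[`, "", "name")
  structure(entries, class = "compound_table")
}

#' @export
print.compound_table <- function(x, ...) {
  cat(sprintf("<compound_table: %d compounds (%s)>\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Standard Gibbs energy at a given temperature
#'
#' Evaluates the least-squares order-2 polynomial through a compound's
#' reference \code{(T, dG0)} points at temperature \code{T}. With exactly
#' three reference points the quadratic interpolates them. Mild
#' extrapolation only: \code{T} must lie within 25 K of the reference range.
#'
#' @param entry one element of a \code{\link{read_compound_table}} (or any
#'   list with \code{ref_T}, \code{ref_dG}).
#' @param temperature temperature in kelvin.
#' @return Gibbs energy in kJ/mol.
#' @export
gibbs_at_temperature <- function(entry, temperature) {
  Tr <- entry$ref_T; g <- entry$ref_dG
  if (length(Tr) < 3L)
    stop("at least 3 reference temperatures are required for the order-2 fit",
         call. = FALSE)
  if (temperature < min(Tr) - 25 || temperature > max(Tr) + 25)
    stop(sprintf("temperature %.2f K outside the allowed window [%.2f, %.2f]",
                 temperature, min(Tr) - 25, max(Tr) + 25), call. = FALSE)
  # centre T for conditioning; least-squares quadratic
  tc <- Tr - mean(Tr)
  co <- stats::lsfit(cbind(tc, tc^2), g)$coefficients
  tt <- temperature - mean(Tr)
  unname(co[1] + co[2] * tt + co[3] * tt^2)
}

#' Define a reaction for thermodynamic analysis
#'
#' @param reactants named numeric vector: moles of each reactant compound.
#' @param products named numeric vector: stoichiometric coefficients
#'   (\code{gamma_p}) of each product compound.
#' @param temperature temperature in kelvin.
#' @param dG0 overall standard Gibbs energy of reaction (kJ/mol). If
#'   \code{NULL}, it is summed from per-compound values in \code{compounds}
#'   adjusted to \code{temperature}.
#' @param units \code{"molar"} (default) or \code{"COD"}; under COD units,
#'   concentrations of aqueous compounds are converted to molarity through
#'   their molar mass before entering the reaction quotient.
#' @param compounds a \code{\link{read_compound_table}} (required when
#'   \code{dG0} is \code{NULL} or units are COD).
#' @return an object of class \code{"reaction_thermo"}.
#' @export
reaction_thermo <- function(reactants, products, temperature, dG0 = NULL,
                            units = c("molar", "COD"), compounds = NULL) {
  units <- match.arg(units)
  stopifnot(length(reactants) > 0, length(products) > 0, temperature > 0,
            !is.null(names(reactants)), !is.null(names(products)),
            all(reactants > 0), all(products > 0))
  if (is.null(dG0)) {
    if (is.null(compounds))
      stop("either 'dG0' or a compound table must be supplied", call. = FALSE)
    need <- c(names(reactants), names(products))
    miss <- setdiff(need, names(compounds))
    if (length(miss))
      stop("compound(s) not in table: ", paste(miss, collapse = ", "),
           call. = FALSE)
    gp <- vapply(names(products), function(nm)
      gibbs_at_temperature(compounds[[nm]], temperature), numeric(1))
    gr <- vapply(names(reactants), function(nm)
      gibbs_at_temperature(compounds[[nm]], temperature), numeric(1))
    dG0 <- sum(products * gp) - sum(reactants * gr)
  }
  structure(list(reactants = reactants, products = products,
                 temperature = temperature, dG0 = dG0, units = units,
                 compounds = compounds),
            class = "reaction_thermo")
}

#' @export
print.reaction_thermo <- function(x, ...) {
  side <- function(v) paste(sprintf("%g %s", v, names(v)), collapse = " + ")
  cat(sprintf("<reaction_thermo: %s -> %s at %g K, dG0' = %.3f kJ/mol (%s units)>\n",
              side(x$reactants), side(x$products), x$temperature, x$dG0,
              x$units))
  invisible(x)
}

#' Gibbs energy of reaction at given activities
#'
#' \code{dG_rxn = dG0' + R T ln( prod(products^gamma) / prod(reactants^nu) )}.
#' Under COD units, activities of aqueous compounds are divided by their
#' molar mass (COD-mass to molarity) before the quotient is formed.
#'
#' @param rxn a \code{\link{reaction_thermo}}.
#' @param activities named vector of activities/concentrations covering all
#'   compounds in the reaction; all must be strictly positive.
#' @return Gibbs energy of reaction, kJ/mol.
#' @export
gibbs_reaction <- function(rxn, activities) {
  stopifnot(inherits(rxn, "reaction_thermo"))
  need <- c(names(rxn$reactants), names(rxn$products))
  miss <- setdiff(need, names(activities))
  if (length(miss))
    stop("missing activities: ", paste(miss, collapse = ", "), call. = FALSE)
  act <- activities[need]
  if (any(act <= 0))
    stop("reaction quotient undefined: nonpositive activity for ",
         paste(need[act <= 0], collapse = ", "), call. = FALSE)
  if (rxn$units == "COD") {
    if (is.null(rxn$compounds))
      stop("COD units require a compound table (for molar masses)",
           call. = FALSE)
    for (nm in need) {
      cmp <- rxn$compounds[[nm]]
      if (!is.null(cmp) && cmp$phase == "aqueous")
        act[nm] <- act[nm] / cmp$molar_mass
    }
  }
  lnQ <- sum(rxn$products * log(act[names(rxn$products)])) -
         sum(rxn$reactants * log(act[names(rxn$reactants)]))
  rxn$dG0 + .R_GAS * rxn$temperature * lnQ
}

#' Thermodynamic growth inhibition factor
#'
#' \code{I_th = 1 - exp(dG_rxn / (R T))}: 0 at equilibrium
#' (\code{dG_rxn = 0}), approaching 1 as the reaction becomes strongly
#' exergonic. For endergonic conditions the raw expression is negative;
#' by default it is clamped at 0 (no catabolic flux when the reaction is
#' infeasible).
#'
#' @param dG_rxn Gibbs energy of reaction, kJ/mol.
#' @param temperature temperature in kelvin.
#' @param clamp floor the factor at 0 (default \code{TRUE}).
#' @return dimensionless factor in \code{[0, 1]} when clamped.
#' @export
thermo_inhibition <- function(dG_rxn, temperature, clamp = TRUE) {
  stopifnot(temperature > 0)
  ith <- 1 - exp(dG_rxn / (.R_GAS * temperature))
  if (clamp) ith <- pmax(ith, 0)
  ith
}

#' Extend a motif with a thermodynamically limited reaction
#'
#' Appends mass balances for reaction compounds not modelled by the motif
#' and couples the growth of one biomass to the reaction's Gibbs energy:
#' each new reactant obeys \code{dS/dt = -D S - f_new X_n I_th}, each new
#' product \code{dS/dt = -D S + gamma_new (1 - Y_n) f_n X_n I_th}, and the
#' target biomass equation becomes
#' \code{dX_n/dt = -D X_n + Y_new f_new X_n I_th - k_dec,n X_n}, with
#' \code{f_new = f_n * mu_new}. \code{I_th} is re-evaluated from the current
#' state at every step: reaction compounds whose name matches a state
#' variable (original or newly added) take that state's concentration as
#' their activity; all others use the fixed activities in
#' \code{base_activities} (default 1).
#'
#' With \code{rxn = NULL} the factor is identically 1 (a neutral
#' extension); with additionally \code{mu_new = 1}, no new compounds and
#' \code{Y_new} equal to the original yield, the system is unchanged.
#'
#' The extended right-hand side involves the clamped exponential factor, so
#' the Jacobian falls back to central finite differences
#' (\code{jac_method = "finite_difference"}).
#'
#' @param motif a \code{\link{build_motif}} object.
#' @param target name of the biomass whose growth the reaction drives
#'   (e.g. \code{"X2"}).
#' @param rxn a \code{\link{reaction_thermo}}, or \code{NULL} for
#'   \code{I_th == 1}.
#' @param new_reactants,new_products character vectors of new state names
#'   to append (must not collide with existing states).
#' @param mu_new growth rescaling for the new substrate (Eq.-style
#'   \code{f_new = f_n mu_new}); default 1.
#' @param Y_new yield on the new substrate; default: the target's original
#'   yield.
#' @param gamma_new stoichiometric coefficient(s) for the new products,
#'   recycled to \code{length(new_products)}; default 1.
#' @param base_activities named vector of fixed activities for reaction
#'   compounds that are not state variables.
#' @param clamp clamp \code{I_th} at 0 (default \code{TRUE}).
#' @return a new \code{"motif"} with the appended states.
#' @export
extend_motif <- function(motif, target, rxn = NULL,
                         new_reactants = character(0),
                         new_products = character(0),
                         mu_new = 1, Y_new = NULL, gamma_new = 1,
                         base_activities = NULL, clamp = TRUE) {
  stopifnot(inherits(motif, "motif"))
  if (!target %in% motif$state_names[motif$biomass_idx])
    stop("'", target, "' is not a biomass state of this motif", call. = FALSE)
  newstates <- c(new_reactants, new_products)
  clash <- intersect(newstates, motif$state_names)
  if (length(clash))
    stop("new state name(s) collide with existing states: ",
         paste(clash, collapse = ", "), call. = FALSE)
  tnum <- sub("^X", "", target)
  if (is.null(Y_new)) Y_new <- motif$params[[paste0("Y", tnum)]]
  gamma_new <- rep_len(gamma_new, length(new_products))
  kdec_name <- paste0("kdec", tnum)

  n_old <- motif$n_states
  states <- c(motif$state_names, newstates)
  n_all <- length(states)
  target_idx <- match(target, states)
  ir <- if (length(new_reactants)) n_old + seq_along(new_reactants) else integer(0)
  ip <- if (length(new_products))
    n_old + length(new_reactants) + seq_along(new_products) else integer(0)

  base_parsed <- lapply(motif$exprs, function(s) parse(text = s)[[1]])
  fn_parsed <- parse(text = motif$growth_exprs[[target]])[[1]]
  # which reaction compounds are state variables?
  act_fixed <- base_activities
  rxn_names <- if (!is.null(rxn)) c(names(rxn$reactants), names(rxn$products))
               else character(0)
  state_compounds <- intersect(rxn_names, states)

  param_env <- NULL  # bound after new_motif(); see below
  rhs_ext <- function(x) {
    e <- new.env(parent = param_env)
    for (k in seq_len(n_old)) assign(states[k], x[[k]], envir = e)
    base <- vapply(base_parsed, eval, numeric(1), envir = e)
    fn <- eval(fn_parsed, envir = e)
    D <- get("D", envir = param_env)
    Yn <- get(paste0("Y", tnum), envir = param_env)
    kd <- get(kdec_name, envir = param_env)
    Xn <- x[[target_idx]]
    ith <- 1
    if (!is.null(rxn)) {
      acts <- act_fixed
      if (is.null(acts)) acts <- stats::setNames(rep(1, length(rxn_names)),
                                                 rxn_names)
      acts[state_compounds] <- pmax(x[match(state_compounds, states)], 1e-12)
      dg <- gibbs_reaction(rxn, acts)
      ith <- thermo_inhibition(dg, rxn$temperature, clamp = clamp)
    }
    fnew <- fn * mu_new
    out <- numeric(n_all)
    out[seq_len(n_old)] <- base
    out[target_idx] <- -D * Xn + Y_new * fnew * Xn * ith - kd * Xn
    if (length(ir)) out[ir] <- -D * x[ir] - fnew * Xn * ith
    if (length(ip)) out[ip] <- -D * x[ip] + gamma_new * (1 - Yn) * fn * Xn * ith
    out
  }

  ext <- new_motif(name = paste0(motif$name, "+thermo"), states = states,
                   exprs = c(motif$exprs,
                             stats::setNames(rep("<thermodynamic extension>",
                                                 length(newstates)), newstates)),
                   parsed = NULL, params = motif$params,
                   n_species = motif$n_species, forms = motif$forms,
                   rhs_closure = rhs_ext)
  # the closure reads parameters through `param_env` in its own environment
  assign("param_env", ext$param_env, envir = environment(ext$rhs_fn))
  ext$growth_exprs <- motif$growth_exprs
  ext$rebuild <- function(new_params)
    extend_motif(motif$rebuild(new_params), target = target, rxn = rxn,
                 new_reactants = new_reactants, new_products = new_products,
                 mu_new = mu_new, Y_new = Y_new, gamma_new = gamma_new,
                 base_activities = base_activities, clamp = clamp)
  ext$extension <- list(target = target, rxn = rxn, mu_new = mu_new,
                        Y_new = Y_new, gamma_new = gamma_new,
                        new_reactants = new_reactants,
                        new_products = new_products, clamp = clamp)
  ext
}
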