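#' Catalogue of ecological interaction motifs
#'
#' Lists the seven bundled chemostat interaction motifs with their ecological
#' term, interaction sign pattern (benefit \code{+}, cost \code{-}, neutral
#' \code{0} for each species) and number of species.
#'
#' @return a data frame with columns \code{name}, \code{term},
#'   \code{interaction}, \code{n_species}, \code{n_states}.
#' @examples
#' list_motifs()
#' @export
list_motifs <- function() {
  data.frame(
    name = c("syntrophy", "food_chain", "food_chain_inhibition",
             "no_common_metabolites", "waste_product_inhibition",
             "substrate_competition", "three_species_food_web"),
    term = c("Cooperation", "Commensalism", "Predation", "No interaction",
             "Amensalism", "Competition", "Competition/Cooperation"),
    interaction = c("+/+", "0/+", "-/+", "0/0", "0/-", "-/-", "(+/-)/+/(-/+)"),
    n_species = c(2L, 2L, 2L, 2L, 2L, 2L, 3L),
    n_states = c(4L, 4L, 5L, 4L, 5L, 3L, 6L),
    stringsAsFactors = FALSE
  )
}

# -- internal motif equation builders ---------------------------------------
#
# Every motif is assembled from the chemostat mass-balance template
#   dS/dt = D (S_in - S) - f(S) X           (substrate)
#   dX/dt = (-D + Y f(S) - k_dec) X         (biomass)
#   dP/dt = D (P_in - P) + gamma (1 - Y) f(S) X   (product routing)
# with growth functions f_n possibly carrying motif-specific inhibition or
# secondary-substrate factors. Equations are kept as strings in the state
# and parameter symbols so that analytic Jacobians can be derived from them.

motif_equations <- function(name, forms, i2 = "i3") {
  f1 <- growth_expr(forms[1], 1, "S1", "X1")
  switch(name,
    syntrophy = {
      # X1 converts S1 -> S2 and is product-inhibited by S2 (its partner's
      # removal of S2 is the benefit); X2 consumes S2.
      f1i <- sprintf("(%s)*(1/(1 + S2/Ki1))", f1)
      f2 <- growth_expr(forms[2], 2, "S2", "X2")
      list(states = c("S1", "X1", "S2", "X2"),
           growth = c(X1 = f1i, X2 = f2),
           exprs = c(
        S1 = sprintf("D*(S1_in - S1) - (%s)*X1", f1i),
        X1 = sprintf("-D*X1 + Y1*(%s)*X1 - kdec1*X1", f1i),
        S2 = sprintf("D*(S2_in - S2) + gamma0*(1 - Y1)*(%s)*X1 - (%s)*X2", f1i, f2),
        X2 = sprintf("-D*X2 + Y2*(%s)*X2 - kdec2*X2", f2)))
    },
    food_chain = {
      # plain commensal chain: X1 converts S1 -> S2, X2 consumes S2
      f2 <- growth_expr(forms[2], 2, "S2", "X2")
      list(states = c("S1", "X1", "S2", "X2"),
           growth = c(X1 = f1, X2 = f2),
           exprs = c(
        S1 = sprintf("D*(S1_in - S1) - (%s)*X1", f1),
        X1 = sprintf("-D*X1 + Y1*(%s)*X1 - kdec1*X1", f1),
        S2 = sprintf("D*(S2_in - S2) + gamma0*(1 - Y1)*(%s)*X1 - (%s)*X2", f1, f2),
        X2 = sprintf("-D*X2 + Y2*(%s)*X2 - kdec2*X2", f2)))
    },
    food_chain_inhibition = {
      # predation sign pattern: the chain of `food_chain`, plus X2's waste
      # product S3 inhibiting X1 noncompetitively
      f1i <- sprintf("(%s)*(1/(1 + S3/Ki1))", f1)
      f2 <- growth_expr(forms[2], 2, "S2", "X2")
      list(states = c("S1", "X1", "S2", "X2", "S3"),
           growth = c(X1 = f1i, X2 = f2),
           exprs = c(
        S1 = sprintf("D*(S1_in - S1) - (%s)*X1", f1i),
        X1 = sprintf("-D*X1 + Y1*(%s)*X1 - kdec1*X1", f1i),
        S2 = sprintf("D*(S2_in - S2) + gamma0*(1 - Y1)*(%s)*X1 - (%s)*X2", f1i, f2),
        X2 = sprintf("-D*X2 + Y2*(%s)*X2 - kdec2*X2", f2),
        S3 = sprintf("D*(S3_in - S3) + gamma1*(1 - Y2)*(%s)*X2", f2)))
    },
    no_common_metabolites = {
      # two fully decoupled substrate/biomass chemostat pairs
      f2 <- growth_expr(forms[2], 2, "S2", "X2")
      list(states = c("S1", "X1", "S2", "X2"),
           growth = c(X1 = f1, X2 = f2),
           exprs = c(
        S1 = sprintf("D*(S1_in - S1) - (%s)*X1", f1),
        X1 = sprintf("-D*X1 + Y1*(%s)*X1 - kdec1*X1", f1),
        S2 = sprintf("D*(S2_in - S2) - (%s)*X2", f2),
        X2 = sprintf("-D*X2 + Y2*(%s)*X2 - kdec2*X2", f2)))
    },
    waste_product_inhibition = {
      # amensalism: X1's waste product S3 inhibits X2, which grows on an
      # independent substrate S2 and returns no effect on X1
      f2 <- growth_expr(forms[2], 2, "S2", "X2")
      f2i <- sprintf("(%s)*(1/(1 + S3/Ki2))", f2)
      list(states = c("S1", "X1", "S2", "X2", "S3"),
           growth = c(X1 = f1, X2 = f2i),
           exprs = c(
        S1 = sprintf("D*(S1_in - S1) - (%s)*X1", f1),
        X1 = sprintf("-D*X1 + Y1*(%s)*X1 - kdec1*X1", f1),
        S2 = sprintf("D*(S2_in - S2) - (%s)*X2", f2i),
        X2 = sprintf("-D*X2 + Y2*(%s)*X2 - kdec2*X2", f2i),
        S3 = sprintf("D*(S3_in - S3) + gamma0*(1 - Y1)*(%s)*X1", f1)))
    },
    substrate_competition = {
      # both biomasses consume the single substrate S1
      f2 <- growth_expr(forms[2], 2, "S1", "X2")
      list(states = c("S1", "X1", "X2"),
           growth = c(X1 = f1, X2 = f2),
           exprs = c(
        S1 = sprintf("D*(S1_in - S1) - (%s)*X1 - (%s)*X2", f1, f2),
        X1 = sprintf("-D*X1 + Y1*(%s)*X1 - kdec1*X1", f1),
        X2 = sprintf("-D*X2 + Y2*(%s)*X2 - kdec2*X2", f2)))
    },
    three_species_food_web = {
      # three-tier food web: X1 degrades S1 using S3 as a secondary
      # substrate, feeding S2 to X2; X2 produces S3 and is noncompetitively
      # inhibited by it; X3 consumes S3 in competition with X1.
      f1c <- sprintf("(%s)*(S3/(KS3c + S3))", f1)
      f2 <- growth_expr(forms[2], 2, "S2", "X2")
      f3 <- growth_expr(forms[3], 3, "S3", "X3")
      I3 <- "(1/(1 + S3/Ki3))"
      Ip <- if (identical(i2, "i3")) I3 else "1"
      list(states = c("S1", "X1", "S2", "X2", "S3", "X3"),
           growth = c(X1 = f1c, X2 = sprintf("(%s)*%s", f2, I3), X3 = f3),
           exprs = c(
        S1 = sprintf("D*(S1_in - S1) - (%s)*X1", f1c),
        X1 = sprintf("-D*X1 + Y1*(%s)*X1 - kdec1*X1", f1c),
        S2 = sprintf("D*(S2_in - S2) + gamma0*(1 - Y1)*(%s)*X1 - (%s)*X2*%s",
                     f1c, f2, I3),
        X2 = sprintf("-D*X2 + Y2*(%s)*X2*%s - kdec2*X2", f2, I3),
        S3 = sprintf(paste0("D*(S3_in - S3) + gamma1*(1 - Y2)*(%s)*X2*%s",
                            " - (%s)*X3 - gamma2*(%s)*X1"),
                     f2, Ip, f3, f1c),
        X3 = sprintf("-D*X3 + Y3*(%s)*X3 - kdec3*X3", f3)))
    },
    stop("unknown motif name: '", name, "'", call. = FALSE))
}

#' Build a parameterised interaction motif
#'
#' Assembles one of the seven bundled motifs (see \code{\link{list_motifs}})
#' into an evaluable ODE system from the chemostat mass-balance template:
#' substrate inflow/outflow at dilution rate \code{D}, consumption
#' \code{-f_n X_n} (times any motif inhibition factors), growth
#' \code{+Y_n f_n X_n}, first-order decay \code{-kdec_n X_n}, and product
#' formation \code{+gamma_j (1 - Y_n) f_n X_n} routed along the motif's
#' coupling topology.
#'
#' Parameter symbols follow the convention \code{D}, \code{S1_in},
#' \code{S2_in}, ..., \code{Y1}, \code{kdec1}, \code{km1}, \code{KS1},
#' \code{gamma0}, \code{gamma1}, \code{gamma2}, inhibition constants
#' \code{Ki1}, \code{Ki2}, \code{Ki3}, and (three-tier only) the secondary
#' substrate affinity \code{KS3c}. Haldane kinetics add \code{Kih<i>},
#' Moser/Hill an exponent \code{n<i>}, and \code{monod_thermo} a fixed
#' factor \code{Ith<i>}.
#'
#' For the three-tier motif, the inhibition factor on the hydrogen
#' production term defaults to the same noncompetitive factor that
#' modulates consumer growth (\code{i2 = "i3"}); set \code{i2 = "none"}
#' to drop it from the production term only.
#'
#' @param name motif identifier, one of \code{list_motifs()$name}.
#' @param params named list (or vector) of parameter values.
#' @param growth per-species growth forms: a character vector of form names,
#'   or a list of \code{\link{growth_kinetics}} objects (whose constants are
#'   then injected into \code{params}). Default: Monod for every species.
#' @param i2 three-tier production-term inhibition, \code{"i3"} or
#'   \code{"none"}.
#' @return an object of class \code{"motif"}: a list with the state names,
#'   parameters, equation strings, and evaluable right-hand side and
#'   Jacobian.
#' @examples
#' m <- build_motif("food_chain",
#'   params = list(D = 0.1, S1_in = 5, S2_in = 0, Y1 = 0.1, Y2 = 0.1,
#'                 kdec1 = 0.02, kdec2 = 0.02, gamma0 = 1,
#'                 km1 = 10, KS1 = 0.5, km2 = 8, KS2 = 0.4))
#' motif_rhs(m, c(S1 = 5, X1 = 0, S2 = 0, X2 = 0))  # washout balance
#' @export
build_motif <- function(name, params, growth = NULL,
                        i2 = c("i3", "none")) {
  i2 <- match.arg(i2)
  nm <- list_motifs()
  if (!name %in% nm$name)
    stop("unknown motif name: '", name, "' (see list_motifs())", call. = FALSE)
  n_species <- nm$n_species[nm$name == name]

  params <- as.list(params)
  forms <- rep("monod", n_species)
  if (!is.null(growth)) {
    if (is.character(growth)) {
      if (length(growth) == 1L) growth <- rep(growth, n_species)
      stopifnot(length(growth) == n_species)
      forms <- growth
    } else if (is.list(growth)) {
      stopifnot(length(growth) == n_species)
      for (i in seq_len(n_species)) {
        g <- growth[[i]]
        stopifnot(inherits(g, "growth_kinetics"))
        forms[i] <- g$form
        params[[paste0("km", i)]] <- g$k_m
        params[[paste0("KS", i)]] <- g$K_S
        if (!is.null(g$extra$K_i)) params[[paste0("Kih", i)]] <- g$extra$K_i
        if (!is.null(g$extra$n))   params[[paste0("n", i)]]   <- g$extra$n
        if (!is.null(g$extra$I_th)) params[[paste0("Ith", i)]] <- g$extra$I_th
      }
    } else stop("'growth' must be a character vector or list of growth_kinetics",
                call. = FALSE)
  }

  eq <- motif_equations(name, forms, i2)
  parsed <- lapply(eq$exprs, function(s) parse(text = s)[[1]])
  required <- setdiff(unique(unlist(lapply(parsed, all.vars))), eq$states)
  missing <- setdiff(required, names(params))
  if (length(missing))
    stop("missing motif parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  validate_motif_params(params, required)

  motif <- new_motif(name = name, states = eq$states, exprs = eq$exprs,
                     parsed = parsed, params = params[required],
                     n_species = n_species, forms = forms)
  motif$growth_exprs <- eq$growth
  motif$i2 <- i2
  motif$rebuild <- function(new_params) build_motif(name, new_params,
                                                    growth = forms, i2 = i2)
  motif
}

# Shared constructor for template-built and extended motifs. For
# expression-built motifs the right-hand side and the analytic Jacobian
# (entrywise symbolic differentiation via stats::D) are compiled into plain
# closures over the parameter environment, which keeps the damped-Newton
# enumeration and the stiff solver cheap.
new_motif <- function(name, states, exprs, parsed, params, n_species, forms,
                      rhs_closure = NULL) {
  param_env <- list2env(params, parent = baseenv())
  biomass_idx <- grep("^X", states)
  substrate_idx <- grep("^S", states)
  n <- length(states)

  assigns <- paste0(states, " <- x[", seq_len(n), "]", collapse = "; ")
  jac_fn <- NULL
  jac_method <- "finite_difference"
  if (is.null(rhs_closure)) {
    rhs_src <- sprintf("function(x) { %s; c(%s) }", assigns,
                       paste(exprs, collapse = ",\n"))
    rhs_fn <- eval(parse(text = rhs_src)[[1]], param_env)
    # column-major entry order: d(rhs_i)/d(state_j) for i fastest
    dentries <- tryCatch(
      unlist(lapply(states, function(s) vapply(parsed, function(p)
        paste(deparse(stats::D(p, s)), collapse = " "), ""))),
      error = function(e) NULL)
    if (!is.null(dentries)) {
      jac_method <- "analytic"
      jac_src <- sprintf(
        "function(x) { %s; matrix(c(%s), %d, %d) }",
        assigns, paste(dentries, collapse = ",\n"), n, n)
      jac_fn <- eval(parse(text = jac_src)[[1]], param_env)
    }
  } else rhs_fn <- rhs_closure

  structure(list(name = name, state_names = states, n_states = n,
                 n_species = n_species, biomass_idx = biomass_idx,
                 substrate_idx = substrate_idx, forms = forms,
                 params = params, param_env = param_env, exprs = exprs,
                 rhs_fn = rhs_fn, jac_fn = jac_fn, jac_method = jac_method),
            class = "motif")
}

validate_motif_params <- function(params, required) {
  for (s in required) {
    v <- params[[s]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", s, "' must be a finite numeric scalar", call. = FALSE)
    if (grepl("^(km|KS|Ki|n)", s) && v <= 0)
      stop("kinetic constant '", s, "' must be strictly positive", call. = FALSE)
    if (grepl("^Y[0-9]", s) && (v <= 0 || v > 1))
      stop("yield '", s, "' must lie in (0, 1]", call. = FALSE)
    if (grepl("^(D$|S[0-9]_in|kdec|gamma)", s) && v < 0)
      stop("parameter '", s, "' must be nonnegative", call. = FALSE)
  }
  invisible(TRUE)
}

#' Update motif parameter values in place
#'
#' Returns a copy of the motif with the named parameters changed; the
#' equations are not re-derived, so this is cheap inside parameter sweeps.
#'
#' @param motif a \code{\link{build_motif}} object.
#' @param ... named parameter values to replace.
#' @return the updated motif.
#' @export
set_params <- function(motif, ...) {
  stopifnot(inherits(motif, "motif"))
  upd <- list(...)
  if (length(upd) == 1L && is.list(upd[[1]]) && is.null(names(upd)[1]))
    upd <- upd[[1]]
  unknown <- setdiff(names(upd), names(motif$params))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  params <- utils::modifyList(motif$params, upd)
  if (is.null(motif$rebuild))
    stop("this motif does not support parameter updates", call. = FALSE)
  motif$rebuild(params)
}

#' Evaluate the motif right-hand side
#'
#' @param motif a \code{\link{build_motif}} object.
#' @param x state vector (length \code{motif$n_states}).
#' @return named vector of time derivatives.
#' @export
motif_rhs <- function(motif, x) {
  stopifnot(inherits(motif, "motif"))
  if (length(x) != motif$n_states)
    stop("state vector length ", length(x), " does not match motif dimension ",
         motif$n_states, call. = FALSE)
  stats::setNames(motif$rhs_fn(as.numeric(x)), motif$state_names)
}

#' Motif Jacobian matrix
#'
#' Evaluates the Jacobian of the motif right-hand side at a state. Uses the
#' analytic (symbolically differentiated) Jacobian when the motif equations
#' admit one; otherwise falls back to central finite differences (the method
#' used is recorded in \code{motif$jac_method}).
#'
#' @param motif a \code{\link{build_motif}} object.
#' @param x state vector.
#' @return the \code{n x n} Jacobian matrix.
#' @export
motif_jacobian <- function(motif, x) {
  stopifnot(inherits(motif, "motif"))
  x <- as.numeric(x)
  if (!is.null(motif$jac_fn)) {
    J <- motif$jac_fn(x)
    dimnames(J) <- list(motif$state_names, motif$state_names)
    return(J)
  }
  fd_jacobian(motif$rhs_fn, x, motif$state_names)
}

# central finite-difference Jacobian
fd_jacobian <- function(f, x, names = NULL, h = 1e-7) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    d <- h * max(abs(x[j]), 1)
    xp <- x; xm <- x
    xp[j] <- xp[j] + d; xm[j] <- xm[j] - d
    J[, j] <- (f(xp) - f(xm)) / (2 * d)
  }
  if (!is.null(names)) dimnames(J) <- list(names, names)
  J
}

#' Washout state of a motif
#'
#' The equilibrium with every biomass extinct and every substrate at its
#' inflow concentration. It is a fixed point of every motif for every valid
#' parameter set.
#'
#' @param motif a \code{\link{build_motif}} object.
#' @return named state vector.
#' @export
washout_state <- function(motif) {
  x <- numeric(motif$n_states)
  for (i in motif$substrate_idx) {
    pin <- paste0(motif$state_names[i], "_in")
    x[i] <- if (pin %in% names(motif$params)) motif$params[[pin]] else 0
  }
  stats::setNames(x, motif$state_names)
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("<motif: %s>  %d species, %d states (%s)\n", x$name,
              x$n_species, x$n_states, paste(x$state_names, collapse = ", ")))
  cat(sprintf("growth forms: %s;  Jacobian: %s\n",
              paste(x$forms, collapse = ", "), x$jac_method))
  invisible(x)
}

#' @export
summary.motif <- function(object, ...) {
  print(object)
  cat("\nEquations:\n")
  for (s in names(object$exprs))
    cat(sprintf("  d%s/dt = %s\n", s, object$exprs[[s]]))
  cat("\nParameters:\n")
  pv <- unlist(object$params)
  cat(paste0("  ", names(pv), " = ", signif(pv, 6), collapse = "\n"), "\n")
  invisible(object)
}
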