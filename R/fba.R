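# Scalarized two-objective flux balance analysis.
#
# A cell's per-step decision is an LP: maximize r_obj = a*X + (1-a)*m over
# the steady-state flux polytope, with the ATP maintenance flux pinned to
# the light-dependent demand. Sweeping a over [0, 1] traces the Pareto front
# between biomass (X) and transactional-metabolite (m) production.

scalar_weight <- function(weights) {
  if (inherits(weights, "objective_weights")) {
    return(weights$w_b)
  }
  a <- as.numeric(weights)
  if (length(a) == 2) {
    if (abs(sum(a) - 1) > 1e-8) stop("objective weights must sum to 1")
    a <- a[1]
  }
  if (length(a) != 1 || is.na(a) || a < -1e-12 || a > 1 + 1e-12) {
    stop("scalarization weight a must lie in [0, 1]")
  }
  min(max(a, 0), 1)
}

effective_bounds <- function(network, maintenance = NULL, extra_bounds = NULL) {
  lb <- network$lower
  ub <- network$upper
  for (id in names(extra_bounds)) {
    if (!id %in% network$reactions) {
      stop(sprintf("bound override for unknown reaction '%s'", id))
    }
    # overrides may only tighten the network's physiological bounds
    lb[[id]] <- max(lb[[id]], extra_bounds[[id]][1])
    ub[[id]] <- min(ub[[id]], extra_bounds[[id]][2])
  }
  if (!is.null(maintenance)) {
    lb[[network$atp_maintenance_rxn]] <- maintenance
    ub[[network$atp_maintenance_rxn]] <- maintenance
  }
  list(lb = lb, ub = ub)
}

#' Solve the scalarized flux-balance problem for one cell
#'
#' The two objective reactions are blended into a single scalarized
#' objective `r_obj = a * X + (1 - a) * m`: the solver maximizes the flux
#' `v_obj` through this combined reaction, which forces the biomass and
#' metabolite components into the ratio `a : (1 - a)` (so `v_X = a * v_obj`
#' and `v_m = (1 - a) * v_obj` hold exactly). The LP runs subject to
#' `S v = 0` and reaction bounds, with the ATP maintenance flux optionally
#' pinned to the light-dependent demand. Among alternate optima the reported
#' flux vector is made reproducible by a secondary lexicographic objective:
#' minimize the sum of absolute fluxes at the fixed optimum.
#'
#' @param network A [metabolic_network()].
#' @param weights Scalarization weight: a number `a` in `[0, 1]`, a pair
#'   `c(w_b, w_m)` summing to 1, or an [objective_weights()] object.
#' @param maintenance ATP maintenance flux to pin (mmol gDW^-1 h^-1), or
#'   `NULL` to leave the maintenance reaction free.
#' @param extra_bounds Named list of `c(lb, ub)` overrides (e.g. uptake
#'   bounds from local nutrient availability); they can only tighten the
#'   network's own bounds.
#' @param tie_break Run the secondary minimum-|flux| LP (default `TRUE`).
#' @return A `flux_solution`: list with `status` (`"optimal"` or
#'   `"infeasible"`; infeasibility is reported, never raised), `fluxes`
#'   (named vector), `objective_value` and `a`.
#' @export
solve_fba <- function(network, weights, maintenance = NULL,
                      extra_bounds = NULL, tie_break = TRUE) {
  stopifnot(inherits(network, "metabolic_network"))
  S <- network$stoichiometry
  if (ncol(S) != length(network$reactions)) {
    stop("malformed network: stoichiometry/reaction dimension mismatch")
  }
  a <- scalar_weight(weights)
  bb <- effective_bounds(network, maintenance, extra_bounds)
  aug <- scalarized_lp(network, a, bb)
  if (is.null(aug)) {
    return(infeasible_solution(a))
  }
  res <- lp_solve(aug$cvec, aug$A, aug$b, aug$lb, aug$ub, maximize = TRUE)
  if (res$status != "optimal") {
    return(infeasible_solution(a))
  }
  n <- ncol(S)
  v <- res$x[seq_len(n)]
  t_opt <- res$obj
  if (tie_break) {
    tb <- minimize_total_flux(network, a, t_opt, bb)
    if (!is.null(tb)) v <- tb
  }
  names(v) <- network$reactions
  structure(list(
    status = "optimal", fluxes = v,
    objective_value = t_opt, a = a
  ), class = "flux_solution")
}

infeasible_solution <- function(a) {
  structure(list(
    status = "infeasible", fluxes = NULL,
    objective_value = NA_real_, a = a
  ), class = "flux_solution")
}

# Build the augmented LP for the blended objective reaction: variables
# (v, t) with coupling rows v_X = a*t and v_m = (1-a)*t, maximize t.
scalarized_lp <- function(network, a, bb) {
  S <- network$stoichiometry
  n <- ncol(S)
  iX <- match(network$biomass_rxn, network$reactions)
  im <- match(network$metabolite_rxn, network$reactions)
  # implied bounds on t from the component bounds
  t_lo <- 0
  t_hi <- Inf
  if (a > 0) {
    t_lo <- max(t_lo, bb$lb[iX] / a)
    t_hi <- min(t_hi, bb$ub[iX] / a)
  }
  if (a < 1) {
    t_lo <- max(t_lo, bb$lb[im] / (1 - a))
    t_hi <- min(t_hi, bb$ub[im] / (1 - a))
  }
  if (!is.finite(t_hi)) t_hi <- 1e6
  if (t_lo > t_hi) {
    return(NULL)
  }
  A <- cbind(S, 0)
  A <- rbind(A, 0, 0)
  ncols <- n + 1
  A[nrow(S) + 1, iX] <- 1
  A[nrow(S) + 1, ncols] <- -a
  A[nrow(S) + 2, im] <- 1
  A[nrow(S) + 2, ncols] <- -(1 - a)
  list(
    cvec = c(numeric(n), 1),
    A = A,
    b = rep(0, nrow(S) + 2),
    lb = c(unname(bb$lb), t_lo),
    ub = c(unname(bb$ub), t_hi)
  )
}

# Secondary LP: min sum |v| s.t. S v = 0, bounds, with the two objective
# components pinned at their optimal values. Splits v = p - q, p, q >= 0.
minimize_total_flux <- function(network, a, t_opt, bb) {
  S <- network$stoichiometry
  n <- ncol(S)
  lb <- unname(bb$lb)
  ub <- unname(bb$ub)
  iX <- match(network$biomass_rxn, network$reactions)
  im <- match(network$metabolite_rxn, network$reactions)
  lb[iX] <- ub[iX] <- a * t_opt
  lb[im] <- ub[im] <- (1 - a) * t_opt
  lp <- pmax(lb, 0)
  up <- pmax(ub, 0)
  lq <- pmax(-ub, 0)
  uq <- pmax(-lb, 0)
  A <- cbind(S, -S)
  b <- rep(0, nrow(S))
  cost <- rep(1, 2 * n)
  res <- lp_solve(cost, A, b, c(lp, lq), c(up, uq), maximize = FALSE)
  if (res$status != "optimal") {
    return(NULL)
  }
  res$x[seq_len(n)] - res$x[n + seq_len(n)]
}

#' Generate the Pareto front between biomass and metabolite production
#'
#' Sweeps the scalarization weight `a` over `steps` evenly spaced values on
#' `[0, 1]` (both endpoints included) and records, for each value, the
#' optimal scalarized objective flux and its decomposition into biomass and
#' metabolite components (`v_X = a * v_obj`, `v_m = (1 - a) * v_obj`).
#'
#' @inheritParams solve_fba
#' @param steps Number of grid points (default 1000, the standard front
#'   resolution).
#' @return A `pareto_front`: data.frame with columns `a`, `nu_obj`, `nu_X`,
#'   `nu_m`, plus attribute `steps`. Grid points where the LP is infeasible
#'   get `NA` rows; if every point is infeasible an error is raised (a
#'   too-high pinned maintenance flux is the usual cause).
#' @export
generate_pareto_front <- function(network, steps = 1000, maintenance = NULL,
                                  extra_bounds = NULL) {
  stopifnot(steps >= 2)
  avals <- seq(0, 1, length.out = steps)
  out <- data.frame(
    a = avals, nu_obj = NA_real_, nu_X = NA_real_, nu_m = NA_real_
  )
  any_ok <- FALSE
  for (k in seq_along(avals)) {
    sol <- solve_fba(network, avals[k],
      maintenance = maintenance,
      extra_bounds = extra_bounds, tie_break = FALSE
    )
    if (sol$status == "optimal") {
      any_ok <- TRUE
      dec <- decompose_objective_flux(avals[k], sol$objective_value)
      out$nu_obj[k] <- sol$objective_value
      out$nu_X[k] <- dec[["mu"]]
      out$nu_m[k] <- dec[["nu_m"]]
    }
  }
  if (!any_ok) {
    stop(paste(
      "network infeasible at every scalarization weight;",
      "the pinned ATP maintenance flux is the usual cause"
    ))
  }
  structure(out, steps = steps, class = c("pareto_front", "data.frame"))
}

#' Decompose a scalarized objective flux into its components
#'
#' The optimal scalarized flux splits exactly into a biomass part and a
#' metabolite part: the growth rate is `mu = v_X = a * v_obj` and the
#' metabolite flux is `v_m = (1 - a) * v_obj`; the two always sum to `v_obj`.
#'
#' @param a Scalarization weight in `[0, 1]`.
#' @param nu_obj Optimal scalarized objective flux.
#' @return Named numeric vector `c(mu = a * nu_obj, nu_m = (1 - a) * nu_obj)`.
#' @export
decompose_objective_flux <- function(a, nu_obj) {
  stopifnot(a >= 0, a <= 1)
  c(mu = a * nu_obj, nu_m = (1 - a) * nu_obj)
}

#' Pareto efficiency of a flux solution
#'
#' Each objective flux is expressed relative to its (experimentally
#' determined) Pareto optimum and the ratios are averaged over the
#' objectives: `eps = mean_j(v_j / v_j_exp)`. A cell matching every optimum
#' scores 1; an idle cell scores 0.
#'
#' @param fluxes A `flux_solution` from [solve_fba()], or a named flux
#'   vector.
#' @param experimental_optima Named positive vector of per-objective optima;
#'   names select the objective reactions.
#' @return The efficiency `eps` (dimensionless).
#' @export
pareto_efficiency <- function(fluxes, experimental_optima) {
  if (inherits(fluxes, "flux_solution")) {
    if (fluxes$status != "optimal") {
      return(0)
    }
    fluxes <- fluxes$fluxes
  }
  if (any(experimental_optima <= 0)) {
    stop("experimental optima must all be positive")
  }
  ids <- names(experimental_optima)
  if (is.null(ids) || !all(ids %in% names(fluxes))) {
    stop("experimental_optima must be named by reactions present in the fluxes")
  }
  mean(fluxes[ids] / experimental_optima)
}
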