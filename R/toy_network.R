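# Packaged synthetic toy metabolic networks for the two cell types of a
# filamentous diazotrophic cyanobacterium, plus the brute-force LP oracle the
# test suite uses to cross-check the simplex solver.
#
# The toy networks stand in for a genome-scale reconstruction: they are
# lumped, elementally balanced in C and N, and small enough (<= 12 reactions)
# that every vertex of the flux polytope can be enumerated exhaustively.
#
# Species and their lumped elemental content (mmol C / mmol N per mmol):
#   ATP   0/0 (energy token)   CH2O  1/0 (fixed-carbon unit)
#   NH3   0/1                  MALT 12/0 (maltose, glycogen proxy)
#   BAA  10/5 (beta-aspartyl arginine, cyanophycin monomer)
#   CO2   1/0   O2 0/0   N2 0/2
# Biomass drains 40 mmol C and 7 mmol N per gDW formed (typical cyanobacterial
# dry-weight composition), so biomass flux is in h^-1.

# NH4 is the extracellular name of the intracellular NH3 species
TOY_ELEMENTS <- list(
  C = c(ATP = 0, CH2O = 1, NH3 = 0, NH4 = 0, MALT = 12, BAA = 10,
        CO2 = 1, O2 = 0, N2 = 0),
  N = c(ATP = 0, CH2O = 0, NH3 = 1, NH4 = 1, MALT = 0, BAA = 5,
        CO2 = 0, O2 = 0, N2 = 2)
)
TOY_BIOMASS_C <- 40 # mmol C per gDW
TOY_BIOMASS_N <- 7 # mmol N per gDW

#' Elemental content of the toy-network species
#'
#' @return A list with numeric vectors `C` and `N` (mmol element per mmol
#'   species) plus the biomass drain coefficients `biomass_C` and `biomass_N`
#'   (mmol element per gDW of biomass formed).
#' @export
toy_element_table <- function() {
  c(TOY_ELEMENTS, list(biomass_C = TOY_BIOMASS_C, biomass_N = TOY_BIOMASS_N))
}

toy_reaction_list <- function(cell_type, light_ub) {
  common <- list(
    LIGHT = list(stoich = c(ATP = 1), bounds = c(0, light_ub)),
    ATPM = list(stoich = c(ATP = -1), bounds = c(0, 500))
  )
  if (cell_type == "photoautotroph") {
    c(common, list(
      BIOMASS = list(
        stoich = c(CH2O = -TOY_BIOMASS_C, NH3 = -TOY_BIOMASS_N, ATP = -30),
        bounds = c(0, 10)
      ),
      CFIX = list(stoich = c(CO2 = -1, ATP = -2, CH2O = 1, O2 = 1), bounds = c(0, 100)),
      MALS = list(stoich = c(CH2O = -12, ATP = -1, MALT = 1), bounds = c(0, 50)),
      # full oxidative degradation of the arginine backbone: a net ATP
      # source whose carbon leaves as CO2, so a starved cell can run on
      # stored cyanophycin even when its objective sinks carry zero flux
      BAADEG = list(stoich = c(BAA = -1, ATP = 15, CO2 = 10, NH3 = 5), bounds = c(0, 50)),
      EX_CO2 = list(stoich = c(CO2 = -1), bounds = c(-50, 500)),
      EX_O2 = list(stoich = c(O2 = -1), bounds = c(-50, 500)),
      EX_NH4 = list(stoich = c(NH3 = -1), bounds = c(-50, 500)),
      EX_MALT = list(stoich = c(MALT = -1), bounds = c(0, 500)),
      EX_BAA = list(stoich = c(BAA = -1), bounds = c(-50, 0))
    ))
  } else {
    # the diazotroph runs on imported maltose carbon throughout: full
    # respiratory oxidation for ATP, direct incorporation into biomass and
    # into the cyanophycin monomer (with the 2 surplus carbons respired)
    c(common, list(
      BIOMASS = list(
        stoich = c(MALT = -TOY_BIOMASS_C / 12, NH3 = -TOY_BIOMASS_N, ATP = -30),
        bounds = c(0, 10)
      ),
      MALDEG = list(
        stoich = c(MALT = -1, O2 = -12, CO2 = 12, ATP = 30),
        bounds = c(0, 50)
      ),
      NFIX = list(stoich = c(N2 = -1, ATP = -16, NH3 = 2), bounds = c(0, 50)),
      BAAS = list(
        stoich = c(MALT = -1, NH3 = -5, ATP = -2, O2 = -2, BAA = 1, CO2 = 2),
        bounds = c(0, 50)
      ),
      EX_CO2 = list(stoich = c(CO2 = -1), bounds = c(-50, 500)),
      EX_O2 = list(stoich = c(O2 = -1), bounds = c(-50, 500)),
      EX_N2 = list(stoich = c(N2 = -1), bounds = c(-50, 0)),
      EX_NH4 = list(stoich = c(NH3 = -1), bounds = c(-50, 500)),
      EX_MALT = list(stoich = c(MALT = -1), bounds = c(-50, 0)),
      EX_BAA = list(stoich = c(BAA = -1), bounds = c(0, 500))
    ))
  }
}

#' Build a packaged toy metabolic network for one cell type
#'
#' Photoautotrophs fix CO2 with light-derived ATP, synthesize maltose (their
#' transactional metabolite) and obtain nitrogen by degrading imported
#' beta-aspartyl arginine. Diazotrophs fix N2, synthesize beta-aspartyl
#' arginine (their transactional metabolite) and obtain carbon and respiratory
#' ATP by catabolizing imported maltose. Exchange topology follows the allowed
#' cross-feeding of the two cell types: maltose flows photoautotroph ->
#' diazotroph, beta-aspartyl arginine the other way, gases exchange freely.
#'
#' The flux-sign convention for `EX_*` reactions is COBRA-style: positive flux
#' exports the species, negative flux imports it.
#'
#' @param cell_type `"photoautotroph"` or `"diazotroph"`.
#' @param light_uE Light intensity used to set the default photon-capture
#'   bound (the LIGHT reaction can supply up to `atp_per_uE * light_uE`
#'   mmol ATP gDW^-1 h^-1).
#' @param atp_per_uE ATP yield bound per microEinstein (default 2).
#' @return A [metabolic_network()] that passes the C/N balance audit.
#' @export
build_toy_network <- function(cell_type = c("photoautotroph", "diazotroph"),
                              light_uE = 100, atp_per_uE = 2) {
  cell_type <- match.arg(cell_type)
  rxns <- toy_reaction_list(cell_type, light_ub = atp_per_uE * light_uE)
  mets <- unique(unlist(lapply(rxns, function(r) names(r$stoich))))
  S <- matrix(0, length(mets), length(rxns),
    dimnames = list(mets, names(rxns))
  )
  for (id in names(rxns)) S[names(rxns[[id]]$stoich), id] <- rxns[[id]]$stoich
  lb <- vapply(rxns, function(r) r$bounds[1], numeric(1))
  ub <- vapply(rxns, function(r) r$bounds[2], numeric(1))
  net <- metabolic_network(S, lb, ub,
    biomass_rxn = "BIOMASS",
    metabolite_rxn = if (cell_type == "photoautotroph") "EX_MALT" else "EX_BAA",
    atp_maintenance_rxn = "ATPM"
  )
  audit <- network_element_balance(net)
  if (!audit$balanced) {
    stop(sprintf(
      "toy network construction failed the %s balance audit for reaction '%s'",
      audit$element, audit$reaction
    ))
  }
  net$cell_type <- cell_type
  net
}

#' Audit carbon and nitrogen balance of a network's internal reactions
#'
#' Internal (non-exchange, non-biomass, non-maintenance) reactions must
#' conserve C and N exactly given the lumped elemental composition of the toy
#' species. Exchange reactions and the biomass drain cross the system
#' boundary and are exempt.
#'
#' @param network A [metabolic_network()] whose metabolites appear in
#'   [toy_element_table()].
#' @return A list: `balanced` (logical) plus, when unbalanced, the offending
#'   `reaction` and `element`.
#' @export
network_element_balance <- function(network) {
  internal <- setdiff(
    network$reactions,
    c(
      grep("^EX_", network$reactions, value = TRUE),
      network$biomass_rxn, network$atp_maintenance_rxn
    )
  )
  for (el in c("C", "N")) {
    content <- TOY_ELEMENTS[[el]]
    for (id in internal) {
      col <- network$stoichiometry[, id]
      tot <- sum(col * content[network$metabolites])
      if (abs(tot) > 1e-9) {
        return(list(balanced = FALSE, reaction = id, element = el))
      }
    }
  }
  list(balanced = TRUE, reaction = NA_character_, element = NA_character_)
}

#' Brute-force vertex-enumeration oracle for small flux LPs
#'
#' Enumerates every vertex of the scalarized flux polytope
#' `{(v, t) : S v = 0, v_X = a t, v_m = (1 - a) t, lb <= v <= ub}` by
#' activating bound constraints on all subsets of null-space dimensions, and
#' returns the maximum scalarized objective flux `t` over feasible vertices.
#' Completely independent of the simplex path in [lp_solve()]; used to
#' cross-check [solve_fba()].
#'
#' @param network A [metabolic_network()].
#' @param a Scalarization weight in `[0, 1]` applied to the biomass flux; the
#'   metabolite flux receives `1 - a`.
#' @param extra_bounds Optional named list of `c(lb, ub)` overrides.
#' @param max_free Refuse problems with more free dimensions than this
#'   (default 8): the enumeration is exponential.
#' @return List with `status` (`"optimal"` or `"infeasible"`) and `obj`.
#' @export
lp_vertex_oracle <- function(network, a, extra_bounds = NULL, max_free = 8) {
  S0 <- network$stoichiometry
  n0 <- ncol(S0)
  lb <- unname(network$lower)
  ub <- unname(network$upper)
  for (id in names(extra_bounds)) {
    k <- match(id, network$reactions)
    lb[k] <- extra_bounds[[id]][1]
    ub[k] <- extra_bounds[[id]][2]
  }
  if (any(lb > ub)) {
    return(list(status = "infeasible", obj = NA_real_))
  }
  # augment with the blended-objective flux t and its coupling rows
  iX <- match(network$biomass_rxn, network$reactions)
  im <- match(network$metabolite_rxn, network$reactions)
  S <- rbind(cbind(S0, 0), 0, 0)
  n <- n0 + 1
  S[nrow(S0) + 1, iX] <- 1
  S[nrow(S0) + 1, n] <- -a
  S[nrow(S0) + 2, im] <- 1
  S[nrow(S0) + 2, n] <- -(1 - a)
  t_hi <- 1e6
  if (a > 0) t_hi <- min(t_hi, ub[iX] / a)
  if (a < 1) t_hi <- min(t_hi, ub[im] / (1 - a))
  t_lo <- 0
  if (a > 0) t_lo <- max(t_lo, lb[iX] / a)
  if (a < 1) t_lo <- max(t_lo, lb[im] / (1 - a))
  if (t_lo > t_hi) {
    return(list(status = "infeasible", obj = NA_real_))
  }
  lb <- c(lb, t_lo)
  ub <- c(ub, t_hi)
  cvec <- c(numeric(n0), 1)
  # null space of S: feasible fluxes are v = N z
  sv <- svd(S, nu = 0, nv = n)
  tolr <- max(dim(S)) * max(sv$d) * .Machine$double.eps
  r <- sum(sv$d > tolr)
  if (r == n) {
    # trivial null space: v = 0 is the only candidate
    ok <- all(lb <= 1e-9) && all(ub >= -1e-9)
    return(list(
      status = if (ok) "optimal" else "infeasible",
      obj = if (ok) 0 else NA_real_
    ))
  }
  N <- sv$v[, seq(r + 1, n), drop = FALSE]
  d <- ncol(N)
  if (d > max_free) {
    stop(sprintf("vertex oracle refused: %d free dimensions (max %d)", d, max_free))
  }
  best <- -Inf
  found <- FALSE
  feas_tol <- 1e-9
  combos <- utils::combn(n, d)
  signs <- as.matrix(expand.grid(rep(list(c(0L, 1L)), d)))
  for (ci in seq_len(ncol(combos))) {
    idx <- combos[, ci]
    Nsub <- N[idx, , drop = FALSE]
    if (abs(det(Nsub)) < 1e-12) next
    for (si in seq_len(nrow(signs))) {
      tgt <- ifelse(signs[si, ] == 1L, ub[idx], lb[idx])
      z <- solve(Nsub, tgt)
      v <- as.vector(N %*% z)
      if (all(v >= lb - feas_tol) && all(v <= ub + feas_tol)) {
        found <- TRUE
        val <- sum(cvec * v)
        if (val > best) best <- val
      }
    }
  }
  if (!found) {
    # the polytope may still contain non-vertex points only if it is empty
    # of vertices, which cannot happen for a bounded nonempty polytope
    return(list(status = "infeasible", obj = NA_real_))
  }
  list(status = "optimal", obj = best)
}
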