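# Cell and Filament agents.
#
# Cells hold non-metabolite biomass plus two internal storage pools
# (glycogen tracked as maltose, cyanophycin tracked as beta-aspartyl
# arginine), solve their scalarized FBA each step, and can divide, go
# stationary, or die. Filaments are ordered chains of cells laid out
# horizontally on the ocean grid; they decide the next cell type, develop
# diazocytes, split under nitrogen limitation, and random-walk as rigid
# bodies.

#' Construct a cell agent
#'
#' @param id Integer cell id.
#' @param type `"photoautotroph"` or `"diazotroph"`.
#' @param biomass_g Non-metabolite biomass in grams.
#' @param filament_id Id of the owning filament.
#' @return A `cell_agent` list.
#' @export
cell_agent <- function(id, type, biomass_g, filament_id) {
  stopifnot(type %in% c("photoautotroph", "diazotroph"), biomass_g > 0)
  structure(list(
    id = as.integer(id),
    type = type,
    biomass_g = biomass_g,
    pools = c(MALT = 0, BAA = 0), # mmol
    state = "growing", # growing | stationary | dead
    filament_id = as.integer(filament_id),
    w_b = NA_real_, w_m = NA_real_, z = NA_real_,
    nu_obj = NA_real_, a = NA_real_,
    efficiency = NA_real_
  ), class = "cell_agent")
}

#' Construct a filament agent
#'
#' @param id Integer filament id.
#' @param cell_ids Ordered integer vector of member cell ids.
#' @param origin_row,origin_col Gridcell of the filament's first cell.
#' @return A `filament_agent` list. Cell `k` (1-based along the filament)
#'   occupies gridcell `(origin_row, origin_col + (k-1) %/% cells_per_gridcell)`.
#' @export
filament_agent <- function(id, cell_ids, origin_row, origin_col) {
  structure(list(
    id = as.integer(id),
    cell_ids = as.integer(cell_ids),
    origin_row = as.integer(origin_row),
    origin_col = as.integer(origin_col),
    diazocyte_developing = FALSE,
    diazocyte_end = NA_character_, # "left" | "right"
    growth_blocked = FALSE
  ), class = "filament_agent")
}

#' Metabolite transfer rules
#'
#' Per-metabolite transport behavior: which species cross the cell membrane
#' through an active transporter (full access to the cell's equal share of
#' the local gridcell), which by passive permeation (a fraction of the
#' share), and which not at all (transactional metabolites reach cells only
#' through the filament). Also carries the beta-aspartyl-arginine uptake cap
#' (fraction of locally available amount, default 0.08), membrane leak rates
#' for the storage pools, and the intrafilament exchange rate.
#'
#' @param transporters Named character vector over env species with values
#'   `"active"`, `"passive"`, `"none"`.
#' @param baa_cap Cap fraction in `[0, 1]` for beta-aspartyl-arginine uptake.
#' @param passive_fraction Fraction of the local share accessible per step
#'   by passive permeation.
#' @param membrane_leak_per_h Named leak rates (h^-1) for pool species.
#' @param intrafilament_rate Gradient fraction exchanged between adjacent
#'   cells per step, in `[0, 1]`.
#' @return A `transfer_rules` list.
#' @export
transfer_rules <- function(
    transporters = c(
      CO2 = "active", O2 = "active", N2 = "active",
      NH4 = "passive", MALT = "none", BAA = "none"
    ),
    baa_cap = 0.08,
    passive_fraction = 0.5,
    membrane_leak_per_h = c(MALT = 0.01, BAA = 0.01),
    intrafilament_rate = 0.5) {
  stopifnot(baa_cap >= 0, baa_cap <= 1, passive_fraction >= 0,
            all(membrane_leak_per_h >= 0),
            intrafilament_rate >= 0, intrafilament_rate <= 1)
  structure(list(
    transporters = transporters, baa_cap = baa_cap,
    passive_fraction = passive_fraction,
    membrane_leak_per_h = membrane_leak_per_h,
    intrafilament_rate = intrafilament_rate
  ), class = "transfer_rules")
}

#' Uptake bound overrides from local availability
#'
#' Converts the cell's equal share of locally available metabolites into
#' lower (uptake) bounds on the exchange reactions, in mmol gDW^-1 h^-1:
#' an active transporter exposes the full share, passive permeation a
#' fraction of it, absent transport nothing. The transactional metabolites
#' are sourced from the cell's own storage pools (filled by intrafilament
#' exchange), and beta-aspartyl-arginine uptake is additionally capped at
#' `baa_cap` of the available amount.
#'
#' @param cell A [cell_agent()].
#' @param local_env Named vector of amounts (mmol) allocated to this cell
#'   from its gridcell (its equal partition of each field).
#' @param rules A [transfer_rules()].
#' @param dt_h Time step (h).
#' @return Named list of `c(lb, ub)` overrides for `EX_*` reactions.
#' @export
set_uptake_bounds <- function(cell, local_env, rules, dt_h) {
  stopifnot(cell$state != "dead")
  mass <- cell$biomass_g
  to_flux <- function(amount_mmol) amount_mmol / (mass * dt_h)
  out <- list()
  for (sp in c("CO2", "O2", "N2", "NH4")) {
    avail <- if (sp %in% names(local_env)) local_env[[sp]] else 0
    mode <- rules$transporters[[sp]]
    if (is.null(mode) || mode == "none" || avail <= 0) {
      out[[paste0("EX_", sp)]] <- c(0, Inf)
      next
    }
    acc <- if (mode == "active") avail else rules$passive_fraction * avail
    out[[paste0("EX_", sp)]] <- c(-to_flux(acc), Inf)
  }
  # transactional metabolites: sourced from the cell's own pools
  malt_avail <- cell$pools[["MALT"]]
  baa_avail <- cell$pools[["BAA"]]
  out[["EX_MALT"]] <- c(-to_flux(malt_avail), Inf)
  out[["EX_BAA"]] <- c(-to_flux(rules$baa_cap * baa_avail), Inf)
  out
}

#' Advance one cell by one time step
#'
#' The per-step metabolic decision, in order: (1) re-weight the objective
#' from the cell's biomass (stationary cells are pinned to the pure
#' metabolite objective); (2) solve the scalarized FBA with the ATP
#' maintenance flux pinned to the light-dependent demand at the cell's
#' depth; (3) if infeasible, retry once allowing catabolism of the cell's
#' own storage pool without the uptake cap, and mark the cell dead if still
#' infeasible; (4) integrate biomass and pools forward by `dt_h` (Euler);
#' (5) return the exchange amounts to apply to the environment.
#'
#' @param cell A [cell_agent()].
#' @param network The cell type's [metabolic_network()].
#' @param front The type's precomputed `pareto_front` (weight matching).
#' @param local_env Named vector of amounts (mmol) allocated to this cell.
#' @param I_local Light intensity at the cell's depth (uE).
#' @param model A [maintenance_model()].
#' @param dist A [mass_distribution()].
#' @param rules A [transfer_rules()].
#' @param dt_h Time step (h).
#' @param base_weights Pareto-matched base [objective_weights()].
#' @param exp_optima Named experimental optima for [pareto_efficiency()].
#' @param tie_break Passed to [solve_fba()].
#' @return List with the updated `cell`, `env_delta` (named mmol changes for
#'   the cell's gridcell) and `died` flag.
#' @export
cell_step <- function(cell, network, front, local_env, I_local, model, dist,
                      rules, dt_h, base_weights, exp_optima,
                      tie_break = FALSE) {
  if (cell$state == "dead") {
    return(list(cell = cell, env_delta = numeric(0), died = FALSE))
  }
  # (1) objective weights from biomass
  if (cell$state == "stationary") {
    w <- objective_weights(0, 1, normalize = FALSE)
    z <- 1
  } else {
    matched <- match_pareto_point(front, base_weights)
    base <- objective_weights(matched$a, 1 - matched$a, normalize = FALSE)
    w <- shift_weights(base, cell$biomass_g, dist)
    z <- cumulative_mass_probability(cell$biomass_g, dist)
  }
  # (2) maintenance-pinned scalarized FBA
  maint <- maintenance_flux(I_local, model, cell$type)
  bounds <- set_uptake_bounds(cell, local_env, rules, dt_h)
  bounds <- bounds[names(bounds) %in% network$reactions]
  sol <- solve_fba(network, w$w_b, maintenance = maint,
                   extra_bounds = bounds, tie_break = tie_break)
  if (sol$status != "optimal") {
    # (3) catabolism: full access to the cell's own storage pool
    mass <- cell$biomass_g
    pool_rxn <- if (cell$type == "photoautotroph") "EX_BAA" else "EX_MALT"
    pool_sp <- if (cell$type == "photoautotroph") "BAA" else "MALT"
    bounds[[pool_rxn]] <- c(-cell$pools[[pool_sp]] / (mass * dt_h), Inf)
    sol <- solve_fba(network, w$w_b, maintenance = maint,
                     extra_bounds = bounds, tie_break = tie_break)
    if (sol$status != "optimal") {
      cell$state <- "dead"
      cell$w_b <- w$w_b
      cell$w_m <- w$w_m
      cell$z <- z
      cell$nu_obj <- NA_real_
      return(list(cell = cell, env_delta = numeric(0), died = TRUE))
    }
  }
  # (4) Euler integration of biomass and pools
  mass <- cell$biomass_g
  dec <- decompose_objective_flux(sol$a, sol$objective_value)
  if (cell$state == "growing") {
    cell$biomass_g <- mass * (1 + dec[["mu"]] * dt_h)
  }
  v <- sol$fluxes
  env_delta <- c(CO2 = 0, O2 = 0, N2 = 0, NH4 = 0, MALT = 0, BAA = 0)
  for (sp in c("CO2", "O2", "N2", "NH4")) {
    rx <- paste0("EX_", sp)
    if (rx %in% names(v)) env_delta[[sp]] <- v[[rx]] * mass * dt_h
  }
  for (sp in c("MALT", "BAA")) {
    rx <- paste0("EX_", sp)
    if (rx %in% names(v)) {
      cell$pools[[sp]] <- max(0, cell$pools[[sp]] + v[[rx]] * mass * dt_h)
    }
  }
  # membrane leakage of storage pools to the environment
  for (sp in names(rules$membrane_leak_per_h)) {
    leak <- cell$pools[[sp]] * rules$membrane_leak_per_h[[sp]] * dt_h
    cell$pools[[sp]] <- cell$pools[[sp]] - leak
    env_delta[[sp]] <- env_delta[[sp]] + leak
  }
  cell$w_b <- w$w_b
  cell$w_m <- w$w_m
  cell$z <- z
  cell$nu_obj <- sol$objective_value
  cell$a <- sol$a
  cell$efficiency <- pareto_efficiency(sol, exp_optima)
  list(cell = cell, env_delta = env_delta, died = FALSE)
}

#' Division decision for one cell
#'
#' Draws a threshold mass from the (zero-truncated) cell mass distribution;
#' the cell divides iff its biomass reaches the draw *and* it sits at a
#' filament end (filaments extend only from their ends). Division halves
#' biomass and both pools between parent and daughter. The decision is
#' memoryless: a fresh draw every step.
#'
#' @param cell A [cell_agent()].
#' @param dist A [mass_distribution()].
#' @param at_end Is the cell at a filament end with room to extend?
#' @param daughter_type Cell type assigned to the daughter (from
#'   [decide_next_cell_type()] at the filament level).
#' @param next_id Id for the daughter cell.
#' @return `NULL` if no division; otherwise list with updated `parent` and
#'   new `daughter`.
#' @export
maybe_divide <- function(cell, dist, at_end, daughter_type, next_id) {
  if (cell$state != "growing" || !at_end) {
    return(NULL)
  }
  threshold <- sample_division_threshold(dist)
  if (cell$biomass_g < threshold) {
    return(NULL)
  }
  daughter <- cell_agent(next_id, daughter_type,
                         cell$biomass_g / 2, cell$filament_id)
  daughter$pools <- cell$pools / 2
  cell$biomass_g <- cell$biomass_g / 2
  cell$pools <- cell$pools / 2
  list(parent = cell, daughter = daughter)
}

#' Stationary-phase transition
#'
#' A growing cell converts (one-way) to stationary growth once its biomass
#' reaches twice the distribution mean: it then produces only metabolites,
#' with no further de novo biomass synthesis.
#'
#' @param cell A [cell_agent()].
#' @param dist A [mass_distribution()].
#' @return The (possibly updated) cell.
#' @export
maybe_go_stationary <- function(cell, dist) {
  if (cell$state == "growing" && cell$biomass_g >= 2 * dist$mean) {
    cell$state <- "stationary"
  }
  cell
}

#' Decide the preferred type of the next cell in a filament
#'
#' Compares the mean Pareto efficiency of the filament's diazotrophs with
#' that of its photoautotrophs: a strictly greater diazotroph mean
#' prioritizes diazotroph development, ties go to the photoautotroph. A
#' filament left homogeneous (e.g. after a split) prefers the missing cell
#' type.
#'
#' @param filament A [filament_agent()].
#' @param cells Named list of all cell agents (names are ids).
#' @return `"photoautotroph"` or `"diazotroph"`.
#' @export
decide_next_cell_type <- function(filament, cells) {
  members <- cells[as.character(filament$cell_ids)]
  if (length(members) == 0) stop("empty filament")
  types <- vapply(members, function(c) c$type, character(1))
  eff <- vapply(members, function(c) {
    if (is.na(c$efficiency)) 0 else c$efficiency
  }, numeric(1))
  n_dz <- sum(types == "diazotroph")
  n_pa <- sum(types == "photoautotroph")
  if (n_dz == 0) {
    return("diazotroph")
  }
  if (n_pa == 0) {
    return("photoautotroph")
  }
  mean_dz <- mean(eff[types == "diazotroph"])
  mean_pa <- mean(eff[types == "photoautotroph"])
  if (mean_dz > mean_pa) "diazotroph" else "photoautotroph"
}

filament_cn_ratio <- function(filament, cells) {
  members <- cells[as.character(filament$cell_ids)]
  el <- toy_element_table()
  ctot <- 0
  ntot <- 0
  for (cl in members) {
    ctot <- ctot + el$biomass_C * cl$biomass_g +
      el$C[["MALT"]] * cl$pools[["MALT"]] + el$C[["BAA"]] * cl$pools[["BAA"]]
    ntot <- ntot + el$biomass_N * cl$biomass_g +
      el$N[["BAA"]] * cl$pools[["BAA"]]
  }
  if (ntot <= 0) {
    return(Inf)
  }
  ctot / ntot
}

filament_nitrogen_limited <- function(filament, cells, baa_reference,
                                      n_limit_fraction) {
  members <- cells[as.character(filament$cell_ids)]
  mean_baa <- mean(vapply(members, function(c) c$pools[["BAA"]], numeric(1)))
  mean_baa < n_limit_fraction * baa_reference
}

longest_homogeneous_run <- function(types) {
  r <- rle(types)
  k <- which.max(r$lengths)
  start <- if (k == 1) 1L else sum(r$lengths[seq_len(k - 1)]) + 1L
  c(start = start, length = unname(r$lengths[k]))
}

#' Split a filament when nitrogen limitation demands a new diazocyte
#'
#' A filament of length >= 4 splits into two when (a) nitrogen is limiting
#' growth and no diazocyte is under development at either end, or (b) its
#' C:N ratio exceeds the physiological bound. The cut falls in the middle of
#' the longest homogeneous run of cell types, clamped so both products keep
#' at least two cells; cell order is preserved.
#'
#' @param filament A [filament_agent()].
#' @param cells Named list of all cell agents.
#' @param baa_reference Reference cyanophycin pool (mmol) defining nitrogen
#'   sufficiency.
#' @param n_limit_fraction Fraction of `baa_reference` below which the
#'   filament counts as nitrogen limited.
#' @param cn_upper Upper physiological C:N bound.
#' @param new_id Id for the second filament product.
#' @param cells_per_gridcell Cells per gridcell (for the new origin).
#' @return `NULL` (no split) or a list of the two resulting filaments.
#' @export
maybe_split <- function(filament, cells, baa_reference, n_limit_fraction,
                        cn_upper, new_id, cells_per_gridcell = 10) {
  len <- length(filament$cell_ids)
  if (len < 4) {
    return(NULL)
  }
  nlim <- filament_nitrogen_limited(filament, cells, baa_reference,
                                    n_limit_fraction)
  cn <- filament_cn_ratio(filament, cells)
  trigger <- (nlim && !filament$diazocyte_developing) || (cn > cn_upper)
  if (!trigger) {
    return(NULL)
  }
  members <- cells[as.character(filament$cell_ids)]
  types <- vapply(members, function(c) c$type, character(1))
  run <- longest_homogeneous_run(types)
  cut <- run[["start"]] - 1L + as.integer(ceiling(run[["length"]] / 2))
  cut <- min(max(cut, 2L), len - 2L)
  left <- filament
  left$cell_ids <- filament$cell_ids[seq_len(cut)]
  left$diazocyte_developing <- FALSE
  left$diazocyte_end <- NA_character_
  right <- filament_agent(
    new_id, filament$cell_ids[(cut + 1L):len],
    filament$origin_row,
    filament$origin_col + (cut %/% cells_per_gridcell)
  )
  list(left, right)
}

filament_gridcells <- function(filament, cells_per_gridcell = 10) {
  len <- length(filament$cell_ids)
  ncellgrid <- ((len - 1L) %/% cells_per_gridcell) + 1L
  data.frame(
    row = rep(filament$origin_row, ncellgrid),
    col = filament$origin_col + seq_len(ncellgrid) - 1L
  )
}

#' Rigid random-walk movement of a filament
#'
#' Draws one of the four grid directions uniformly and translates the whole
#' filament if and only if every target gridcell lies on the grid and is
#' free of other filaments (all-or-nothing move).
#'
#' @param filament A [filament_agent()].
#' @param occupancy Integer matrix of filament ids (0 = free).
#' @param width,height Grid dimensions.
#' @param cells_per_gridcell Cells per gridcell.
#' @return List with the (possibly moved) `filament` and `moved` flag.
#' @export
random_walk <- function(filament, occupancy, width, height,
                        cells_per_gridcell = 10) {
  dirs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  d <- dirs[[sample.int(4, 1)]]
  cellsg <- filament_gridcells(filament, cells_per_gridcell)
  nr <- cellsg$row + d[1]
  nc <- cellsg$col + d[2]
  ok <- all(nr >= 1 & nr <= height & nc >= 1 & nc <= width)
  if (ok) {
    occ <- occupancy[cbind(nr, nc)]
    ok <- all(occ == 0 | occ == filament$id)
  }
  if (!ok) {
    return(list(filament = filament, moved = FALSE))
  }
  filament$origin_row <- filament$origin_row + d[1]
  filament$origin_col <- filament$origin_col + d[2]
  list(filament = filament, moved = TRUE)
}

#' Gradient-driven exchange of storage pools along a filament
#'
#' Maltose and beta-aspartyl arginine diffuse freely between adjacent cells
#' of a filament: each adjacent pair exchanges `rate/2 * (p_i - p_{i+1})`
#' per step. Total filament inventory of each species is conserved exactly;
#' with equal pools there is no net transfer, and repeated application
#' equilibrates the chain.
#'
#' @param filament A [filament_agent()].
#' @param cells Named list of all cell agents.
#' @param rules A [transfer_rules()].
#' @return The updated `cells` list.
#' @export
intrafilament_exchange <- function(filament, cells, rules) {
  ids <- as.character(filament$cell_ids)
  alive <- ids[vapply(cells[ids], function(c) c$state != "dead", logical(1))]
  if (length(alive) < 2) {
    return(cells)
  }
  rate <- rules$intrafilament_rate
  for (sp in c("MALT", "BAA")) {
    p <- vapply(cells[alive], function(c) c$pools[[sp]], numeric(1))
    for (i in seq_len(length(p) - 1L)) {
      flow <- rate / 2 * (p[i] - p[i + 1L])
      p[i] <- p[i] - flow
      p[i + 1L] <- p[i + 1L] + flow
    }
    for (i in seq_along(alive)) cells[[alive[i]]]$pools[[sp]] <- p[i]
  }
  cells
}
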