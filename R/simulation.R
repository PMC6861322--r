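# Scheduler and driver: binds the ocean grid, the filament/cell agents and
# the metabolic core into a deterministic time-stepping loop with CSV
# logging.
#
# Stage order within a step is fixed: (1) atmospheric surface exchange;
# (2) kernel diffusion of every tracked species; (3) filament-level
# decisions (diazocyte development, splitting, movement); (4) per-cell
# metabolic steps in a seeded random order (division and stationary
# transitions included); (5) logging. One global RNG seed is split into
# named substreams (scheduling, division, movement) so features do not
# perturb each other's draws.

ENV_SPECIES <- c("CO2", "O2", "N2", "NH4", "MALT", "BAA")
ATM_GASES <- c("CO2", "O2", "N2")

#' Build a simulation configuration
#'
#' All defaults come from the packaged parameter table
#' ([default_parameters()]): 0.1 h steps, a 25 x 25 grid of 100 um
#' gridcells, 100 uE surface light, 150 cells over 10 filaments at a 3:7
#' diazotroph:photoautotroph ratio, YBC-II-like initial nutrient fields and
#' atmospheric partial pressures.
#'
#' @param n_steps Number of time steps to run.
#' @param seed Integer RNG seed.
#' @param dt_h Time step (h).
#' @param grid_width,grid_height Grid dimensions (gridcells).
#' @param delta_um Gridcell edge (um).
#' @param I0_uE Surface light intensity (uE).
#' @param k_ext Light extinction coefficient (m^-1).
#' @param n_cells,n_filaments Seeding layout.
#' @param dz_fraction Diazotroph fraction of seeded cells, in `[0, 1)`.
#' @param atp_per_uE Photon-capture bound of the toy networks.
#' @param base_weights Length-2 base objective weights `(w_b, w_m)`.
#' @param front_steps Resolution of the cached Pareto fronts.
#' @param movement_interval_steps Steps between random-walk moves.
#' @param tie_break Use the lexicographic minimum-|flux| tie-break in every
#'   cell solve (slower; defaults to `FALSE` for simulation runs).
#' @param surface_exchange Enable atmospheric exchange (disable to audit
#'   closed-system mass conservation).
#' @param snapshot_every Record a grid snapshot every this many steps
#'   (0 = only first/last).
#' @param rules A [transfer_rules()].
#' @param init_fields Named initial concentrations (uM); defaults packaged.
#' @param out_dir Output directory for [run_simulation()] artifacts (`NULL`
#'   for no file output).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_steps = 120,
                              seed = 1L,
                              dt_h = param_value("dt_h"),
                              grid_width = param_value("grid_width"),
                              grid_height = param_value("grid_height"),
                              delta_um = param_value("grid_delta_um"),
                              I0_uE = param_value("light_I0_uE"),
                              k_ext = param_value("light_extinction_m"),
                              n_cells = param_value("n_cells"),
                              n_filaments = param_value("n_filaments"),
                              dz_fraction = param_value("diazotroph_fraction"),
                              atp_per_uE = param_value("atp_per_uE"),
                              base_weights = c(0.5, 0.5),
                              front_steps = 201,
                              movement_interval_steps =
                                param_value("movement_interval_steps"),
                              tie_break = FALSE,
                              surface_exchange = TRUE,
                              snapshot_every = 0,
                              rules = transfer_rules(),
                              init_fields = NULL,
                              out_dir = NULL) {
  stopifnot(dt_h > 0, n_steps >= 0, dz_fraction >= 0, dz_fraction < 1)
  if (n_filaments == 0 || n_cells == 0) {
    if (n_filaments != 0 || n_cells != 0) {
      stop("infeasible seeding: cells and filaments must both be zero or both positive")
    }
  } else if (n_cells < 2 * n_filaments) {
    stop("infeasible seeding: every filament needs at least two cells")
  }
  if (is.null(init_fields)) {
    init_fields <- param_table("initial_fields_uM")
  }
  structure(list(
    n_steps = as.integer(n_steps), seed = as.integer(seed), dt_h = dt_h,
    grid_width = grid_width, grid_height = grid_height, delta_um = delta_um,
    I0_uE = I0_uE, k_ext = k_ext,
    n_cells = n_cells, n_filaments = n_filaments, dz_fraction = dz_fraction,
    atp_per_uE = atp_per_uE, base_weights = base_weights,
    front_steps = front_steps,
    movement_interval_steps = movement_interval_steps,
    tie_break = tie_break, surface_exchange = surface_exchange,
    snapshot_every = snapshot_every, rules = rules,
    init_fields = init_fields,
    cells_per_gridcell = param_value("cells_per_gridcell"),
    baa_reference = param_value("baa_pool_reference_mmol"),
    n_limit_fraction = param_value("n_limit_fraction"),
    cn_bounds = param_value("cn_bounds"),
    out_dir = out_dir
  ), class = "simulation_config")
}

# --- seeded RNG substreams -------------------------------------------------

make_streams <- function(seed, names = c("scheduling", "division", "movement")) {
  streams <- list()
  for (i in seq_along(names)) {
    set.seed((seed + i * 7919L) %% .Machine$integer.max)
    streams[[names[i]]] <- get(".Random.seed", envir = globalenv())
  }
  streams
}

# Run fun() under the named substream, returning its value and the advanced
# stream state; the ambient RNG state is untouched.
use_stream <- function(streams, name, fun) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  prev <- if (had) get(".Random.seed", envir = genv) else NULL
  assign(".Random.seed", streams[[name]], envir = genv)
  value <- fun()
  streams[[name]] <- get(".Random.seed", envir = genv)
  if (had) assign(".Random.seed", prev, envir = genv)
  list(value = value, streams = streams)
}

# --- seeding ---------------------------------------------------------------

largest_remainder <- function(total, weights) {
  ideal <- total * weights / sum(weights)
  base <- floor(ideal)
  short <- total - sum(base)
  if (short > 0) {
    ord <- order(ideal - base, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

#' Seed the initial cell population
#'
#' Distributes `n_cells` over `n_filaments` of (near-)equal length with any
#' remainder spread deterministically, assigns diazotrophs as contiguous
#' interior runs sized by `dz_fraction` (largest-remainder apportionment
#' across filaments), places the filaments horizontally on distinct rows,
#' and gives every cell the mean biomass of the mass distribution. Fully
#' reproducible from the configuration seed.
#'
#' @param config A [simulation_config()].
#' @param dist A [mass_distribution()].
#' @return List with `cells` (named list of [cell_agent()]) and `filaments`.
#' @export
seed_population <- function(config, dist = mass_distribution()) {
  nf <- config$n_filaments
  if (nf == 0) {
    return(list(cells = list(), filaments = list()))
  }
  lens <- rep(config$n_cells %/% nf, nf)
  rem <- config$n_cells %% nf
  if (rem > 0) lens[seq_len(rem)] <- lens[seq_len(rem)] + 1
  if (any(lens < 2)) stop("infeasible seeding: filament shorter than 2 cells")
  n_dz_total <- round(config$n_cells * config$dz_fraction)
  dz_counts <- largest_remainder(n_dz_total, lens)
  if (any(dz_counts >= lens)) {
    stop("infeasible seeding: a filament would be all diazotrophs")
  }
  cpg <- config$cells_per_gridcell
  rows <- pmin(
    config$grid_height,
    pmax(1, round(seq_len(nf) * config$grid_height / (nf + 1)))
  )
  cells <- list()
  filaments <- list()
  next_cell <- 1L
  for (i in seq_len(nf)) {
    len <- lens[i]
    k <- dz_counts[i]
    dz_start <- (len - k) %/% 2 + 1L
    types <- rep("photoautotroph", len)
    if (k > 0) types[dz_start:(dz_start + k - 1L)] <- "diazotroph"
    ids <- next_cell:(next_cell + len - 1L)
    next_cell <- next_cell + len
    ngrid <- ((len - 1L) %/% cpg) + 1L
    if (ngrid > config$grid_width) {
      stop("infeasible seeding: filament longer than the grid")
    }
    origin_col <- max(1L, (config$grid_width - ngrid) %/% 2 + 1L)
    fil <- filament_agent(i, ids, rows[i], origin_col)
    filaments[[as.character(i)]] <- fil
    for (j in seq_along(ids)) {
      cells[[as.character(ids[j])]] <-
        cell_agent(ids[j], types[j], dist$mean, i)
    }
  }
  list(cells = cells, filaments = filaments)
}

# --- world -----------------------------------------------------------------

#' Initialize a simulation world
#'
#' Builds the ocean grid, seeds the population, generates and caches the
#' per-type Pareto fronts under replete default bounds, and derives the
#' per-type experimental optima (the decomposed objective fluxes at the
#' balanced point `a = 0.5`) used for Pareto-efficiency scoring.
#'
#' @param config A [simulation_config()].
#' @return A `world` list.
#' @export
init_world <- function(config) {
  dist <- mass_distribution()
  model <- maintenance_model("printed")
  diff_tab <- param_table("diffusivities_um2_s")
  grid <- ocean_grid(config$grid_width, config$grid_height,
    delta_um = config$delta_um, dt_h = config$dt_h,
    diffusivities = diff_tab[ENV_SPECIES],
    init = config$init_fields
  )
  boundary <- surface_boundary(
    param_table("partial_pressures_atm"),
    param_table("henry_constants_uM_atm")
  )
  networks <- list(
    photoautotroph = build_toy_network("photoautotroph",
      light_uE = config$I0_uE, atp_per_uE = config$atp_per_uE
    ),
    diazotroph = build_toy_network("diazotroph",
      light_uE = config$I0_uE, atp_per_uE = config$atp_per_uE
    )
  )
  fronts <- list()
  exp_optima <- list()
  for (ct in names(networks)) {
    maint <- maintenance_flux(config$I0_uE, model, ct)
    fronts[[ct]] <- generate_pareto_front(networks[[ct]],
      steps = config$front_steps, maintenance = maint
    )
    mid <- fronts[[ct]][which.min(abs(fronts[[ct]]$a - 0.5)), ]
    nu_x <- max(mid$nu_X, 1e-6)
    nu_m <- max(mid$nu_m, 1e-6)
    eo <- c(nu_x, nu_m)
    names(eo) <- c(
      networks[[ct]]$biomass_rxn,
      networks[[ct]]$metabolite_rxn
    )
    exp_optima[[ct]] <- eo
  }
  pop <- seed_population(config, dist)
  structure(list(
    config = config, dist = dist, model = model,
    grid = grid, boundary = boundary,
    networks = networks, fronts = fronts, exp_optima = exp_optima,
    cells = pop$cells, filaments = pop$filaments,
    streams = make_streams(config$seed),
    step_index = 0L,
    next_cell_id = length(pop$cells) + 1L,
    next_filament_id = length(pop$filaments) + 1L,
    cell_log = list(), event_log = list(), snapshots = list()
  ), class = "world")
}

occupancy_matrix <- function(world) {
  occ <- matrix(0L, world$grid$height, world$grid$width)
  for (fil in world$filaments) {
    g <- filament_gridcells(fil, world$config$cells_per_gridcell)
    occ[cbind(g$row, g$col)] <- fil$id
  }
  occ
}

cell_position <- function(world, cell) {
  fil <- world$filaments[[as.character(cell$filament_id)]]
  k <- match(cell$id, fil$cell_ids)
  cpg <- world$config$cells_per_gridcell
  c(row = fil$origin_row, col = fil$origin_col + (k - 1L) %/% cpg)
}

gridcell_volume_L <- function(grid) grid$delta_um^3 * 1e-15

conc_to_mmol <- function(conc_uM, grid) {
  conc_uM * gridcell_volume_L(grid) * 1e-3
}

mmol_to_conc <- function(amount_mmol, grid) {
  amount_mmol / (gridcell_volume_L(grid) * 1e-3)
}

#' Total carbon and nitrogen inventory of the world
#'
#' Sums element content over cell biomass, storage pools and every grid
#' field. On a closed system (surface exchange disabled) both totals are
#' invariant under [step_world()] up to LP tolerance.
#'
#' @param world A `world` from [init_world()].
#' @return Named vector `c(C = ..., N = ...)` in mmol.
#' @export
world_element_totals <- function(world) {
  el <- toy_element_table()
  ctot <- 0
  ntot <- 0
  for (cl in world$cells) {
    ctot <- ctot + el$biomass_C * cl$biomass_g +
      el$C[["MALT"]] * cl$pools[["MALT"]] + el$C[["BAA"]] * cl$pools[["BAA"]]
    ntot <- ntot + el$biomass_N * cl$biomass_g +
      el$N[["BAA"]] * cl$pools[["BAA"]]
  }
  for (sp in names(world$grid$fields)) {
    amt <- conc_to_mmol(sum(world$grid$fields[[sp]]), world$grid)
    ctot <- ctot + el$C[[sp]] * amt
    ntot <- ntot + el$N[[sp]] * amt
  }
  c(C = ctot, N = ntot)
}

# --- the step --------------------------------------------------------------

filament_stage <- function(world) {
  cfg <- world$config
  ids <- names(world$filaments)
  for (fid in ids) {
    fil <- world$filaments[[fid]]
    if (is.null(fil)) next
    nlim <- filament_nitrogen_limited(
      fil, world$cells, cfg$baa_reference, cfg$n_limit_fraction
    )
    cn <- filament_cn_ratio(fil, world$cells)
    if (nlim && !fil$diazocyte_developing) {
      fil$diazocyte_developing <- TRUE
      fil$diazocyte_end <- "right"
    } else if (fil$diazocyte_developing &&
               cn <= cfg$cn_bounds[2] && !nlim) {
      # development region closes once the filament-level C:N recovers
      fil$diazocyte_developing <- FALSE
      fil$diazocyte_end <- NA_character_
    }
    split <- maybe_split(
      fil, world$cells, cfg$baa_reference, cfg$n_limit_fraction,
      cfg$cn_bounds[2], world$next_filament_id, cfg$cells_per_gridcell
    )
    if (!is.null(split)) {
      world$next_filament_id <- world$next_filament_id + 1L
      world$filaments[[fid]] <- split[[1]]
      world$filaments[[as.character(split[[2]]$id)]] <- split[[2]]
      for (cid in split[[2]]$cell_ids) {
        world$cells[[as.character(cid)]]$filament_id <- split[[2]]$id
      }
      world$event_log[[length(world$event_log) + 1L]] <- data.frame(
        step = world$step_index, event = "split",
        filament_id = fil$id, detail = split[[2]]$id
      )
      fil <- world$filaments[[fid]]
    }
    if (cfg$movement_interval_steps > 0 &&
        world$step_index %% cfg$movement_interval_steps == 0L) {
      occ <- occupancy_matrix(world)
      res <- use_stream(world$streams, "movement", function() {
        random_walk(fil, occ, world$grid$width, world$grid$height,
                    cfg$cells_per_gridcell)
      })
      world$streams <- res$streams
      world$filaments[[fid]] <- res$value$filament
      if (res$value$moved) {
        world$event_log[[length(world$event_log) + 1L]] <- data.frame(
          step = world$step_index, event = "move",
          filament_id = fil$id, detail = NA_integer_
        )
      }
    }
    # growth blocked while another filament occupies the extension site
    fil <- world$filaments[[fid]]
    occ <- occupancy_matrix(world)
    g <- filament_gridcells(fil, cfg$cells_per_gridcell)
    len <- length(fil$cell_ids)
    ext_col <- fil$origin_col + (len %/% cfg$cells_per_gridcell)
    blocked <- FALSE
    if (ext_col > world$grid$width) {
      blocked <- TRUE
    } else if (ext_col > max(g$col)) {
      other <- occ[fil$origin_row, ext_col]
      blocked <- other != 0L && other != fil$id
    }
    world$filaments[[fid]]$growth_blocked <- blocked
    world$cells <- intrafilament_exchange(fil, world$cells, cfg$rules)
  }
  world
}

compute_allocations <- function(world) {
  cfg <- world$config
  alive <- Filter(function(c) c$state != "dead", world$cells)
  if (length(alive) == 0) {
    return(list())
  }
  pos <- t(vapply(alive, function(c) cell_position(world, c), numeric(2)))
  key <- paste(pos[, 1], pos[, 2], sep = ",")
  alloc <- stats::setNames(
    rep(list(numeric(0)), length(alive)),
    vapply(alive, function(c) as.character(c$id), character(1))
  )
  for (gk in unique(key)) {
    members <- which(key == gk)
    rc <- as.integer(strsplit(gk, ",")[[1]])
    for (sp in c("CO2", "O2", "N2", "NH4")) {
      avail <- conc_to_mmol(world$grid$fields[[sp]][rc[1], rc[2]], world$grid)
      # demand: each cell could draw up to its network uptake capacity
      demands <- vapply(members, function(mi) {
        cl <- alive[[mi]]
        net <- world$networks[[cl$type]]
        rx <- paste0("EX_", sp)
        cap <- if (rx %in% net$reactions) max(0, -net$lower[[rx]]) else 0
        cap * cl$biomass_g * cfg$dt_h
      }, numeric(1))
      shares <- partition_uptake(avail, demands)
      for (j in seq_along(members)) {
        cid <- as.character(alive[[members[j]]]$id)
        alloc[[cid]][[sp]] <- shares[j]
      }
    }
  }
  alloc
}

cell_stage <- function(world) {
  cfg <- world$config
  alloc <- compute_allocations(world)
  ids <- names(world$cells)
  res <- use_stream(world$streams, "scheduling", function() sample(ids))
  world$streams <- res$streams
  order_ids <- res$value
  delta_m <- world$grid$delta_um * 1e-6
  for (cid in order_ids) {
    cell <- world$cells[[cid]]
    if (is.null(cell) || cell$state == "dead") next
    fil <- world$filaments[[as.character(cell$filament_id)]]
    pos <- cell_position(world, cell)
    depth_m <- (pos[["row"]] - 0.5) * delta_m
    I_local <- light_at_depth(cfg$I0_uE, cfg$k_ext, depth_m)
    la <- alloc[[cid]]
    if (is.null(la)) la <- numeric(0)
    net <- world$networks[[cell$type]]
    out <- cell_step(
      cell, net, world$fronts[[cell$type]], la, I_local,
      world$model, world$dist, cfg$rules, cfg$dt_h,
      objective_weights(cfg$base_weights[1], cfg$base_weights[2]),
      world$exp_optima[[cell$type]],
      tie_break = cfg$tie_break
    )
    cell <- out$cell
    divided <- FALSE
    if (out$died) {
      world$event_log[[length(world$event_log) + 1L]] <- data.frame(
        step = world$step_index, event = "death",
        filament_id = cell$filament_id, detail = cell$id
      )
    } else {
      # apply exchange amounts to the cell's gridcell
      for (sp in names(out$env_delta)) {
        d <- out$env_delta[[sp]]
        if (d != 0) {
          f <- world$grid$fields[[sp]]
          f[pos[["row"]], pos[["col"]]] <-
            max(0, f[pos[["row"]], pos[["col"]]] + mmol_to_conc(d, world$grid))
          world$grid$fields[[sp]] <- f
        }
      }
      cell <- maybe_go_stationary(cell, world$dist)
      # division: only end cells extend, and only when not blocked
      k <- match(cell$id, fil$cell_ids)
      at_end <- k == 1L || k == length(fil$cell_ids)
      if (at_end && !fil$growth_blocked && cell$state == "growing") {
        pref <- decide_next_cell_type(fil, world$cells)
        daughter_type <- if (pref == "diazotroph" && fil$diazocyte_developing) {
          "diazotroph"
        } else if (pref == "diazotroph" && !fil$diazocyte_developing) {
          "photoautotroph"
        } else {
          pref
        }
        res <- use_stream(world$streams, "division", function() {
          maybe_divide(cell, world$dist, TRUE, daughter_type,
                       world$next_cell_id)
        })
        world$streams <- res$streams
        if (!is.null(res$value)) {
          divided <- TRUE
          cell <- res$value$parent
          daughter <- res$value$daughter
          world$cells[[as.character(daughter$id)]] <- daughter
          world$next_cell_id <- world$next_cell_id + 1L
          fil$cell_ids <- if (k == 1L) {
            c(daughter$id, fil$cell_ids)
          } else {
            c(fil$cell_ids, daughter$id)
          }
          world$filaments[[as.character(fil$id)]] <- fil
          world$event_log[[length(world$event_log) + 1L]] <- data.frame(
            step = world$step_index, event = "division",
            filament_id = fil$id, detail = daughter$id
          )
        }
      }
    }
    world$cells[[cid]] <- cell
    world$cell_log[[length(world$cell_log) + 1L]] <- data.frame(
      step = world$step_index, cell_id = cell$id,
      filament_id = cell$filament_id, type = cell$type, state = cell$state,
      biomass_g = cell$biomass_g,
      maltose_mmol = cell$pools[["MALT"]],
      cyanophycin_mmol = cell$pools[["BAA"]],
      w_b = cell$w_b, w_m = cell$w_m, z = cell$z,
      nu_obj = cell$nu_obj,
      died = out$died, divided = divided
    )
  }
  world
}

#' Advance the world by one time step
#'
#' Runs the five scheduler stages in their fixed order (surface exchange,
#' diffusion, filament decisions, cell steps in seeded random order,
#' logging). Deterministic given the configuration seed.
#'
#' @param world A `world` from [init_world()].
#' @return The updated world.
#' @export
step_world <- function(world) {
  world$step_index <- world$step_index + 1L
  step_i <- world$step_index
  tryCatch({
    if (world$config$surface_exchange) {
      for (gas in ATM_GASES) {
        world$grid <- surface_exchange(world$grid, world$boundary, gas)
      }
    }
    for (sp in names(world$grid$fields)) {
      world$grid <- diffusion_step(world$grid, sp)
    }
    world <- filament_stage(world)
    world <- cell_stage(world)
    snap <- world$config$snapshot_every
    if (snap > 0 && step_i %% snap == 0L) {
      world$snapshots[[length(world$snapshots) + 1L]] <-
        grid_snapshot(world$grid, step_i)
    }
    world
  }, error = function(e) {
    stop(sprintf("simulation failed at step %d: %s", step_i,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run a configured simulation
#'
#' Initializes the world, advances it `n_steps` steps and assembles the
#' run log. When `config$out_dir` is set, writes `cells.csv` (per-step cell
#' log), `events.csv`, `grid.csv` (snapshots of the concentration fields)
#' and `manifest.json` (config, seed, package version); logs are flushed
#' per run.
#'
#' @param config A [simulation_config()].
#' @param quiet Suppress per-step progress messages (default `TRUE`).
#' @return A `run_log`: list with `cell_log`, `event_log`, `summary` (one
#'   row per step), `snapshots`, and the final `world`.
#' @export
run_simulation <- function(config, quiet = TRUE) {
  world <- init_world(config)
  world$snapshots[[1]] <- grid_snapshot(world$grid, 0L)
  for (i in seq_len(config$n_steps)) {
    world <- step_world(world)
    if (!quiet) {
      message(sprintf("[step %d/%d] cells=%d", i, config$n_steps,
                      length(world$cells)))
    }
  }
  world$snapshots[[length(world$snapshots) + 1L]] <-
    grid_snapshot(world$grid, world$step_index)
  cell_log <- if (length(world$cell_log)) {
    do.call(rbind, world$cell_log)
  } else {
    data.frame()
  }
  event_log <- if (length(world$event_log)) {
    do.call(rbind, world$event_log)
  } else {
    data.frame(step = integer(0), event = character(0),
               filament_id = integer(0), detail = integer(0))
  }
  summary <- summarize_run(cell_log, world)
  log <- structure(list(
    cell_log = cell_log, event_log = event_log, summary = summary,
    snapshots = world$snapshots, world = world
  ), class = "run_log")
  if (!is.null(config$out_dir)) write_run_artifacts(log, config)
  log
}

summarize_run <- function(cell_log, world) {
  if (nrow(cell_log) == 0) {
    return(data.frame())
  }
  steps <- sort(unique(cell_log$step))
  rows <- lapply(steps, function(s) {
    sub <- cell_log[cell_log$step == s, ]
    data.frame(
      step = s,
      n_alive = sum(sub$state != "dead"),
      total_biomass_g = sum(sub$biomass_g[sub$state != "dead"]),
      mean_maltose_mmol = mean(sub$maltose_mmol),
      mean_cyanophycin_mmol = mean(sub$cyanophycin_mmol),
      n_divisions = sum(sub$divided),
      n_deaths = sum(sub$died)
    )
  })
  out <- do.call(rbind, rows)
  nh4 <- vapply(world$snapshots, function(sn) {
    mean(sn$concentration_uM[sn$metabolite == "NH4"])
  }, numeric(1))
  attr(out, "mean_NH4_uM_final") <- nh4[length(nh4)]
  out
}

#' Population growth rate from a run log
#'
#' Log-linear growth rate of total live biomass between the first and last
#' logged step, in h^-1.
#'
#' @param log A `run_log`.
#' @return Growth rate (h^-1), `NA` if fewer than two steps were logged.
#' @export
population_growth_rate <- function(log) {
  s <- log$summary
  if (nrow(s) < 2) {
    return(NA_real_)
  }
  dt_h <- log$world$config$dt_h
  t_span <- (s$step[nrow(s)] - s$step[1]) * dt_h
  log(s$total_biomass_g[nrow(s)] / s$total_biomass_g[1]) / t_span
}

write_run_artifacts <- function(log, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(log$cell_log, file.path(config$out_dir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(log$event_log, file.path(config$out_dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, log$snapshots),
                   file.path(config$out_dir, "grid.csv"), row.names = FALSE)
  manifest <- list(
    package = "trichosim",
    version = as.character(utils::packageVersion("trichosim")),
    seed = config$seed, n_steps = config$n_steps,
    config = config[setdiff(names(config), c("rules", "out_dir"))]
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(config$out_dir)
}
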