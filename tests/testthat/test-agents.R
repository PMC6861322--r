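# Cell and filament agents.

test_that("uptake bounds respect transporter modes and the 8% cyanophycin cap", {
  cell <- make_cell("photoautotroph")
  rules <- transfer_rules()
  dt <- 0.1
  mass <- cell$biomass_g
  # 100 mmol of beta-aspartyl arginine available -> bound equivalent of 8
  cell$pools[["BAA"]] <- 100
  b <- set_uptake_bounds(cell, c(CO2 = 0), rules, dt)
  expect_equal(b$EX_BAA[1] * mass * dt, -8)
  # zero local concentration -> zero uptake bound
  expect_equal(b$EX_CO2[1], 0)
  # active transporter exposes the full share, passive only a fraction
  b2 <- set_uptake_bounds(cell, c(CO2 = 1e-9, NH4 = 1e-9), rules, dt)
  expect_equal(b2$EX_CO2[1] * mass * dt, -1e-9)
  expect_equal(b2$EX_NH4[1] * mass * dt, -rules$passive_fraction * 1e-9)
})

test_that("cells sharing a gridcell build bounds from their equal partition", {
  rules <- transfer_rules()
  dt <- 0.1
  avail <- 1e-9
  shares <- partition_uptake(avail, c(1, 1)) # both could take everything
  cells <- list(make_cell(id = 1), make_cell(id = 2))
  for (i in 1:2) {
    b <- set_uptake_bounds(cells[[i]], c(CO2 = shares[i]), rules, dt)
    expect_equal(b$EX_CO2[1] * cells[[i]]$biomass_g * dt, -avail / 2)
  }
})

cell_step_args <- function(type = "photoautotroph", I = 100) {
  net <- build_toy_network(type)
  model <- maintenance_model("printed")
  maint <- maintenance_flux(I, model, type)
  front <- generate_pareto_front(net, steps = 41, maintenance = maint)
  eo <- c(1, 1)
  names(eo) <- c(net$biomass_rxn, net$metabolite_rxn)
  list(
    network = net, front = front, model = model,
    dist = mass_distribution(), rules = transfer_rules(),
    base = objective_weights(0.5, 0.5), exp_optima = eo
  )
}

test_that("cell_step: abundant nutrients grow a small cell with a biomass-leaning solve", {
  a <- cell_step_args("photoautotroph")
  cell <- make_cell("photoautotroph", biomass = 0.5 * a$dist$mean)
  cell$pools[["BAA"]] <- 1e-6 # ample nitrogen source
  env <- c(CO2 = 1e-6, O2 = 0, N2 = 0, NH4 = 0)
  out <- cell_step(cell, a$network, a$front, env, 100, a$model, a$dist,
    a$rules, 0.1, a$base, a$exp_optima)
  expect_false(out$died)
  expect_gt(out$cell$biomass_g, cell$biomass_g)
  expect_gt(out$cell$w_b, 0.5) # small cell leans toward biomass
})

test_that("cell_step: unmeetable maintenance kills the cell", {
  # photon capture bound far below the pinned maintenance demand
  net <- build_toy_network("photoautotroph", atp_per_uE = 0.1) # ub 10 < 78.5
  a <- cell_step_args("photoautotroph")
  cell <- make_cell("photoautotroph")
  out <- cell_step(cell, net, a$front, c(CO2 = 1e-6), 100, a$model, a$dist,
    a$rules, 0.1, a$base, a$exp_optima)
  expect_true(out$died)
  expect_equal(out$cell$state, "dead")
  # dead cells take no further actions
  out2 <- cell_step(out$cell, net, a$front, c(CO2 = 1e-6), 100, a$model,
    a$dist, a$rules, 0.1, a$base, a$exp_optima)
  expect_identical(out2$cell, out$cell)
  expect_false(out2$died)
})

test_that("cell_step: a cell short of maintenance survives by catabolizing its pool", {
  net <- build_toy_network("photoautotroph", atp_per_uE = 0.1)
  a <- cell_step_args("photoautotroph")
  cell <- make_cell("photoautotroph")
  # enough stored cyanophycin to fuel maintenance via degradation, but only
  # when the 8% uptake cap is lifted by the catabolism retry
  cell$pools[["BAA"]] <- 3e-9
  out <- cell_step(cell, net, a$front, c(CO2 = 0), 100, a$model, a$dist,
    a$rules, 0.1, a$base, a$exp_optima)
  expect_false(out$died)
  expect_lt(out$cell$pools[["BAA"]], cell$pools[["BAA"]])
})

test_that("stationary cells produce metabolite only, without biomass synthesis", {
  a <- cell_step_args("photoautotroph")
  cell <- make_cell("photoautotroph", biomass = 2.5 * a$dist$mean)
  cell <- maybe_go_stationary(cell, a$dist)
  expect_equal(cell$state, "stationary")
  pool0 <- cell$pools[["MALT"]]
  out <- cell_step(cell, a$network, a$front, c(CO2 = 1e-6), 100, a$model,
    a$dist, a$rules, 0.1, a$base, a$exp_optima)
  expect_equal(out$cell$biomass_g, cell$biomass_g)
  expect_gt(out$cell$pools[["MALT"]], pool0)
  expect_equal(out$cell$w_m, 1)
})

test_that("division halves biomass and pools exactly and only happens at ends", {
  set.seed(9)
  d <- mass_distribution()
  cell <- make_cell(biomass = 2e-9)
  cell$pools <- c(MALT = 4e-10, BAA = 2e-10)
  res <- maybe_divide(cell, d, at_end = TRUE, daughter_type = "diazotroph",
    next_id = 99L)
  expect_false(is.null(res)) # 2 ng is far above any plausible threshold
  expect_equal(res$parent$biomass_g, 1e-9)
  expect_equal(res$daughter$biomass_g, 1e-9)
  expect_equal(res$parent$pools, cell$pools / 2)
  expect_equal(res$daughter$pools, cell$pools / 2)
  expect_equal(res$daughter$type, "diazotroph")
  expect_equal(res$daughter$id, 99L)
  # population biomass is continuous across the division
  expect_equal(res$parent$biomass_g + res$daughter$biomass_g, cell$biomass_g)
  # interior cells never divide regardless of mass
  expect_null(maybe_divide(cell, d, at_end = FALSE, "photoautotroph", 100L))
})

test_that("division probability vanishes far below the mean (CDF bound)", {
  set.seed(10)
  # a narrow distribution so mean - 5 sd is still a positive mass
  d <- mass_distribution(sd_fraction = 0.1)
  tiny <- make_cell(biomass = d$mean - 5 * d$sd)
  hits <- 0
  for (i in 1:300) {
    if (!is.null(maybe_divide(tiny, d, TRUE, "photoautotroph", 1L))) {
      hits <- hits + 1
    }
  }
  expect_equal(hits, 0)
})

test_that("stationary transition is one-way at twice the mean mass", {
  d <- mass_distribution()
  expect_equal(maybe_go_stationary(make_cell(biomass = 2 * d$mean), d)$state,
    "stationary")
  expect_equal(maybe_go_stationary(make_cell(biomass = d$mean), d)$state,
    "growing")
  # never reverts even if mass were to fall again
  cell <- maybe_go_stationary(make_cell(biomass = 3 * d$mean), d)
  for (i in 1:100) {
    cell$biomass_g <- d$mean * 0.5
    cell <- maybe_go_stationary(cell, d)
    expect_equal(cell$state, "stationary")
  }
})

filament_with <- function(types, effs = NULL) {
  cells <- list()
  for (i in seq_along(types)) {
    cl <- make_cell(types[i], id = i)
    cl$filament_id <- 1L
    cl$efficiency <- if (is.null(effs)) 0.5 else effs[i]
    cells[[as.character(i)]] <- cl
  }
  list(fil = filament_agent(1L, seq_along(types), 2L, 2L), cells = cells)
}

test_that("next cell type follows mean Pareto efficiency, ties and gaps resolved", {
  f <- filament_with(c("diazotroph", "photoautotroph"), c(0.9, 0.5))
  expect_equal(decide_next_cell_type(f$fil, f$cells), "diazotroph")
  f2 <- filament_with(c("diazotroph", "photoautotroph"), c(0.5, 0.5))
  expect_equal(decide_next_cell_type(f2$fil, f2$cells), "photoautotroph")
  # homogeneous filament prefers the missing type
  f3 <- filament_with(rep("photoautotroph", 4))
  expect_equal(decide_next_cell_type(f3$fil, f3$cells), "diazotroph")
  f4 <- filament_with(rep("diazotroph", 3))
  expect_equal(decide_next_cell_type(f4$fil, f4$cells), "photoautotroph")
  empty <- filament_agent(9L, integer(0), 1L, 1L)
  expect_error(decide_next_cell_type(empty, f$cells), "empty")
})

test_that("splitting: length rule, cut in the longest homogeneous run, triggers", {
  # nitrogen-limited (empty pools), no diazocyte developing
  f <- filament_with(c("photoautotroph", "photoautotroph", "photoautotroph",
    "photoautotroph", "diazotroph", "diazotroph"))
  res <- maybe_split(f$fil, f$cells, baa_reference = 1e-9,
    n_limit_fraction = 0.25, cn_upper = 8, new_id = 2L)
  expect_length(res, 2)
  # cut falls inside the PPPP run at its middle
  expect_equal(res[[1]]$cell_ids, 1:2)
  expect_equal(res[[2]]$cell_ids, 3:6)
  expect_true(all(lengths(list(res[[1]]$cell_ids, res[[2]]$cell_ids)) >= 2))
  # length 3 never splits
  f3 <- filament_with(rep("photoautotroph", 3))
  expect_null(maybe_split(f3$fil, f3$cells, 1e-9, 0.25, 8, 2L))
  # nitrogen-replete with a developing diazocyte: no split
  f4 <- filament_with(rep("photoautotroph", 6))
  for (id in names(f4$cells)) f4$cells[[id]]$pools[["BAA"]] <- 1e-8
  f4$fil$diazocyte_developing <- TRUE
  expect_null(maybe_split(f4$fil, f4$cells, 1e-9, 0.25, 8, 2L))
})

test_that("property: splits never produce singletons over randomized filaments", {
  set.seed(12)
  for (i in 1:2000) {
    len <- sample(2:12, 1)
    types <- sample(c("photoautotroph", "diazotroph"), len, replace = TRUE)
    f <- filament_with(types)
    res <- maybe_split(f$fil, f$cells, 1e-9, 0.25, 8, 2L)
    if (!is.null(res)) {
      expect_gte(length(res[[1]]$cell_ids), 2)
      expect_gte(length(res[[2]]$cell_ids), 2)
      expect_equal(c(res[[1]]$cell_ids, res[[2]]$cell_ids), f$fil$cell_ids)
    } else {
      expect_lt(len, 4)
    }
  }
})

test_that("random walk: isolated filaments always move, enclosed ones never", {
  set.seed(13)
  occ_free <- matrix(0L, 9, 9)
  fil <- filament_agent(1L, 1:4, 5L, 5L)
  occ_free[5, 5] <- 1L
  moved <- vapply(1:20, function(i) {
    random_walk(fil, occ_free, 9, 9)$moved
  }, logical(1))
  expect_true(all(moved))
  # fully enclosed by another filament
  occ_block <- matrix(2L, 9, 9)
  occ_block[5, 5] <- 1L
  moved2 <- vapply(1:20, function(i) {
    random_walk(fil, occ_block, 9, 9)$moved
  }, logical(1))
  expect_false(any(moved2))
})

test_that("blocked extension halts filament growth until the filaments separate", {
  # 10-cell filaments fill a whole gridcell, so extending needs the next one
  cfg <- simulation_config(n_steps = 0, n_cells = 20, n_filaments = 2,
    grid_width = 8, grid_height = 8, front_steps = 11)
  world <- init_world(cfg)
  # place a second filament directly on the extension site of the first
  f1 <- world$filaments[["1"]]
  g1 <- trichosim:::filament_gridcells(f1, cfg$cells_per_gridcell)
  ext_col <- max(g1$col) + 1L
  world$filaments[["2"]]$origin_row <- f1$origin_row
  world$filaments[["2"]]$origin_col <- ext_col
  world <- trichosim:::filament_stage(world)
  expect_true(world$filaments[["1"]]$growth_blocked)
  # move the blocker away: growth resumes
  world$filaments[["2"]]$origin_row <- f1$origin_row + 3L
  world <- trichosim:::filament_stage(world)
  expect_false(world$filaments[["1"]]$growth_blocked)
})

test_that("intrafilament exchange equilibrates pools and conserves inventory", {
  f <- filament_with(c("photoautotroph", "diazotroph"))
  rules <- transfer_rules(intrafilament_rate = 1)
  f$cells[["1"]]$pools[["MALT"]] <- 10
  cells <- f$cells
  for (i in 1:50) cells <- intrafilament_exchange(f$fil, cells, rules)
  expect_equal(cells[["1"]]$pools[["MALT"]], 5, tolerance = 1e-6)
  expect_equal(cells[["2"]]$pools[["MALT"]], 5, tolerance = 1e-6)
  # equal pools: no net transfer
  before <- cells
  cells <- intrafilament_exchange(f$fil, cells, rules)
  expect_equal(cells[["1"]]$pools, before[["1"]]$pools, tolerance = 1e-9)
  # conservation over random initializations and chain lengths
  set.seed(14)
  for (i in 1:50) {
    len <- sample(2:8, 1)
    ff <- filament_with(rep("photoautotroph", len))
    for (id in names(ff$cells)) {
      ff$cells[[id]]$pools[["BAA"]] <- runif(1, 0, 5)
    }
    tot0 <- sum(vapply(ff$cells, function(c) c$pools[["BAA"]], numeric(1)))
    out <- intrafilament_exchange(ff$fil, ff$cells, transfer_rules())
    tot1 <- sum(vapply(out, function(c) c$pools[["BAA"]], numeric(1)))
    expect_equal(tot1, tot0, tolerance = 1e-12)
  }
})
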