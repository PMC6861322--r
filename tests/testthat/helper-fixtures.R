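# Shared fixtures: tiny networks and scaled-down simulation configs.

# A 3-reaction linear chain: SRC -> A (ub 10), CONV: A -> B, SNK: B ->.
# With maintenance absent and both objectives on CONV/SNK this is solvable
# by hand: every flux equals min of the ubs along the chain.
chain_network <- function(ub = c(10, 8, 12)) {
  S <- matrix(
    c(
      1, -1, 0,
      0, 1, -1
    ),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("A", "B"), c("SRC", "CONV", "SNK"))
  )
  metabolic_network(S, c(0, 0, 0), ub,
    biomass_rxn = "CONV", metabolite_rxn = "SNK",
    atp_maintenance_rxn = "SRC"
  )
}

toy_pair <- function(light_uE = 100) {
  list(
    photoautotroph = build_toy_network("photoautotroph", light_uE = light_uE),
    diazotroph = build_toy_network("diazotroph", light_uE = light_uE)
  )
}

maintenance_pin <- function(net, value) {
  stats::setNames(list(c(value, value)), net$atp_maintenance_rxn)
}

# a small world that runs fast: 12 cells over 2 filaments on an 8x8 grid
tiny_config <- function(n_steps = 10, seed = 1, ...) {
  simulation_config(
    n_steps = n_steps, seed = seed, n_cells = 12, n_filaments = 2,
    grid_width = 8, grid_height = 8, front_steps = 41, ...
  )
}

make_cell <- function(type = "photoautotroph", biomass = NULL, id = 1L) {
  if (is.null(biomass)) biomass <- default_mean_mass()
  cell_agent(id, type, biomass, filament_id = 1L)
}
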