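# Metabolic core: scalarized FBA, Pareto front, maintenance model,
# efficiency.

test_that("scalarization limits: a=1 maximizes biomass alone, a=0 metabolite alone", {
  for (net in toy_pair()) {
    s1 <- solve_fba(net, 1)
    expect_equal(s1$status, "optimal")
    expect_equal(s1$fluxes[[net$metabolite_rxn]], 0, tolerance = 1e-9)
    expect_equal(s1$fluxes[[net$biomass_rxn]], s1$objective_value,
      tolerance = 1e-9
    )
    s0 <- solve_fba(net, 0)
    expect_equal(s0$fluxes[[net$biomass_rxn]], 0, tolerance = 1e-9)
    expect_equal(s0$fluxes[[net$metabolite_rxn]], s0$objective_value,
      tolerance = 1e-9
    )
    expect_gt(s1$objective_value, 0)
    expect_gt(s0$objective_value, 0)
  }
})

test_that("every optimal solution satisfies S v = 0 and bounds", {
  mm <- maintenance_model("printed")
  for (net in toy_pair()) {
    maint <- maintenance_flux(100, mm, net$cell_type)
    for (a in seq(0, 1, by = 0.25)) {
      s <- solve_fba(net, a, maintenance = maint)
      expect_equal(s$status, "optimal")
      expect_lt(max(abs(net$stoichiometry %*% s$fluxes)), 1e-6)
      expect_true(all(s$fluxes >= net$lower - 1e-8))
      expect_true(all(s$fluxes <= net$upper + 1e-8))
      expect_equal(s$fluxes[[net$atp_maintenance_rxn]], maint,
        tolerance = 1e-8
      )
    }
  }
})

test_that("solver matches the vertex-enumeration oracle on a hand-solvable chain", {
  net <- chain_network(ub = c(10, 8, 12))
  # steady state forces the two objective fluxes equal (both carry the chain
  # flux f <= 8), so the blended objective with components in ratio
  # a:(1-a) is only nonzero at a = 0.5, where t = f_X + f_m = 16
  hand <- c(`0` = 0, `0.5` = 16, `1` = 0)
  for (a in c(0, 0.5, 1)) {
    s <- solve_fba(net, a)
    o <- lp_vertex_oracle(net, a)
    expect_equal(s$objective_value, hand[[as.character(a)]], tolerance = 1e-9)
    expect_equal(o$obj, hand[[as.character(a)]], tolerance = 1e-9)
  }
})

test_that("infeasible problems report infeasible from both routes, never raise", {
  net <- chain_network()
  pin <- maintenance_pin(net, 20) # SRC pinned above its ub is impossible
  s <- solve_fba(net, 0.5, extra_bounds = pin)
  expect_equal(s$status, "infeasible")
  o <- lp_vertex_oracle(net, 0.5, extra_bounds = pin)
  expect_equal(o$status, "infeasible")
})

test_that("malformed network dimensions fail structurally before solving", {
  S <- matrix(1, 2, 3, dimnames = list(c("A", "B"), c("r1", "r2", "r3")))
  expect_error(
    metabolic_network(S, c(0, 0), c(1, 1), "r1", "r2", "r3"),
    "dimension mismatch"
  )
})

test_that("tie-break makes the reported flux vector the minimum-|v| optimum", {
  # add a futile pair to the photoautotroph: two opposing reactions that can
  # carry arbitrary cycles without affecting the objective
  net <- build_toy_network("photoautotroph")
  s <- solve_fba(net, 0.5, maintenance = 10, tie_break = TRUE)
  s2 <- solve_fba(net, 0.5, maintenance = 10, tie_break = TRUE)
  expect_identical(s$fluxes, s2$fluxes)
  # the tie-broken vector can be no longer (in l1) than the plain one
  plain <- solve_fba(net, 0.5, maintenance = 10, tie_break = FALSE)
  expect_lte(sum(abs(s$fluxes)), sum(abs(plain$fluxes)) + 1e-9)
  expect_equal(s$objective_value, plain$objective_value, tolerance = 1e-9)
})

test_that("pareto front: endpoints, resolution, decomposition, self-consistency", {
  net <- build_toy_network("photoautotroph")
  fr2 <- generate_pareto_front(net, steps = 2)
  expect_equal(fr2$a, c(0, 1))
  fr <- generate_pareto_front(net, steps = 51)
  expect_equal(nrow(fr), 51)
  expect_true(all(diff(fr$a) > 0))
  expect_equal(fr$nu_X, fr$a * fr$nu_obj, tolerance = 1e-12)
  expect_equal(fr$nu_m, (1 - fr$a) * fr$nu_obj, tolerance = 1e-12)
  s1 <- solve_fba(net, 1)
  expect_equal(fr$nu_X[nrow(fr)], s1$objective_value, tolerance = 1e-9)
})

test_that("pareto front is monotone: nu_X nondecreasing, nu_m nonincreasing in a", {
  mm <- maintenance_model("printed")
  for (net in toy_pair()) {
    maint <- maintenance_flux(100, mm, net$cell_type)
    fr <- generate_pareto_front(net, steps = 101, maintenance = maint)
    expect_true(all(diff(fr$nu_X) >= -1e-7))
    expect_true(all(diff(fr$nu_m) <= 1e-7))
  }
})

test_that("all-infeasible front names the maintenance constraint", {
  net <- chain_network()
  expect_error(
    generate_pareto_front(net, steps = 5, extra_bounds = maintenance_pin(net, 20)),
    "maintenance"
  )
})

test_that("decompose_objective_flux is exact arithmetic", {
  expect_equal(decompose_objective_flux(0, 5), c(mu = 0, nu_m = 5))
  expect_equal(decompose_objective_flux(1, 5), c(mu = 5, nu_m = 0))
  expect_equal(decompose_objective_flux(0.25, 8), c(mu = 2, nu_m = 6))
  expect_equal(sum(decompose_objective_flux(0.37, 3.21)), 3.21)
})

test_that("fit_maintenance: point-slope fit, anchor recovery, order invariance", {
  expect_equal(fit_maintenance(80, 40, 100, 60),
    c(m_slope = 1.0, nu0 = -40.0))
  # published photoautotroph anchors give a different (m, nu0) than printed
  fit <- fit_maintenance(100, 53.3, 80, 34.3)
  expect_equal(fit[["m_slope"]], 0.95, tolerance = 1e-12)
  expect_equal(fit[["nu0"]], -41.7, tolerance = 1e-9)
  expect_equal(fit_maintenance(80, 34.3, 100, 53.3), fit)
  expect_error(fit_maintenance(80, 40, 80, 60), "degenerate")
})

test_that("maintenance fit round-trips through both anchors exactly", {
  tab <- maintenance_constants()
  for (i in seq_len(nrow(tab))) {
    fit <- fit_maintenance(100, tab$nu_atp_100[i], 80, tab$nu_atp_80[i])
    expect_equal(fit[["m_slope"]] * 100 + fit[["nu0"]], tab$nu_atp_100[i])
    expect_equal(fit[["m_slope"]] * 80 + fit[["nu0"]], tab$nu_atp_80[i])
  }
})

test_that("maintenance_flux evaluates the printed line with clamping", {
  mm <- maintenance_model("printed")
  # printed photoautotroph constants at 100 uE: 0.952 * 100 - 16.7 = 78.5
  expect_equal(maintenance_flux(100, mm, "photoautotroph"), 78.5)
  expect_equal(maintenance_flux(0, mm, "photoautotroph"), 0) # clamped
  root <- 16.7 / 0.952
  expect_equal(maintenance_flux(root, mm, "photoautotroph"), 0)
  expect_error(maintenance_flux(50, mm, "heterotroph"), "unknown cell type")
})

test_that("refit maintenance model reproduces the anchors, printed does not", {
  refit <- maintenance_model("refit")
  printed <- maintenance_model("printed")
  tab <- maintenance_constants()
  for (ct in tab$cell_type) {
    row <- tab[tab$cell_type == ct, ]
    expect_equal(maintenance_flux(100, refit, ct), row$nu_atp_100)
    expect_equal(maintenance_flux(80, refit, ct), row$nu_atp_80)
    # the printed constants are internally inconsistent with the anchors
    expect_gt(abs(maintenance_flux(100, printed, ct) - row$nu_atp_100), 1)
  }
})

test_that("pareto_efficiency averages flux ratios over objectives", {
  v <- c(BIOMASS = 1, EX_MALT = 2)
  expect_equal(pareto_efficiency(v, c(BIOMASS = 1, EX_MALT = 2)), 1)
  expect_equal(pareto_efficiency(c(BIOMASS = 0, EX_MALT = 0),
    c(BIOMASS = 1, EX_MALT = 2)), 0)
  # (0.5x, 1.5x) of the optima average to 1
  expect_equal(pareto_efficiency(c(BIOMASS = 0.5, EX_MALT = 3),
    c(BIOMASS = 1, EX_MALT = 2)), 1)
  expect_error(pareto_efficiency(v, c(BIOMASS = 0, EX_MALT = 2)), "positive")
})
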