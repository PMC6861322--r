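{
  "version": "1.0",
  "comment": "Packaged default parameter table. source: 'paper' entries are published constants stored verbatim; source: 'default' entries are standard literature values chosen because the original supplementary tables are not machine-readable, and are overridable by configuration.",
  "mean_cell_mass_g": { "value": 1.029e-9, "source": "paper" },
  "sd_fraction": { "value": 0.433, "source": "paper" },
  "cell_side_um": { "value": 10, "source": "paper" },
  "seawater_density_kg_m3": { "value": 1029, "source": "paper" },
  "dt_h": { "value": 0.1, "source": "paper" },
  "baa_uptake_cap": { "value": 0.08, "source": "paper" },
  "pareto_steps": { "value": 1000, "source": "paper" },
  "grid_delta_um": { "value": 100, "source": "paper" },
  "grid_width": { "value": 25, "source": "paper" },
  "grid_height": { "value": 25, "source": "paper" },
  "n_cells": { "value": 150, "source": "paper" },
  "n_filaments": { "value": 10, "source": "paper" },
  "diazotroph_fraction": { "value": 0.3, "source": "paper" },
  "light_I0_uE": { "value": 100, "source": "paper" },
  "maintenance": {
    "source": "paper",
    "photoautotroph": {
      "nu_atp_80": 34.3, "nu_atp_100": 53.3,
      "m": 0.952, "nu0": -16.7, "L0": 16.9
    },
    "diazotroph": {
      "nu_atp_80": 62.3, "nu_atp_100": 82.0,
      "m": 0.987, "nu0": -41.9, "L0": 44.0
    }
  },
  "light_extinction_m": { "value": 0.04, "source": "default" },
  "diffusivities_um2_s": {
    "source": "default",
    "CO2": 1900, "O2": 2100, "N2": 2000, "NH4": 1980, "MALT": 570, "BAA": 600
  },
  "henry_constants_uM_atm": {
    "source": "default",
    "CO2": 34000, "O2": 1260, "N2": 640
  },
  "partial_pressures_atm": {
    "source": "default",
    "CO2": 4.0e-4, "O2": 0.21, "N2": 0.79
  },
  "initial_fields_uM": {
    "source": "default",
    "comment": "YBC-II-like: dissolved inorganic carbon pool represented as the CO2 species at 2.5 mM bicarbonate equivalent; O2 and N2 at Henry equilibrium with the atmosphere.",
    "CO2": 2500, "O2": 264.6, "N2": 505.6, "NH4": 0, "MALT": 0, "BAA": 0
  },
  "membrane_leak_per_h": {
    "source": "default",
    "MALT": 0.01, "BAA": 0.01
  },
  "intrafilament_exchange_rate": { "value": 0.5, "source": "default" },
  "cells_per_gridcell": { "value": 10, "source": "paper" },
  "atp_per_uE": { "value": 2, "source": "default" },
  "movement_interval_steps": { "value": 10, "source": "default" },
  "n_limit_fraction": { "value": 0.25, "source": "default" },
  "baa_pool_reference_mmol": { "value": 1.0e-9, "source": "default" },
  "cn_bounds": { "value": [4, 8], "source": "default" }
}
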