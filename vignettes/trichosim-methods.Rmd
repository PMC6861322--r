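---
title: "Methods: multiscale agent-based metabolic simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale agent-based metabolic simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trichosim)
```

## The model

trichosim simulates a population of filamentous cyanobacterial cells in
which two metabolically distinct cell types divide labor along a shared
filament: photoautotrophs fix CO~2~ and export maltose (a glycogen proxy),
diazotrophs fix N~2~ and export beta-aspartyl arginine (the cyanophycin
monomer). Each living cell, at each 0.1 h time step, solves a small linear
program; the filament and ocean layers couple those per-cell solutions in
space and time.

The per-cell problem is a scalarized two-objective flux balance analysis.
The two objective reactions — biomass synthesis $X$ and the
transactional-metabolite sink $m$ — are blended into a single scalarized
objective

$$ r_{obj} = a\,X + (1-a)\,m, \qquad a \in [0,1], $$

and the solver maximizes the flux $\nu_{obj}$ through this combined
reaction subject to steady state $S\nu = 0$, reaction bounds, and an ATP
maintenance flux pinned to the light-dependent demand. Because the blend is
a single reaction, the component fluxes decompose exactly:
$\mu = \nu_X = a\,\nu_{obj}$ and $\nu_m = (1-a)\,\nu_{obj}$. We note a
subtlety here that shaped the implementation: if the scalarization is
instead implemented as a weighted *sum* of two independent fluxes, the
decomposition above does not hold and $a\,\nu_{obj}(a)$ is not monotone in
$a$; only the single-blended-reaction reading makes the front
decomposition exact and monotone, so that is what `solve_fba()` implements.
Sweeping $a$ over 1000 evenly spaced values (endpoints included — `steps`
counts grid points, which makes the two limits directly testable) yields
the Pareto front between growth and storage-compound production
(`generate_pareto_front()`).

Alternate LP optima are resolved by a documented secondary objective:
among all flux vectors attaining the optimal $\nu_{obj}$, the reported one
minimizes $\sum_i |\nu_i|$. This makes flux maps reproducible
run-to-run; it is optional (and off by default) inside simulation runs,
where only the objective value and exchange fluxes feed the dynamics.

### Maintenance energy

The ATP maintenance demand is linear in light intensity,
$\nu_{ATP}(I) = mI + \nu_0$, with per-cell-type constants fitted from
anchors at 80 and 100 µE. The published constant table is stored verbatim
in `inst/extdata/parameters.json`, but it is internally inconsistent: the
printed $(m, \nu_0)$ pairs do not reproduce the printed anchor fluxes
(for the photoautotroph, $0.952 \cdot 100 - 16.7 = 78.5 \ne 53.3$), and
the printed zero-light parameter $L_0$ differs from $-\nu_0/m$. Which set
the original implementation used cannot be determined, so both are
exposed: `maintenance_model("printed")` (the default) evaluates the line
with the printed constants; `maintenance_model("refit")` re-derives
$(m, \nu_0)$ from the anchors by the point-slope formula, which
reproduces both anchors exactly. Below the root of the line the demand is
clamped to zero: a flux demand cannot be negative, and the published law
is silent below its root.

### Mutable objective weights

Cell mass is modeled as $N(\mu, 0.433\,\mu)$ with
$\mu = 1.029\times10^{-9}$ g — a 10 µm cube at seawater density
(1029 kg m^-3^). With this width a sampled cell falls at or below twice
the mean with probability `r round(100*pnorm(2, 1, 0.433))`%, which gives
the weighting scheme its switch-like, bistable character. Each step, a
cell computes $z = F(X \le x)$, the probability that a random cell is no
heavier than itself, scales its Pareto-matched base weights as
$\hat w_b = (1-z)\,\bar w_b$ (the "expansion space") and
$\hat w_m = z\,\bar w_m$, and renormalizes to sum to one. Small cells
therefore prioritize growth, large cells storage metabolites. The
normalization is written for $k$ objectives; the package implements and
tests the two-objective case, and a property test checks the $k$-form
against a direct transcription of the two-weight formulation.

Two deliberate choices: (1) the weighting input is the cell's
*non-metabolite* biomass (the storage pools are tracked separately and do
not count toward $x$) — the source material describes the input both ways
and this reading is the one consistent with decoupling storage from the
biomass equation; (2) division thresholds are drawn from the same normal
truncated at zero, because masses are physical.

### The ocean grid

Concentration fields (CO~2~, O~2~, N~2~, NH~4~^+^, maltose,
beta-aspartyl arginine; µM) live on a 2-D grid of 100 µm gridcells, row 1
at the surface. Diffusion uses a discrete Gaussian-kernel scheme: cell $i$
exchanges with its neighborhood with weights $e^{-d_j^2/\eta}$,
$\eta = 4\mathcal{D}\Delta t$, normalized over the neighborhood (self
included, so $\eta \to 0$ is exactly the identity and $\eta \to \infty$
relaxes each neighborhood to its mean). The neighborhood is Moore
(8 neighbors, $d_j \in \{\delta, \delta\sqrt2\}$); the diagonal terms are
naturally down-weighted by the kernel, and a von Neumann option exists.

Two implementation decisions matter for the invariants:

* **Pairwise transfers.** The per-cell normalization constant $A_i$
  varies at closed-boundary edges, so applying the textbook update
  cell-by-cell does not conserve mass exactly near edges. The sweep is
  therefore implemented as pairwise antisymmetric transfers
  $A_i w_{ij} (f_j - f_i)$ — identical in the interior, exactly
  conservative everywhere, and incapable of producing negative
  concentrations.
* **Two half-steps.** Updates are applied in place sequentially (the
  order dependence is intrinsic to the discrete scheme); each step runs
  one forward and one reversed sweep, each with $\eta$ computed from
  $\Delta t/2$. In a mirrored-pulse experiment this reduces the
  order-induced asymmetry by more than an order of magnitude (tested).

Lateral and bottom boundaries are closed so conservation is testable; only
the surface row exchanges with the atmosphere, relaxing toward the
Henry's-law equilibrium $c_{eq} = K_H p$ with fractional approach
$\min(1, \mathcal{D}\Delta t/\delta^2)$ per step — monotone and free of
overshoot. Light follows Beer–Lambert attenuation with depth. When
several cells share a gridcell, access to each metabolite is divided
equally, with unclaimed shares re-divided among unsatisfied cells to a
fixed point.

### Cells and filaments

Cells hold non-metabolite biomass plus maltose and cyanophycin pools.
Per step, in order: re-weight the objective from mass; solve the
maintenance-pinned FBA with uptake bounds from the cell's equal share of
local nutrients (active transporters expose the full share, passive
permeation a fraction, and the transactional metabolites come from the
cell's own pools, with beta-aspartyl-arginine uptake capped at 8% of the
available amount); on infeasibility, retry once with unrestricted access
to the cell's own storage pool (catabolism), and die if still infeasible;
then integrate biomass and pools forward by explicit Euler and exchange
with the environment. Stationary cells (a one-way transition at twice the
mean mass) produce metabolites only.

Division is memoryless: each step an end cell divides iff its biomass
reaches a fresh draw from the mass distribution, halving biomass and pools
between parent and daughter. The garbled published description of the
threshold rule is resolved as "divide when biomass exceeds a fresh
$N(\mu,\sigma)$ draw", consistent with the distribution's role and the
no-growth-beyond-2× assumption. Daughters become diazotrophs only when
the filament-level inequality (mean Pareto efficiency of diazotrophs
strictly exceeding that of photoautotrophs) holds *and* a diazocyte is
under development; ties prefer the photoautotroph, and a homogeneous
filament prefers its missing type. Pareto efficiency is the mean of the
objective fluxes relative to per-type optima — the surrounding text's
"divided by the number of objectives" is followed (the displayed equation
omits it, but only the text's version makes matched fluxes score 1).

Filaments split when nitrogen limits growth with no diazocyte developing,
or when the C:N ratio leaves its physiological bound; the cut falls in the
middle of the longest homogeneous run, clamped so both products keep at
least two cells. "Nitrogen limiting" is operationalized as the filament
mean cyanophycin pool falling below a configurable fraction (default
0.25) of a reference pool, because no quantitative trigger is published;
the C:N bound defaults to [4, 8] around the toy network's biomass
composition (C:N = 40/7). A developing diazocyte closes when the
filament-level C:N recovers. Movement is an all-or-nothing rigid random
walk into a fully vacant direction; a filament whose extension gridcell
is occupied by another filament halts growth until they separate.

### Scheduling and reproducibility

Stage order per step is fixed: surface exchange, diffusion, filament
decisions, cell steps in a seeded random order, logging. The seed is split
into named substreams (scheduling, division, movement) so adding draws to
one feature cannot perturb another's sequence. Identical configuration and
seed give byte-identical logs; this is an acceptance criterion.

## The synthetic world

No genome-scale reconstruction ships with the package. Instead,
`build_toy_network()` provides a two-cell-type toy model (≤ 12 reactions
each, so the vertex-enumeration oracle can exhaustively check every
solve): a light-driven ATP source, lumped carbon fixation, maltose
synthesis/catabolism, lumped N~2~ fixation, cyanophycin-monomer
synthesis/degradation, a biomass drain (40 mmol C and 7 mmol N per gDW,
typical cyanobacterial composition), ATP maintenance, and exchange
reactions that reproduce the allowed cross-feeding topology
(maltose photoautotroph → diazotroph, beta-aspartyl arginine the reverse,
gases and ammonium freely). Both networks are elementally balanced in C
and N by construction and audited at build time. Catabolic routes
(arginine oxidation at 15 ATP, maltose respiration at 30 ATP per mmol)
were chosen so that a starved cell can meet maintenance from its storage
pool even when its objective sinks carry no flux — with full oxidation to
CO~2~ so the carbon has a disposal route.

The default world mirrors the published setup where stated: 150 cells over
10 filaments at a 3:7 diazotroph:photoautotroph ratio, 0.1 h steps, 100 µE
surface light, a 25 × 25 grid of 100 µm cells, YBC-II-like initial fields
(2.5 mM dissolved inorganic carbon represented on the CO~2~ species, O~2~
and N~2~ at Henry equilibrium with the atmosphere), and atmospheric
partial pressures. Where only supplementary tables (not machine-readable
here) held the values — free diffusivities, Henry constants, membrane
permeabilities — standard seawater literature values are packaged and
tagged `source: "default"` in `parameters.json`, overridable per run.

What a green test does **not** establish: the toy network's absolute
fluxes and growth rates are not those of the organism (growth comes out
of order 0.1 h^-1^ against a measured ~0.01 h^-1^, because the lumped
network is far less constrained than a genome-scale model), so the
package's quantitative claims are about mechanisms and invariants — mass
conservation, solver correctness against an independent oracle,
determinism, monotone fronts, and the emergent ordering that short
filaments out-grow long ones in replete medium — not about reproducing
published concentrations or rate curves. Day/night cycling is likewise
out of scope.

## Numerical choices

* LP: dense two-phase simplex with Bland's rule (no LP package is
  assumed); feasibility tolerance 1e-9, phase-1 acceptance 1e-7. Every
  optimal solution is checked against $S\nu = 0$ at 1e-6 in tests, and
  against exhaustive vertex enumeration at 1e-8 on the toy networks.
* The vertex oracle refuses more than 8 free dimensions; the toy networks
  have 3–4 after null-space elimination.
* Infinite bounds are clamped to ±1000 mmol gDW^-1^ h^-1^ on network
  construction.
* Euler integration of biomass and pools at the scheduler's Δt; no
  sub-cycling by default (`dt` can simply be reduced, since η is computed
  from Δt).
* Ties in Pareto-point matching break toward larger $a$ (biomass).

## Known limitations

Single 12-hour-light-period worlds (no diurnal cycle); 2-D diffusion with
closed lateral boundaries and no advection; point-occupancy cell geometry
(10 cells per gridcell); two concurrent objectives only; the toy network
is a stand-in, not a reconstruction. Dead cells become inert but retain
their mass (no lysis or remineralization).
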