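# The Ocean layer: per-metabolite concentration fields on a delta-spaced 2-D
# grid, discrete Gaussian-kernel diffusion with exact mass conservation,
# Henry's-law exchange with the atmosphere across the top row, and
# Beer-Lambert light attenuation with depth.
#
# Unit conventions (kept consistent everywhere): concentrations uM, grid
# lengths um, time steps h (converted to seconds where diffusivities in
# um^2 s^-1 enter), fluxes mmol gDW^-1 h^-1.

#' Construct an ocean grid
#'
#' @param width,height Grid dimensions in gridcells (`>= 1`). Row 1 is the
#'   surface; depth increases with row index.
#' @param delta_um Gridcell edge length in micrometers (default 100).
#' @param dt_h Time step in hours (default 0.1).
#' @param diffusivities Named vector of free diffusivities, um^2 s^-1, one
#'   per tracked metabolite.
#' @param init Named list/vector of initial uniform concentrations (uM);
#'   defaults to 0 for every tracked metabolite.
#' @param neighborhood `"moore"` (8 neighbors, default) or `"von_neumann"`
#'   (4 neighbors).
#' @return An `ocean_grid` with one `height x width` concentration matrix
#'   per metabolite.
#' @export
ocean_grid <- function(width, height, delta_um = 100, dt_h = 0.1,
                       diffusivities, init = NULL,
                       neighborhood = c("moore", "von_neumann")) {
  stopifnot(width >= 1, height >= 1, delta_um > 0, dt_h > 0)
  neighborhood <- match.arg(neighborhood)
  mets <- names(diffusivities)
  if (is.null(mets)) stop("diffusivities must be a named vector")
  fields <- lapply(mets, function(m) {
    c0 <- if (!is.null(init) && m %in% names(init)) as.numeric(init[[m]]) else 0
    matrix(c0, nrow = height, ncol = width)
  })
  names(fields) <- mets
  structure(list(
    width = width, height = height, delta_um = delta_um, dt_h = dt_h,
    diffusivities = diffusivities, fields = fields,
    neighborhood = neighborhood
  ), class = "ocean_grid")
}

#' Kernel diffusivity control
#'
#' `eta = 4 * D * dt`, the diffusivity control of the discrete diffusion
#' kernel (the Fickian variance accumulated over the step). As `eta -> 0`
#' diffusion halts; as `eta -> Inf` each neighborhood relaxes to its mean.
#'
#' @param D Diffusivity (length^2 / time).
#' @param dt Time step, in the same time unit as `D`.
#' @return `eta = 4 * D * dt` (length^2).
#' @export
compute_eta <- function(D, dt) {
  stopifnot(D >= 0, dt > 0)
  4 * D * dt
}

neighbor_offsets <- function(neighborhood) {
  if (neighborhood == "moore") {
    g <- expand.grid(dr = -1:1, dc = -1:1)
    g <- g[!(g$dr == 0 & g$dc == 0), ]
  } else {
    g <- data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  g
}

# One in-place sweep of pairwise kernel exchange over the given cell order.
# Transfers A_i * w_j * (f_j - f_i) from neighbor j to center i, which
# conserves mass exactly and can never drive a concentration negative.
diffusion_sweep <- function(f, order_idx, offsets, w_by_dist, height, width) {
  for (idx in order_idx) {
    r <- ((idx - 1L) %% height) + 1L
    cc <- ((idx - 1L) %/% height) + 1L
    rr <- r + offsets$dr
    cn <- cc + offsets$dc
    keep <- rr >= 1L & rr <= height & cn >= 1L & cn <= width
    if (!any(keep)) next
    rr <- rr[keep]
    cn <- cn[keep]
    w <- w_by_dist[keep]
    A <- 1 / (1 + sum(w)) # self weight exp(0) = 1 closes the normalization
    nidx <- (cn - 1L) * height + rr
    transfer <- A * w * (f[nidx] - f[idx])
    f[idx] <- f[idx] + sum(transfer)
    f[nidx] <- f[nidx] - transfer
  }
  f
}

#' Advance one metabolite field by one diffusion step
#'
#' Each gridcell exchanges mass with its neighborhood using Gaussian kernel
#' weights `exp(-d^2 / eta)` normalized over the neighborhood (self
#' included), with `eta = 4 * D * dt`. The update runs as two in-place
#' sweeps, one in forward cell order and one reversed, each covering half
#' the time step, to mitigate the order dependence of sequential updating.
#' Exchange is pairwise, so total mass on the (closed) grid is conserved to
#' machine precision and concentrations stay nonnegative.
#'
#' @param grid An [ocean_grid()].
#' @param metabolite Name of the field to advance.
#' @return The updated `ocean_grid`.
#' @export
diffusion_step <- function(grid, metabolite) {
  stopifnot(inherits(grid, "ocean_grid"))
  f <- grid$fields[[metabolite]]
  if (is.null(f)) stop(sprintf("no field for metabolite '%s'", metabolite))
  D <- grid$diffusivities[[metabolite]]
  if (is.null(D) || D <= 0) {
    return(grid) # eta = 0: diffusion halts, identity map
  }
  n_cells <- grid$width * grid$height
  if (n_cells == 1L) {
    return(grid)
  }
  dt_s <- grid$dt_h * 3600
  eta <- compute_eta(D, dt_s / 2) # half step per sweep
  offsets <- neighbor_offsets(grid$neighborhood)
  d2 <- (offsets$dr^2 + offsets$dc^2) * grid$delta_um^2
  w <- exp(-d2 / eta)
  fwd <- seq_len(n_cells)
  f <- diffusion_sweep(f, fwd, offsets, w, grid$height, grid$width)
  f <- diffusion_sweep(f, rev(fwd), offsets, w, grid$height, grid$width)
  grid$fields[[metabolite]] <- f
  grid
}

#' Surface boundary for atmospheric gases
#'
#' @param partial_pressures Named vector of gas partial pressures (atm).
#' @param henry_constants Named vector of Henry constants `K_H`
#'   (uM atm^-1); equilibrium dissolved concentration is `K_H * p`.
#' @return A `surface_boundary` object.
#' @export
surface_boundary <- function(partial_pressures, henry_constants) {
  stopifnot(
    all(partial_pressures >= 0), all(henry_constants >= 0),
    !is.null(names(partial_pressures)), !is.null(names(henry_constants))
  )
  structure(list(
    partial_pressures = partial_pressures,
    henry_constants = henry_constants
  ), class = "surface_boundary")
}

#' Exchange a dissolved gas with the atmosphere across the surface row
#'
#' Top-row gridcells relax toward the Henry's-law equilibrium concentration
#' `c_eq = K_H * p` by mono-directional slab diffusion: the fractional
#' approach per step is `min(1, D * dt / delta^2)`, so the update is
#' monotone and never overshoots the equilibrium. A zero partial pressure
#' drives the gas out of the water.
#'
#' @param grid An [ocean_grid()].
#' @param boundary A [surface_boundary()].
#' @param gas Gas name (must have a Henry constant in `boundary`).
#' @return The updated `ocean_grid`.
#' @export
surface_exchange <- function(grid, boundary, gas) {
  stopifnot(inherits(grid, "ocean_grid"), inherits(boundary, "surface_boundary"))
  if (!gas %in% names(boundary$henry_constants)) {
    stop(sprintf("no Henry constant configured for gas '%s'", gas))
  }
  kh <- boundary$henry_constants[[gas]]
  p <- if (gas %in% names(boundary$partial_pressures)) {
    boundary$partial_pressures[[gas]]
  } else {
    0
  }
  f <- grid$fields[[gas]]
  if (is.null(f)) stop(sprintf("no field for gas '%s'", gas))
  c_eq <- kh * p
  D <- grid$diffusivities[[gas]]
  lambda <- min(1, D * (grid$dt_h * 3600) / grid$delta_um^2)
  f[1, ] <- f[1, ] + lambda * (c_eq - f[1, ])
  grid$fields[[gas]] <- f
  grid
}

#' Light intensity at depth
#'
#' Beer-Lambert attenuation through the water column: `I = I0 * exp(-k*y)`.
#'
#' @param I0 Surface light intensity (uE).
#' @param k Extinction coefficient (m^-1).
#' @param y Depth below the surface (m), `>= 0`.
#' @return Light intensity at depth `y` (uE).
#' @export
light_at_depth <- function(I0, k, y) {
  stopifnot(all(y >= 0))
  I0 * exp(-k * y)
}

#' Partition a shared resource equally among competing cells
#'
#' Cells sharing a gridcell divide access to the locally available amount
#' equally: each receives `min(demand, equal share)` and any unclaimed share
#' is re-divided among still-unsatisfied cells until a fixed point. The
#' total allocation never exceeds the available amount.
#'
#' @param available Amount available in the gridcell (`>= 0`).
#' @param requests Numeric vector of per-cell demands (`>= 0`).
#' @return Numeric vector of per-cell allocations.
#' @export
partition_uptake <- function(available, requests) {
  stopifnot(available >= 0, all(requests >= 0))
  alloc <- numeric(length(requests))
  if (length(requests) == 0 || available == 0) {
    return(alloc)
  }
  remaining <- available
  repeat {
    unsat <- which(alloc < requests - 1e-12)
    if (length(unsat) == 0 || remaining <= 1e-15) break
    share <- remaining / length(unsat)
    grant <- pmin(requests[unsat] - alloc[unsat], share)
    alloc[unsat] <- alloc[unsat] + grant
    remaining <- remaining - sum(grant)
    if (sum(grant) <= 1e-15) break
  }
  alloc
}

#' Long-format snapshot of the grid fields
#'
#' @param grid An [ocean_grid()].
#' @param step Step index recorded in the output.
#' @return data.frame with columns `step`, `x`, `y`, `metabolite`,
#'   `concentration_uM`.
#' @export
grid_snapshot <- function(grid, step = 0L) {
  stopifnot(inherits(grid, "ocean_grid"))
  out <- lapply(names(grid$fields), function(m) {
    f <- grid$fields[[m]]
    data.frame(
      step = step,
      x = rep(seq_len(grid$width), each = grid$height),
      y = rep(seq_len(grid$height), times = grid$width),
      metabolite = m,
      concentration_uM = as.vector(f)
    )
  })
  do.call(rbind, out)
}
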