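# Mutable scalar objectives.
#
# Each cell re-weights its biomass-vs-storage objective every step from its
# own (non-metabolite) biomass: the probability z that a randomly drawn cell
# is no larger than this one scales the metabolite weight, while the
# remaining "expansion space" 1 - z scales the biomass weight. Small cells
# therefore prioritize growth and large cells prioritize storage-compound
# production, with switch-like behavior controlled by the width of the cell
# size distribution.

#' Cell mass distribution
#'
#' Cell biomass is modeled as Normal with mean `mean_mass` and standard
#' deviation `sd_fraction * mean_mass`. The defaults describe a 10 um cubic
#' cell at seawater density (mean 1.029e-9 g) with sd fraction 0.433, narrow
#' enough that a sampled cell falls below twice the mean with probability
#' ~99%, which is what gives the objective shift its bistable, switch-like
#' character.
#'
#' @param mean_mass Mean cell mass in grams (default [default_mean_mass()]).
#' @param sd_fraction Standard deviation as a fraction of the mean, in
#'   (0, 1) (default 0.433).
#' @return A `mass_distribution` with fields `mean`, `sd_fraction`, `sd`.
#' @export
mass_distribution <- function(mean_mass = default_mean_mass(),
                              sd_fraction = 0.433) {
  stopifnot(mean_mass > 0, sd_fraction > 0, sd_fraction < 1)
  structure(
    list(mean = mean_mass, sd_fraction = sd_fraction,
         sd = sd_fraction * mean_mass),
    class = "mass_distribution"
  )
}

#' Default mean cell mass from cell geometry
#'
#' Mass of a cubic cell: `density * side^3`, converted exactly to grams.
#' With the defaults (10 um side, seawater density 1029 kg m^-3) this is
#' 1.029e-9 g.
#'
#' @param side_um Cube edge length in micrometers (default 10).
#' @param density_kg_m3 Density in kg m^-3 (default 1029, seawater).
#' @return Mass in grams.
#' @export
default_mean_mass <- function(side_um = 10, density_kg_m3 = 1029) {
  stopifnot(side_um > 0, density_kg_m3 > 0)
  side_m <- side_um * 1e-6
  density_kg_m3 * side_m^3 * 1e3 # kg -> g
}

#' Cumulative probability of a cell mass
#'
#' `z = F(X <= x)` under the cell mass distribution: the probability that a
#' randomly drawn cell's biomass does not exceed `x`.
#'
#' @param x Cell mass in grams.
#' @param dist A [mass_distribution()].
#' @return `z` in `[0, 1]`.
#' @export
cumulative_mass_probability <- function(x, dist) {
  stopifnot(inherits(dist, "mass_distribution"))
  stats::pnorm(x, mean = dist$mean, sd = dist$sd)
}

#' Construct an objective weight pair
#'
#' @param w_b Biomass objective weight.
#' @param w_m Transactional-metabolite objective weight.
#' @param normalize Rescale so the weights sum to 1 (default `TRUE`).
#' @return An `objective_weights` object with fields `w_b`, `w_m`.
#' @export
objective_weights <- function(w_b, w_m, normalize = TRUE) {
  stopifnot(w_b >= 0, w_m >= 0, w_b + w_m > 0)
  if (normalize) {
    a_norm <- 1 / (w_b + w_m)
    w_b <- w_b * a_norm
    w_m <- w_m * a_norm
  }
  structure(list(w_b = w_b, w_m = w_m), class = "objective_weights")
}

#' Shift objective weights from a cell's biomass
#'
#' Given Pareto-matched base weights, the biomass weight is scaled by the
#' expansion space `eps = 1 - z` and the metabolite weight by `z`, where
#' `z` is the cell's [cumulative_mass_probability()]; the scaled weights are
#' then renormalized to sum to 1. At the distribution mean the base weights
#' are returned unchanged; very large cells converge to a pure metabolite
#' objective and very small cells to a pure biomass objective.
#'
#' When one scaled weight underflows to exactly zero together with its
#' partner (possible when `z` saturates at 0 or 1 against a zero base
#' weight), the result falls back to the corresponding pure single-objective
#' weights.
#'
#' @param base An [objective_weights()] pair (Pareto-matched base weights).
#' @param x Cell (non-metabolite) biomass in grams.
#' @param dist A [mass_distribution()].
#' @return A normalized [objective_weights()] pair.
#' @export
shift_weights <- function(base, x, dist) {
  stopifnot(inherits(base, "objective_weights"))
  z <- cumulative_mass_probability(x, dist)
  w_b_hat <- (1 - z) * base$w_b
  w_m_hat <- z * base$w_m
  tot <- w_b_hat + w_m_hat
  if (tot <= 0) {
    # degenerate saturation: fall back to the single surviving objective
    if (z >= 0.5) {
      return(objective_weights(0, 1, normalize = FALSE))
    }
    return(objective_weights(1, 0, normalize = FALSE))
  }
  objective_weights(w_b_hat / tot, w_m_hat / tot, normalize = FALSE)
}

#' Match objective weights to a Pareto-front point
#'
#' Selects the front point whose implied weight vector `(a, 1 - a)` is
#' closest in Euclidean distance to the target weights; for a front on a
#' regular `a` grid this is the point with `a` nearest `w_b`. Ties break
#' toward larger `a` (biomass).
#'
#' @param front A `pareto_front` from [generate_pareto_front()].
#' @param weights An [objective_weights()] pair.
#' @return The selected front row (one-row data.frame).
#' @export
match_pareto_point <- function(front, weights) {
  stopifnot(inherits(front, "pareto_front"))
  if (nrow(front) == 0) stop("empty Pareto front")
  stopifnot(inherits(weights, "objective_weights"))
  # distance^2 between (a, 1-a) and (w_b, w_m) is 2 * (a - w_b)^2
  d <- abs(front$a - weights$w_b)
  best <- which(d <= min(d) + 1e-15)
  front[best[which.max(front$a[best])], , drop = FALSE]
}

#' Sample a division threshold mass
#'
#' Draws from the cell mass distribution truncated at zero (physical masses
#' only). A cell divides when its biomass reaches or exceeds the draw.
#'
#' @param dist A [mass_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of threshold masses (grams), all `>= 0`.
#' @export
sample_division_threshold <- function(dist, n = 1) {
  stopifnot(inherits(dist, "mass_distribution"))
  out <- stats::rnorm(n, dist$mean, dist$sd)
  while (any(out < 0)) {
    k <- out < 0
    out[k] <- stats::rnorm(sum(k), dist$mean, dist$sd)
  }
  out
}
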