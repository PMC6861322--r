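# MetabolicNetwork: stoichiometry + bounds + the three named reactions that
# the scalarized objective machinery needs (biomass X, transactional
# metabolite m, ATP maintenance). Fluxes are mmol gDW^-1 h^-1 throughout.

#' Construct a metabolic network
#'
#' Bundles a stoichiometric matrix with reaction bounds and the identities of
#' the three special reactions used by the simulator: the biomass reaction
#' (the `X` objective), the transactional-metabolite sink (the `m` objective:
#' a beta-aspartyl-arginine sink for diazotrophs, a maltose sink for
#' photoautotrophs) and the ATP maintenance reaction whose flux is pinned to
#' the light-dependent maintenance demand.
#'
#' @param stoichiometry Numeric matrix, metabolites x reactions, with
#'   dimnames giving metabolite and reaction ids.
#' @param lower,upper Named or positional bound vectors, one per reaction,
#'   in mmol gDW^-1 h^-1. Infinite entries are clamped to `+/-big_bound`.
#' @param biomass_rxn,metabolite_rxn,atp_maintenance_rxn Reaction ids.
#' @param big_bound Magnitude used to replace infinite bounds (default 1000).
#' @return An object of class `metabolic_network`.
#' @export
metabolic_network <- function(stoichiometry, lower, upper,
                              biomass_rxn, metabolite_rxn,
                              atp_maintenance_rxn, big_bound = 1000) {
  if (is.null(dimnames(stoichiometry)) ||
      is.null(rownames(stoichiometry)) || is.null(colnames(stoichiometry))) {
    stop("stoichiometry must have metabolite rownames and reaction colnames")
  }
  rxns <- colnames(stoichiometry)
  mets <- rownames(stoichiometry)
  n <- length(rxns)
  if (length(lower) != n || length(upper) != n) {
    stop("bound vectors must match the number of reactions (dimension mismatch)")
  }
  lower <- stats::setNames(as.numeric(lower), rxns)
  upper <- stats::setNames(as.numeric(upper), rxns)
  lower[lower == -Inf] <- -big_bound
  upper[upper == Inf] <- big_bound
  if (any(lower > upper)) {
    bad <- rxns[lower > upper][1]
    stop(sprintf("lower bound exceeds upper bound for reaction '%s'", bad))
  }
  for (id in c(biomass_rxn, metabolite_rxn, atp_maintenance_rxn)) {
    if (!id %in% rxns) stop(sprintf("named reaction '%s' not in network", id))
  }
  if (identical(biomass_rxn, metabolite_rxn)) {
    stop("biomass_rxn and metabolite_rxn must differ")
  }
  structure(list(
    reactions = rxns,
    metabolites = mets,
    stoichiometry = stoichiometry,
    lower = lower,
    upper = upper,
    biomass_rxn = biomass_rxn,
    metabolite_rxn = metabolite_rxn,
    atp_maintenance_rxn = atp_maintenance_rxn
  ), class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf(
    "<metabolic_network> %d reactions x %d metabolites\n  biomass: %s | metabolite: %s | maintenance: %s\n",
    length(x$reactions), length(x$metabolites),
    x$biomass_rxn, x$metabolite_rxn, x$atp_maintenance_rxn
  ))
  invisible(x)
}

#' Read a metabolic network from JSON or SBML
#'
#' Two on-disk formats are supported. The packaged JSON dialect is
#' `{"reactions": [{"id", "bounds": [lb, ub], "stoich": {met: coeff}}],
#' "objectives": {"biomass", "metabolite", "atp_maintenance"}}`. SBML Level 3
#' documents are read with the `fbc` flux-bound attributes when present;
#' because plain SBML carries no objective annotation, the three special
#' reaction ids must then be supplied via `objectives`.
#'
#' @param path File path; format chosen by extension (`.json` vs
#'   `.xml`/`.sbml`).
#' @param objectives Optional named list/vector with entries `biomass`,
#'   `metabolite`, `atp_maintenance`; overrides ids found in the file.
#' @return A [metabolic_network()].
#' @export
read_network <- function(path, objectives = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    read_network_json(path, objectives)
  } else if (ext %in% c("xml", "sbml")) {
    read_network_sbml(path, objectives)
  } else {
    stop(sprintf("unrecognised network file extension '%s'", ext))
  }
}

read_network_json <- function(path, objectives = NULL) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$reactions)) stop("network JSON lacks a 'reactions' array")
  ids <- vapply(doc$reactions, function(r) as.character(r$id), character(1))
  mets <- unique(unlist(lapply(doc$reactions, function(r) names(r$stoich))))
  S <- matrix(0, length(mets), length(ids), dimnames = list(mets, ids))
  lb <- numeric(length(ids))
  ub <- numeric(length(ids))
  for (k in seq_along(doc$reactions)) {
    r <- doc$reactions[[k]]
    bounds <- unlist(r$bounds)
    if (length(bounds) != 2) {
      stop(sprintf("reaction '%s': bounds must be [lb, ub]", ids[k]))
    }
    if (bounds[1] > bounds[2]) {
      stop(sprintf("reaction '%s': lb > ub", ids[k]))
    }
    lb[k] <- bounds[1]
    ub[k] <- bounds[2]
    for (met in names(r$stoich)) S[met, k] <- as.numeric(r$stoich[[met]])
  }
  obj <- objectives
  if (is.null(obj)) obj <- doc$objectives
  need <- c("biomass", "metabolite", "atp_maintenance")
  missing <- setdiff(need, names(obj))
  if (length(missing) > 0) {
    stop(sprintf(
      "network is missing objective annotation for: %s",
      paste(missing, collapse = ", ")
    ))
  }
  metabolic_network(S, lb, ub,
    biomass_rxn = as.character(obj$biomass),
    metabolite_rxn = as.character(obj$metabolite),
    atp_maintenance_rxn = as.character(obj$atp_maintenance)
  )
}

read_network_sbml <- function(path, objectives = NULL) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  species <- xml2::xml_attr(sp, "id")
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pvals <- stats::setNames(
    as.numeric(xml2::xml_attr(params, "value")),
    xml2::xml_attr(params, "id")
  )
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rx) == 0) stop("SBML document contains no reactions")
  ids <- xml2::xml_attr(rx, "id")
  mets <- species[!boundary]
  S <- matrix(0, length(mets), length(ids), dimnames = list(mets, ids))
  lb <- numeric(length(ids))
  ub <- numeric(length(ids))
  for (k in seq_along(rx)) {
    r <- rx[[k]]
    for (ref in xml2::xml_find_all(r, "./listOfReactants/speciesReference")) {
      s <- xml2::xml_attr(ref, "species")
      coef <- as.numeric(xml2::xml_attr(ref, "stoichiometry"))
      if (is.na(coef)) coef <- 1
      if (s %in% mets) S[s, k] <- S[s, k] - coef
    }
    for (ref in xml2::xml_find_all(r, "./listOfProducts/speciesReference")) {
      s <- xml2::xml_attr(ref, "species")
      coef <- as.numeric(xml2::xml_attr(ref, "stoichiometry"))
      if (is.na(coef)) coef <- 1
      if (s %in% mets) S[s, k] <- S[s, k] + coef
    }
    lbp <- xml2::xml_attr(r, "lowerFluxBound")
    ubp <- xml2::xml_attr(r, "upperFluxBound")
    rev <- identical(xml2::xml_attr(r, "reversible"), "true")
    lb[k] <- if (!is.na(lbp) && lbp %in% names(pvals)) pvals[[lbp]] else if (rev) -1000 else 0
    ub[k] <- if (!is.na(ubp) && ubp %in% names(pvals)) pvals[[ubp]] else 1000
  }
  if (is.null(objectives)) {
    stop(paste(
      "SBML input carries no objective annotation;",
      "supply objectives = list(biomass=, metabolite=, atp_maintenance=)"
    ))
  }
  metabolic_network(S, lb, ub,
    biomass_rxn = as.character(objectives$biomass),
    metabolite_rxn = as.character(objectives$metabolite),
    atp_maintenance_rxn = as.character(objectives$atp_maintenance)
  )
}

#' Write a metabolic network to the packaged JSON dialect
#'
#' @param network A [metabolic_network()].
#' @param path Output file path.
#' @return `path`, invisibly. `read_network(write_network(x, p))` restores
#'   `x` losslessly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "metabolic_network"))
  reactions <- lapply(network$reactions, function(id) {
    col <- network$stoichiometry[, id]
    col <- col[col != 0]
    list(
      id = id,
      bounds = c(network$lower[[id]], network$upper[[id]]),
      stoich = as.list(col)
    )
  })
  doc <- list(
    reactions = reactions,
    objectives = list(
      biomass = network$biomass_rxn,
      metabolite = network$metabolite_rxn,
      atp_maintenance = network$atp_maintenance_rxn
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
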