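#' Generate a virtual stream-segment landscape
#'
#' Simulates a planar landscape of inter-confluence stream segments with
#' spatially autocorrelated habitat gradients, as a stand-in for a
#' GIS-derived segment framework. Habitat variables follow the usual
#' macrohabitat categories for stream fish (climate, geology, hydrology,
#' stream morphology, land cover, disturbance): each is driven by a
#' Gaussian random field with exponential covariance
#' \eqn{C(d) = (1-\nu)\exp(-d/\rho) + \nu 1[d=0]} evaluated at the segment
#' coordinates, then mapped to a realistic scale. Segments are grouped into
#' basins (coherent blocks of the extent) and nested coarse watershed units
#' used for resolution coarsening.
#'
#' @param n_segments number of stream segments
#' @param n_basins number of river basins (coherent spatial blocks)
#' @param n_units number of coarse watershed units (nested within basins)
#' @param spatial_range exponential covariance range \eqn{\rho}, in the same
#'   units as the landscape extent
#' @param extent side length of the square landscape
#' @param nugget fraction of habitat variance that is spatially independent
#' @param seed integer seed; identical arguments and seed give identical
#'   landscapes
#' @return an object of class \code{virtual_landscape}: a list with
#'   \code{segments} (data frame of segment_id, basin, unit_id, coordinates)
#'   and \code{habitat} (segments x variables numeric matrix)
#' @export
generate_landscape <- function(n_segments, n_basins = 4L, n_units = n_basins,
                               spatial_range = 25, extent = 100,
                               nugget = 0.3, seed = 1L) {
  if (n_segments < 1 || n_basins < 1 || n_units < 1) {
    stop_arg("n_segments, n_basins and n_units must be positive")
  }
  if (!(n_segments >= n_units && n_units >= n_basins)) {
    stop_arg("need n_segments >= n_units >= n_basins")
  }
  if (spatial_range <= 0) stop_arg("spatial_range must be > 0")
  if (nugget < 0 || nugget > 1) stop_arg("nugget must be in [0,1]")
  set.seed(seed)

  x <- stats::runif(n_segments, 0, extent)
  y <- stats::runif(n_segments, 0, extent)

  # basins as vertical strips (spatially coherent), units as y-ordered chunks
  # within each basin, so units nest inside basins
  basin_idx <- if (n_basins == 1L) rep(1L, n_segments) else {
    as.integer(cut(rank(x, ties.method = "first"),
                   breaks = n_basins, labels = FALSE))
  }
  basin <- paste0("basin_", basin_idx)
  units_per_basin <- diff(round(seq(0, n_units, length.out = n_basins + 1)))
  units_per_basin <- pmax(units_per_basin, 1L)
  unit_id <- character(n_segments)
  unit_counter <- 0L
  for (b in seq_len(n_basins)) {
    in_b <- which(basin_idx == b)
    k <- min(units_per_basin[b], length(in_b))
    chunk <- if (k == 1L) rep(1L, length(in_b)) else {
      as.integer(cut(rank(y[in_b], ties.method = "first"),
                     breaks = k, labels = FALSE))
    }
    unit_id[in_b] <- paste0("unit_", unit_counter + chunk)
    unit_counter <- unit_counter + k
  }

  d <- as.matrix(stats::dist(cbind(x, y)))
  K <- (1 - nugget) * exp(-d / spatial_range)
  diag(K) <- 1
  # jitter for numerical positive definiteness with near-duplicate coords
  L <- t(chol(K + diag(1e-8, n_segments)))

  vars <- c("tmp", "ppt", "ele", "slp", "flow", "bfi",
            "c_ub", "c_ag", "c_fr", "dist_score")
  z <- L %*% matrix(stats::rnorm(n_segments * length(vars)),
                    n_segments, length(vars))
  colnames(z) <- vars
  habitat <- cbind(
    tmp        = 12 + 5 * z[, "tmp"],          # mean annual temperature, C
    ppt        = 1000 + 250 * z[, "ppt"],      # annual precipitation, mm
    ele        = 300 + 150 * z[, "ele"],       # elevation, m
    slp        = exp(0.8 * z[, "slp"]),        # slope, degrees (log-normal)
    flow       = 10 * exp(z[, "flow"]),        # mean annual flow, cfs
    bfi        = 100 * inv_logit(z[, "bfi"]),  # base-flow index, %
    c_ub       = 100 * inv_logit(z[, "c_ub"] - 1.5),  # % urban cover
    c_ag       = 100 * inv_logit(z[, "c_ag"]),        # % agriculture
    c_fr       = 100 * inv_logit(z[, "c_fr"]),        # % forest
    dist_score = 100 * inv_logit(z[, "dist_score"])   # disturbance score
  )
  rownames(habitat) <- sprintf("seg_%04d", seq_len(n_segments))

  structure(list(
    segments = data.frame(
      segment_id = rownames(habitat), basin = basin, unit_id = unit_id,
      coord_x = x, coord_y = y, stringsAsFactors = FALSE
    ),
    habitat = habitat,
    spatial_range = spatial_range, extent = extent,
    nugget = nugget, seed = seed
  ), class = "virtual_landscape")
}

#' @export
print.virtual_landscape <- function(x, ...) {
  cat("Virtual landscape:", nrow(x$segments), "segments,",
      length(unique(x$segments$basin)), "basins,",
      length(unique(x$segments$unit_id)), "units,",
      ncol(x$habitat), "habitat variables\n")
  invisible(x)
}

# Contribution of one response curve to the occupancy logit.
# logistic(midpoint, slope): linear term slope*(x - midpoint), zero at the
#   midpoint so baseline_logit alone sets occupancy there.
# gaussian(optimum, breadth): -((x - optimum)/breadth)^2 / 2, peaking at 0.
# threshold(cutpoint, low_p, high_p): step on the probability scale,
#   logit(low_p) below the cutpoint and logit(high_p) above (infinite logits
#   allowed; plogis maps them back to exact 0/1).
response_contribution <- function(curve, x) {
  switch(curve$type,
    logistic  = curve$slope * (x - curve$midpoint),
    gaussian  = -((x - curve$optimum) / curve$breadth)^2 / 2,
    threshold = logit(ifelse(x > curve$cutpoint, curve$high_p, curve$low_p)),
    stop_arg("unknown response curve type: ", curve$type)
  )
}

# Width of a response curve in sd units of its variable: how much of the
# gradient the species tolerates. Used as the habitat-breadth rarity axis.
curve_width <- function(curve, x) {
  s <- stats::sd(x)
  switch(curve$type,
    logistic  = 4 / (abs(curve$slope) * s + 1e-12),
    gaussian  = 2 * curve$breadth / s,
    threshold = 0.25
  )
}

occupancy_logit <- function(curves, habitat, baseline_logit) {
  contrib <- rep(baseline_logit, nrow(habitat))
  for (v in names(curves)) {
    contrib <- contrib + response_contribution(curves[[v]], habitat[, v])
  }
  contrib
}

#' Generate virtual species with known niches
#'
#' Each virtual species has a baseline logit plus at most one response curve
#' per habitat variable (logistic, Gaussian, or threshold form); true
#' occupancy probability at a segment is the inverse logit of the summed
#' contributions. When \code{niche_spec} is NULL, species are drawn at
#' random: 1-3 habitat variables each, curve parameters anchored to the
#' observed quantiles of the variable, and the baseline calibrated by root
#' finding so that mean occupancy hits a target drawn from
#' \code{occupancy_targets}. A fraction of species is flagged as game
#' species (excluded from community-absence evidence downstream).
#'
#' @param landscape a \code{virtual_landscape}
#' @param n_species number of species (ignored when \code{niche_spec} given)
#' @param niche_spec optional list, one element per species, each with
#'   \code{curves} (named list keyed by habitat variable), and optionally
#'   \code{baseline_logit}, \code{detection_prob}, \code{is_game},
#'   \code{family_number}
#' @param occupancy_targets range of mean-occupancy targets for random species
#' @param detection_range range of per-visit detection probabilities
#' @param prop_game fraction of species flagged as game species
#' @param n_families number of families (phylogeny-surrogate covariate)
#' @param seed integer seed
#' @return list of \code{virtual_species} objects, each carrying
#'   \code{true_occupancy} per segment
#' @export
generate_species <- function(landscape, n_species = 20L, niche_spec = NULL,
                             occupancy_targets = c(0.1, 0.6),
                             detection_range = c(0.4, 0.9),
                             prop_game = 0.15,
                             n_families = max(2L, ceiling(n_species / 5)),
                             seed = 1L) {
  stopifnot(inherits(landscape, "virtual_landscape"))
  set.seed(seed)
  habitat <- landscape$habitat
  vars <- colnames(habitat)

  if (is.null(niche_spec)) {
    niche_spec <- replicate(n_species, {
      nv <- sample(1:3, 1)
      chosen <- sample(vars, nv)
      curves <- lapply(chosen, function(v) {
        x <- habitat[, v]
        if (stats::runif(1) < 0.5) {
          list(type = "logistic",
               midpoint = stats::quantile(x, stats::runif(1, 0.25, 0.75)),
               slope = sample(c(-1, 1), 1) *
                 stats::runif(1, 1, 3) / stats::sd(x))
        } else {
          list(type = "gaussian",
               optimum = stats::quantile(x, stats::runif(1, 0.2, 0.8)),
               breadth = stats::runif(1, 0.5, 1.5) * stats::sd(x))
        }
      })
      names(curves) <- chosen
      list(curves = curves)
    }, simplify = FALSE)
  }
  n_species <- length(niche_spec)

  lapply(seq_along(niche_spec), function(i) {
    sp <- niche_spec[[i]]
    if (length(sp$curves) < 1) stop_arg("each species needs >= 1 response curve")
    unknown <- setdiff(names(sp$curves), vars)
    if (length(unknown)) {
      stop_arg("niche_spec references unknown habitat variable(s): ",
               paste(unknown, collapse = ", "))
    }
    baseline <- sp$baseline_logit
    if (is.null(baseline)) {
      target <- stats::runif(1, occupancy_targets[1], occupancy_targets[2])
      contrib <- occupancy_logit(sp$curves, habitat, 0)
      baseline <- stats::uniroot(
        function(b) mean(inv_logit(b + contrib)) - target,
        lower = -30, upper = 30
      )$root
    }
    occ <- inv_logit(occupancy_logit(sp$curves, habitat, baseline))
    structure(list(
      species_id = sp$species_id %||% sprintf("sp_%03d", i),
      family_number = sp$family_number %||% sample.int(n_families, 1),
      is_game = sp$is_game %||% (stats::runif(1) < prop_game),
      response_curves = sp$curves,
      baseline_logit = baseline,
      detection_prob = sp$detection_prob %||%
        stats::runif(1, detection_range[1], detection_range[2]),
      true_occupancy = occ
    ), class = "virtual_species")
  })
}

#' @export
print.virtual_species <- function(x, ...) {
  cat("Virtual species", x$species_id, "| curves on:",
      paste(names(x$response_curves), collapse = ", "),
      sprintf("| mean occupancy %.3f | detection %.2f%s\n",
              mean(x$true_occupancy), x$detection_prob,
              if (x$is_game) " | game" else ""))
  invisible(x)
}

#' Survey design for community-based presence-only sampling
#'
#' @param visits_per_segment nonnegative integer, scalar or one per segment
#' @param effort_bias optional nonnegative per-segment weights; expected
#'   visits become \code{visits_per_segment * bias / mean(bias)} with
#'   Poisson-distributed realized counts (emulating uneven historical effort)
#' @param seed integer seed
#' @export
survey_design <- function(visits_per_segment = 3L, effort_bias = NULL,
                          seed = 1L) {
  if (any(visits_per_segment < 0)) stop_arg("visits_per_segment must be >= 0")
  structure(list(visits_per_segment = visits_per_segment,
                 effort_bias = effort_bias, seed = seed),
            class = "survey_design")
}

#' Simulate community-based presence-only survey records
#'
#' Occupancy is drawn once per segment per species from the species' true
#' occupancy probability and held fixed across visits (historical
#' accumulation treated as repeated observation of a quasi-static
#' distribution). On every visit to a segment, each occupying species is
#' recorded independently with its per-visit detection probability. Only
#' presence rows are emitted — absences are never observed directly, which
#' is precisely the data pathology the inferred-absence framework addresses.
#'
#' @param landscape a \code{virtual_landscape}
#' @param species_list list of \code{virtual_species}
#' @param design a \code{survey_design}
#' @return data frame of presence records with columns species_id,
#'   segment_id, basin, year (visit index), source
#' @export
simulate_surveys <- function(landscape, species_list, design = survey_design()) {
  stopifnot(inherits(landscape, "virtual_landscape"),
            inherits(design, "survey_design"))
  set.seed(design$seed)
  segs <- landscape$segments
  n <- nrow(segs)
  visits <- rep_len(design$visits_per_segment, n)
  if (!is.null(design$effort_bias)) {
    bias <- rep_len(design$effort_bias, n)
    if (any(bias < 0)) stop_arg("effort_bias must be nonnegative")
    visits <- stats::rpois(n, visits * bias / mean(bias))
  }
  max_v <- if (n > 0) max(visits, 0L) else 0L
  out <- vector("list", length(species_list))
  for (k in seq_along(species_list)) {
    sp <- species_list[[k]]
    occupied <- stats::rbinom(n, 1, sp$true_occupancy) == 1
    recs <- list()
    for (v in seq_len(max_v)) {
      active <- occupied & (visits >= v)
      detected <- active & (stats::runif(n) < sp$detection_prob)
      if (any(detected)) {
        recs[[length(recs) + 1L]] <- data.frame(
          species_id = sp$species_id,
          segment_id = segs$segment_id[detected],
          basin = segs$basin[detected],
          year = v, source = "survey",
          stringsAsFactors = FALSE
        )
      }
    }
    out[[k]] <- if (length(recs)) do.call(rbind, recs) else NULL
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(species_id = character(), segment_id = character(),
                      basin = character(), year = integer(),
                      source = character(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Species metadata table for a list of virtual species
#'
#' @param species_list list of \code{virtual_species}
#' @return data frame with species_id, family_number, is_game
#' @export
species_metadata <- function(species_list) {
  data.frame(
    species_id = vapply(species_list, `[[`, "", "species_id"),
    family_number = vapply(species_list, `[[`, 0L, "family_number"),
    is_game = vapply(species_list, `[[`, FALSE, "is_game"),
    stringsAsFactors = FALSE
  )
}

#' Classify virtual species into the eight rarity types
#'
#' Rarity follows the three classical dimensions — geographic range size,
#' habitat breadth, and local population size — each dichotomized
#' (large/small) to give eight classes A-H. Range size is the fraction of
#' segments whose true occupancy exceeds \code{occupancy_cut}; habitat
#' breadth is the mean response-curve width in sd units of each variable;
#' local population size is proxied by per-visit detection probability.
#' Cutoffs default to the median of each dimension across the supplied
#' species (relative rarity within the generated pool). The letter encoding
#' sets A as common on all three dimensions and H rare on all three, with
#' large-range/small-population species falling in classes B-D.
#'
#' @param species_list list of \code{virtual_species}
#' @param landscape the \code{virtual_landscape} they inhabit
#' @param occupancy_cut occupancy probability above which a segment counts
#'   as occupied for range size; default median of all occupancy values
#' @param cutoffs optional named list (range, breadth, population) of
#'   dichotomization thresholds; defaults to per-dimension medians
#' @return data frame: species_id, range_size, habitat_breadth,
#'   local_population, rarity_type
#' @export
classify_rarity <- function(species_list, landscape,
                            occupancy_cut = NULL, cutoffs = NULL) {
  stopifnot(inherits(landscape, "virtual_landscape"))
  occs <- lapply(species_list, `[[`, "true_occupancy")
  if (any(vapply(occs, is.null, TRUE))) stop_arg("species lack true_occupancy")
  if (is.null(occupancy_cut)) occupancy_cut <- stats::median(unlist(occs))

  range_size <- vapply(occs, function(o) mean(o > occupancy_cut), 0)
  habitat_breadth <- vapply(species_list, function(sp) {
    mean(vapply(names(sp$response_curves), function(v) {
      curve_width(sp$response_curves[[v]], landscape$habitat[, v])
    }, 0))
  }, 0)
  local_population <- vapply(species_list, `[[`, 0, "detection_prob")

  if (is.null(cutoffs)) {
    cutoffs <- list(range = stats::median(range_size),
                    breadth = stats::median(habitat_breadth),
                    population = stats::median(local_population))
  }
  small_range <- range_size <= cutoffs$range
  narrow <- habitat_breadth <= cutoffs$breadth
  small_pop <- local_population <= cutoffs$population
  rarity_type <- LETTERS[1 + small_pop + 2 * narrow + 4 * small_range]

  data.frame(
    species_id = vapply(species_list, `[[`, "", "species_id"),
    range_size = range_size, habitat_breadth = habitat_breadth,
    local_population = local_population, rarity_type = rarity_type,
    stringsAsFactors = FALSE
  )
}
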