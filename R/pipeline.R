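#' Restrict a metacommunity to a subset of segments
#'
#' @param metacommunity a \code{metacommunity}
#' @param segments segment ids to keep
#' @return a \code{metacommunity} over those segments
#' @export
subset_segments <- function(metacommunity, segments) {
  stopifnot(inherits(metacommunity, "metacommunity"))
  keep <- intersect(rownames(metacommunity$incidence), segments)
  if (!length(keep)) stop_arg("no matching segments")
  structure(list(
    incidence = metacommunity$incidence[keep, , drop = FALSE],
    species_meta = metacommunity$species_meta,
    segment_basin = metacommunity$segment_basin[keep]
  ), class = "metacommunity")
}

#' Assemble a labeled design matrix for one focal species
#'
#' Combines the inferred-absence labels with the habitat predictors:
#' presences of the focal species (label 1) and community-evidenced
#' inferred absences (label 0), with the habitat rows of those segments as
#' the design matrix. Optionally restricted to one basin.
#'
#' @param metacommunity a \code{metacommunity}
#' @param habitat segments x variables matrix (rownames = segment ids)
#' @param focal focal species id
#' @param basin optional basin to restrict to
#' @param min_other_nongame,exclude_game see \code{\link{infer_absences}}
#' @return list: focal, X, y, segment_id, basin
#' @export
build_species_dataset <- function(metacommunity, habitat, focal,
                                  basin = NULL, min_other_nongame = 1L,
                                  exclude_game = TRUE) {
  if (!is.null(basin)) {
    segs <- names(metacommunity$segment_basin)[
      metacommunity$segment_basin == basin]
    metacommunity <- subset_segments(metacommunity, segs)
  }
  labels <- infer_absences(metacommunity, focal,
                           min_other_nongame = min_other_nongame,
                           exclude_game = exclude_game)
  missing_hab <- setdiff(labels$segment_id, rownames(habitat))
  if (length(missing_hab)) {
    stop_arg("habitat rows missing for labeled segment(s): ",
             paste(utils::head(missing_hab, 5), collapse = ", "))
  }
  X <- habitat[labels$segment_id, , drop = FALSE]
  if (anyNA(X)) stop_arg("habitat matrix contains missing values")
  list(focal = focal, X = X, y = labels$label,
       segment_id = labels$segment_id, basin = labels$basin)
}

framework_defaults <- function() {
  list(
    # synthetic study conditions
    n_segments = 300, n_basins = 4, n_units = 60, spatial_range = 25,
    n_species = 30, visits = 3L, prop_game = 0.15,
    # pipeline settings
    model_types = c("lasso", "brt", "maxent"),
    spatial = c(FALSE, TRUE), resolutions = c("segment", "unit"),
    min_other_nongame = 1L, exclude_game = TRUE, r_threshold = 0.8,
    cv_k = 5, alpha = 0.05, pcnm_permutations = 199,
    background_mode = "inferred_absence",
    brt = list(learning_rate = 0.05, tree_complexity = 3,
               bag_fraction = 0.5, n_trees_max = 300, block = 25,
               cv_folds = 3),
    seed = 1L, out_dir = NULL
  )
}

#' Run the full community-based SDM framework
#'
#' End-to-end pipeline: simulate (or accept) a metacommunity of presence
#' records, build the incidence matrix, infer absences per focal species,
#' prune collinear habitat variables, optionally spatialize the predictors
#' on per-basin PCNM eigenvectors, fit the requested model kinds at
#' segment and coarse-unit resolution, and evaluate each fit by training
#' and stratified k-fold cross-validation AUC. Results are returned as a
#' long table (one row per species x basin x model x spatial flag x
#' resolution) feeding the blocked ANCOVA and Tukey contrasts. Every
#' random stage is seeded from the config seed; identical configs give
#' identical results. Failures of individual model fits are recorded in
#' \code{skipped} with the stage and reason, and never abort the run.
#'
#' @param config named list overriding the defaults: synthetic study
#'   conditions (\code{n_segments}, \code{n_basins}, \code{n_units},
#'   \code{spatial_range}, \code{n_species}, \code{visits},
#'   \code{prop_game}) or pre-built inputs (\code{occurrences},
#'   \code{habitat}, \code{species_meta}, \code{coords},
#'   \code{unit_mapping}, \code{rarity}); pipeline settings
#'   (\code{model_types}, \code{spatial}, \code{resolutions},
#'   \code{min_other_nongame}, \code{exclude_game}, \code{r_threshold},
#'   \code{cv_k}, \code{alpha}, \code{background_mode}, \code{brt},
#'   \code{seed}, \code{out_dir})
#' @return object of class \code{sdm_framework_result}: \code{results}
#'   (long table), \code{ancova}, \code{tukey_model_type}, \code{skipped},
#'   \code{pruned} variable report, and the resolved \code{config}
#' @export
run_framework <- function(config = list()) {
  cfg <- utils::modifyList(framework_defaults(), config)
  seed <- cfg$seed

  # ---- data: simulate unless supplied ----
  if (is.null(cfg$occurrences)) {
    landscape <- generate_landscape(cfg$n_segments, cfg$n_basins,
                                    cfg$n_units,
                                    spatial_range = cfg$spatial_range,
                                    seed = child_seed(seed, 1))
    species <- generate_species(landscape, cfg$n_species,
                                prop_game = cfg$prop_game,
                                seed = child_seed(seed, 2))
    occurrences <- simulate_surveys(
      landscape, species,
      survey_design(cfg$visits, seed = child_seed(seed, 3))
    )
    species_meta <- species_metadata(species)
    rarity <- classify_rarity(species, landscape)
    habitat <- landscape$habitat
    coords <- as.matrix(landscape$segments[, c("coord_x", "coord_y")])
    rownames(coords) <- landscape$segments$segment_id
    unit_mapping <- stats::setNames(landscape$segments$unit_id,
                                    landscape$segments$segment_id)
  } else {
    occurrences <- if (is.character(cfg$occurrences)) {
      read_occurrences(cfg$occurrences)
    } else cfg$occurrences
    species_meta <- cfg$species_meta
    rarity <- cfg$rarity
    habitat <- as.matrix(cfg$habitat)
    coords <- as.matrix(cfg$coords)
    unit_mapping <- cfg$unit_mapping
  }
  if (nrow(occurrences) == 0) stop_arg("no occurrence records")

  meta_seg <- build_incidence(occurrences, species_meta)
  pruned <- prune_collinear(habitat, r_threshold = cfg$r_threshold)
  vars <- colnames(pruned$habitat)

  # resolution-specific data bundles
  bundles <- list()
  if ("segment" %in% cfg$resolutions) {
    bundles$segment <- list(meta = meta_seg,
                            habitat = habitat[, vars, drop = FALSE],
                            coords = coords)
  }
  if ("unit" %in% cfg$resolutions) {
    if (is.null(unit_mapping)) stop_arg("unit resolution needs unit_mapping")
    cu <- coarsen(meta_seg, habitat[, vars, drop = FALSE], unit_mapping,
                  coords = coords)
    bundles$unit <- list(meta = cu$metacommunity, habitat = cu$habitat,
                         coords = cu$coords)
  }

  # per (resolution, basin): spatialized habitat of the sampled segments
  spatial_hab <- list()
  skipped <- list()
  if (any(cfg$spatial)) {
    for (res in names(bundles)) {
      b <- bundles[[res]]
      for (bas in unique(b$meta$segment_basin)) {
        segs <- names(b$meta$segment_basin)[b$meta$segment_basin == bas]
        key <- paste(res, bas, sep = "|")
        sp_hab <- tryCatch({
          if (length(segs) < 10) stop_arg("too few sampled segments")
          basis <- pcnm(b$coords[segs, , drop = FALSE],
                        n_permutations = cfg$pcnm_permutations,
                        seed = child_seed(seed, 7))
          basis <- select_vectors(basis, alpha = cfg$alpha)
          spatialize(b$habitat[segs, , drop = FALSE], basis)
        }, error = function(e) {
          skipped[[length(skipped) + 1L]] <<- data.frame(
            stage = "spatialize", species = NA, basin = bas,
            resolution = res, reason = conditionMessage(e))
          NULL
        })
        if (!is.null(sp_hab)) spatial_hab[[key]] <- sp_hab
      }
    }
  }

  focal_pool <- cfg$focal_species %||%
    species_meta$species_id[!species_meta$is_game]

  fit_funs <- function(model_type, fit_seed) {
    switch(model_type,
      lasso = function(X, y) fit_lasso_logistic(X, y, cv_folds = cfg$cv_k,
                                                seed = fit_seed),
      brt = function(X, y) {
        do.call(fit_brt, c(list(X = X, y = y, seed = fit_seed), cfg$brt))
      },
      maxent = function(X, y) {
        fit_presence_background(X[y == 1, , drop = FALSE],
                                X[y == 0, , drop = FALSE],
                                mode = cfg$background_mode,
                                cv_folds = cfg$cv_k, seed = fit_seed)
      },
      stop_arg("unknown model type: ", model_type))
  }

  rows <- list()
  combo <- 0L
  for (res in names(bundles)) {
    b <- bundles[[res]]
    basins <- unique(b$meta$segment_basin)
    for (bas in basins) {
      for (focal in focal_pool) {
        ds <- tryCatch(
          build_species_dataset(b$meta, b$habitat, focal, basin = bas,
                                min_other_nongame = cfg$min_other_nongame,
                                exclude_game = cfg$exclude_game),
          error = function(e) NULL)
        if (is.null(ds) || min(table(factor(ds$y, levels = 0:1))) < cfg$cv_k) {
          skipped[[length(skipped) + 1L]] <- data.frame(
            stage = "dataset", species = focal, basin = bas,
            resolution = res, reason = "insufficient labeled data")
          next
        }
        for (sp_flag in cfg$spatial) {
          Xd <- ds$X
          if (sp_flag) {
            sh <- spatial_hab[[paste(res, bas, sep = "|")]]
            if (is.null(sh)) next
            Xd <- sh[ds$segment_id, , drop = FALSE]
          }
          if (sp_flag && model_negates_spatial(Xd)) next
          for (mt in cfg$model_types) {
            combo <- combo + 1L
            # maxent with random background swaps the negative class
            Xy <- list(X = Xd, y = ds$y)
            if (mt == "maxent" && cfg$background_mode == "random_background") {
              hab_all <- if (sp_flag) {
                spatial_hab[[paste(res, bas, sep = "|")]]
              } else {
                segs <- names(b$meta$segment_basin)[
                  b$meta$segment_basin == bas]
                b$habitat[segs, , drop = FALSE]
              }
              bg <- sample_background(hab_all,
                                      exclude = ds$segment_id[ds$y == 1],
                                      n = sum(ds$y == 0),
                                      seed = child_seed(seed, 100 + combo))
              Xy <- list(X = rbind(Xd[ds$y == 1, , drop = FALSE], bg),
                         y = c(rep(1L, sum(ds$y == 1)),
                               rep(0L, nrow(bg))))
            }
            fit_seed <- child_seed(seed, 1000 + combo)
            row <- tryCatch({
              ev <- kfold_cv(fit_funs(mt, fit_seed), Xy$X, Xy$y,
                             k = cfg$cv_k, seed = fit_seed)
              data.frame(
                species_id = focal, basin = bas, model_type = mt,
                spatial = if (sp_flag) "yes" else "no", resolution = res,
                rarity_type = rarity$rarity_type[
                  match(focal, rarity$species_id)] %||% NA,
                family_number = species_meta$family_number[
                  match(focal, species_meta$species_id)],
                prevalence = mean(ds$y), n_obs = length(ds$y),
                auc_train = ev$auc_train, auc_cv = ev$auc_cv,
                seed = fit_seed, stringsAsFactors = FALSE)
            }, error = function(e) {
              skipped[[length(skipped) + 1L]] <<- data.frame(
                stage = paste0("fit:", mt), species = focal, basin = bas,
                resolution = res, reason = conditionMessage(e))
              NULL
            })
            if (!is.null(row)) rows[[length(rows) + 1L]] <- row
          }
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  skipped <- if (length(skipped)) do.call(rbind, skipped) else NULL

  ancova <- NULL
  tukey <- NULL
  if (!is.null(results) && nrow(results) >= 20) {
    ancova <- tryCatch(suppressWarnings(ancova_auc(results)),
                       error = function(e) NULL)
    if (!is.null(ancova) && length(unique(results$model_type)) >= 2) {
      tukey <- tryCatch(tukey_hsd_auc(ancova, "model_type"),
                        error = function(e) NULL)
    }
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(results, file.path(cfg$out_dir, "model_performance.csv"),
                     row.names = FALSE)
    if (!is.null(ancova)) {
      utils::write.csv(ancova$table, file.path(cfg$out_dir, "ancova.csv"),
                       row.names = FALSE)
    }
    if (!is.null(tukey)) {
      utils::write.csv(tukey$table,
                       file.path(cfg$out_dir, "tukey_model_type.csv"),
                       row.names = FALSE)
    }
  }

  structure(list(results = results, ancova = ancova,
                 tukey_model_type = tukey, skipped = skipped,
                 pruned = pruned$dropped, config = cfg),
            class = "sdm_framework_result")
}

# spatialized matrices can collapse to near-constant columns on tiny basins
model_negates_spatial <- function(X) {
  all(apply(X, 2, stats::sd) < 1e-10)
}

#' @export
print.sdm_framework_result <- function(x, ...) {
  cat("SDM framework run:", if (is.null(x$results)) 0 else nrow(x$results),
      "fitted models,",
      if (is.null(x$skipped)) 0 else nrow(x$skipped), "skipped\n")
  if (!is.null(x$results)) {
    agg <- stats::aggregate(auc_cv ~ model_type + spatial, x$results, mean)
    print(agg, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Inferred-absence versus random-background comparison
#'
#' The headline experiment: on community-sampled synthetic data, compare
#' the cross-validated AUC of (a) the presence-absence Lasso logistic
#' model on inferred absences, (b) the presence-background surrogate with
#' the same inferred absences as its negative class, and (c) the
#' presence-background surrogate with random background points — the
#' default pseudo-absence setting of presence-only models. Background
#' points that fall on actually occupied segments introduce false
#' negatives, which is why the inferred-absence arms should validate
#' better.
#'
#' Historical survey effort is uneven: only \code{sampled_fraction} of the
#' segments are ever visited, so the background pool contains unsampled
#' occupied habitat while inferred absences are confined to
#' community-evidenced segments.
#'
#' @param n_species number of focal (non-game) species evaluated
#' @param n_segments,n_basins,n_units,spatial_range,visits synthetic study
#'   conditions
#' @param sampled_fraction fraction of segments that receive any survey
#'   visits
#' @param cv_k cross-validation folds
#' @param seed integer seed
#' @return data frame, one row per evaluated species: auc_pa_lasso,
#'   auc_po_inferred, auc_po_background (paired)
#' @export
background_comparison_experiment <- function(n_species = 20, n_segments = 300,
                                             n_basins = 1, n_units = 10,
                                             spatial_range = 25, visits = 3L,
                                             sampled_fraction = 0.6,
                                             cv_k = 5, seed = 1L) {
  landscape <- generate_landscape(n_segments, n_basins, n_units,
                                  spatial_range = spatial_range,
                                  seed = child_seed(seed, 1))
  # extra community species beyond the focal pool provide absence evidence
  species <- generate_species(landscape, n_species + 10, prop_game = 0.15,
                              seed = child_seed(seed, 2))
  set.seed(child_seed(seed, 4))
  visit_vec <- visits *
    stats::rbinom(n_segments, 1, sampled_fraction)
  occ <- simulate_surveys(landscape, species,
                          survey_design(visit_vec, seed = child_seed(seed, 3)))
  meta <- build_incidence(occ, species_metadata(species))
  habitat <- landscape$habitat

  nongame <- species_metadata(species)
  focals <- nongame$species_id[!nongame$is_game &
                                 nongame$species_id %in% colnames(meta$incidence)]
  rows <- list()
  for (i in seq_along(focals)) {
    if (length(rows) >= n_species) break
    focal <- focals[i]
    ds <- build_species_dataset(meta, habitat, focal)
    if (min(table(factor(ds$y, levels = 0:1))) < cv_k) next
    s <- child_seed(seed, 100 + i)

    pa <- kfold_cv(function(X, y) fit_lasso_logistic(X, y, cv_folds = cv_k,
                                                     seed = s),
                   ds$X, ds$y, k = cv_k, seed = s)
    po_inf <- kfold_cv(function(X, y) {
      fit_presence_background(X[y == 1, , drop = FALSE],
                              X[y == 0, , drop = FALSE],
                              mode = "inferred_absence", cv_folds = cv_k,
                              seed = s)
    }, ds$X, ds$y, k = cv_k, seed = s)

    bg <- sample_background(habitat, exclude = ds$segment_id[ds$y == 1],
                            n = sum(ds$y == 0), seed = s)
    Xpo <- rbind(ds$X[ds$y == 1, , drop = FALSE], bg)
    ypo <- c(rep(1L, sum(ds$y == 1)), rep(0L, nrow(bg)))
    po_bg <- kfold_cv(function(X, y) {
      fit_presence_background(X[y == 1, , drop = FALSE],
                              X[y == 0, , drop = FALSE],
                              mode = "random_background", cv_folds = cv_k,
                              seed = s)
    }, Xpo, ypo, k = cv_k, seed = s)

    rows[[length(rows) + 1L]] <- data.frame(
      species_id = focal, prevalence = mean(ds$y), n_obs = length(ds$y),
      auc_pa_lasso = pa$auc_cv, auc_po_inferred = po_inf$auc_cv,
      auc_po_background = po_bg$auc_cv, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Spatial filtering diagnostic experiment
#'
#' Reproduces the residual-autocorrelation diagnostic: each replicate
#' simulates a habitat variable as a smooth spatial field observed with
#' independent noise, and a species responding to the smooth component
#' only. A non-spatial logistic fit to the noisy observed variable leaves
#' the unexplained smooth signal in its deviance residuals — significant
#' Moran's I — while refitting on the spatialized (PCNM-projected)
#' predictor, which recovers the smooth component, reduces the residual
#' autocorrelation.
#'
#' @param n_replicates number of simulated species
#' @param n_segments sites per replicate
#' @param spatial_range covariance range of the smooth field (extent 100)
#' @param nugget observation-noise share of the habitat variance
#' @param effect logit-scale effect size of the smooth field (per sd)
#' @param n_permutations Moran permutations
#' @param seed integer seed
#' @return data frame per replicate: p_nonspatial, p_spatial,
#'   n_selected_vectors
#' @export
spatial_filtering_experiment <- function(n_replicates = 25, n_segments = 150,
                                         spatial_range = 30, nugget = 0.6,
                                         effect = 2.5, n_permutations = 199,
                                         seed = 1L) {
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    s <- child_seed(seed, r)
    set.seed(s)
    x <- stats::runif(n_segments, 0, 100)
    y_ <- stats::runif(n_segments, 0, 100)
    d <- as.matrix(stats::dist(cbind(x, y_)))
    K <- exp(-d / spatial_range)
    smooth <- t(chol(K + diag(1e-8, n_segments))) %*% stats::rnorm(n_segments)
    smooth <- as.numeric(scale(smooth))
    observed <- sqrt(1 - nugget) * smooth +
      sqrt(nugget) * stats::rnorm(n_segments)
    noise_var <- stats::rnorm(n_segments)   # an uninformative extra predictor
    X <- cbind(hab = observed, other = noise_var)
    rownames(X) <- paste0("s", seq_len(n_segments))
    yy <- stats::rbinom(n_segments, 1, inv_logit(effect * smooth))
    if (length(unique(yy)) < 2) next

    w <- (d <= mst_longest_edge(d)) * 1
    diag(w) <- 0

    m0 <- fit_glm_logistic(X, yy)
    p0 <- residual_moran_test(m0, X, yy, w,
                              n_permutations = n_permutations,
                              seed = child_seed(s, 1))$p_value

    p1 <- NA_real_
    nsel <- 0L
    basis <- select_vectors(pcnm(cbind(x, y_),
                                 n_permutations = n_permutations,
                                 seed = child_seed(s, 2)))
    nsel <- sum(basis$selected)
    if (nsel > 0) {
      Xs <- spatialize(X, basis)
      m1 <- fit_glm_logistic(Xs, yy)
      p1 <- residual_moran_test(m1, Xs, yy, w,
                                n_permutations = n_permutations,
                                seed = child_seed(s, 3))$p_value
    }
    rows[[r]] <- data.frame(replicate = r, p_nonspatial = p0,
                            p_spatial = p1, n_selected_vectors = nsel)
  }
  do.call(rbind, rows)
}

#' Threshold recovery by boosted-tree partial dependence
#'
#' Each replicate plants a virtual species with a sharp occupancy
#' threshold on one habitat variable (step from \code{low_p} to
#' \code{high_p} at the variable's median), fits a boosted regression tree
#' on the full habitat matrix, and asks whether the partial dependence
#' curve detects a threshold within one grid step of the planted
#' cutpoint.
#'
#' @param n_replicates replicates
#' @param n_segments sample size per replicate
#' @param variable habitat variable carrying the threshold
#' @param low_p,high_p occupancy below/above the cutpoint
#' @param n_grid partial dependence grid size
#' @param brt_args list of \code{\link{fit_brt}} settings
#' @param seed integer seed
#' @return data frame per replicate: cutpoint, detected_threshold,
#'   grid_step, recovered (within one grid step), top_variable
#' @export
brt_threshold_experiment <- function(n_replicates = 20, n_segments = 500,
                                     variable = "tmp", low_p = 0.1,
                                     high_p = 0.9, n_grid = 50,
                                     brt_args = list(learning_rate = 0.05,
                                                     n_trees_max = 300,
                                                     block = 25,
                                                     cv_folds = 3),
                                     seed = 1L) {
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    s <- child_seed(seed, r)
    landscape <- generate_landscape(n_segments, 1, 1, spatial_range = 25,
                                    seed = s)
    cut <- stats::median(landscape$habitat[, variable])
    niche <- list(list(curves = stats::setNames(list(
      list(type = "threshold", cutpoint = cut, low_p = low_p,
           high_p = high_p)), variable),
      baseline_logit = 0, detection_prob = 1))
    sp <- generate_species(landscape, niche_spec = niche,
                           seed = child_seed(s, 1))[[1]]
    set.seed(child_seed(s, 2))
    yy <- stats::rbinom(n_segments, 1, sp$true_occupancy)
    fit <- do.call(fit_brt, c(list(X = landscape$habitat, y = yy,
                                   seed = child_seed(s, 3)), brt_args))
    pd <- partial_dependence(fit, variable, n_grid = n_grid)
    step <- diff(pd$curve$grid[1:2])
    rows[[r]] <- data.frame(
      replicate = r, cutpoint = cut,
      detected_threshold = pd$detected_threshold, grid_step = step,
      recovered = !is.na(pd$detected_threshold) &&
        abs(pd$detected_threshold - cut) <= step,
      top_variable = variable_importance(fit)$variable[1],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Planted-driver recovery in boosted-tree variable importance
#'
#' Each replicate plants one strongly informative habitat variable (steep
#' logistic response) among the remaining uninformative ones, fits a
#' boosted regression tree, and records whether the planted driver ranks
#' first in relative influence.
#'
#' @param n_replicates replicates
#' @param n_segments sample size per replicate
#' @param variable planted driver
#' @param slope_sd logistic slope in sd units of the driver
#' @param brt_args list of \code{\link{fit_brt}} settings
#' @param seed integer seed
#' @return data frame per replicate: top_variable, planted_first,
#'   planted_influence
#' @export
influence_recovery_experiment <- function(n_replicates = 25,
                                          n_segments = 300,
                                          variable = "tmp", slope_sd = 2,
                                          brt_args = list(learning_rate = 0.05,
                                                          n_trees_max = 300,
                                                          block = 25,
                                                          cv_folds = 3),
                                          seed = 1L) {
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    s <- child_seed(seed, r)
    landscape <- generate_landscape(n_segments, 1, 1, spatial_range = 25,
                                    seed = s)
    x <- landscape$habitat[, variable]
    niche <- list(list(curves = stats::setNames(list(
      list(type = "logistic", midpoint = stats::median(x),
           slope = slope_sd / stats::sd(x))), variable),
      baseline_logit = 0, detection_prob = 1))
    sp <- generate_species(landscape, niche_spec = niche,
                           seed = child_seed(s, 1))[[1]]
    set.seed(child_seed(s, 2))
    yy <- stats::rbinom(n_segments, 1, sp$true_occupancy)
    fit <- do.call(fit_brt, c(list(X = landscape$habitat, y = yy,
                                   seed = child_seed(s, 3)), brt_args))
    vi <- variable_importance(fit)
    rows[[r]] <- data.frame(
      replicate = r, top_variable = vi$variable[1],
      planted_first = vi$variable[1] == variable,
      planted_influence = vi$influence[vi$variable == variable],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
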