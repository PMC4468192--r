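#' Plain (unpenalized) logistic regression under the common SDM contract
#'
#' Maximum-likelihood logistic fit used by the prevalence bootstrap, where
#' the paper-style experiment fits an ordinary logistic model to each
#' resample. Aliased coefficients are set to zero.
#'
#' @param X predictor matrix
#' @param y 0/1 response
#' @return object of class \code{glm_sdm}
#' @export
fit_glm_logistic <- function(X, y) {
  X <- as.matrix(X)
  check_binary_labels(y)
  fit <- suppressWarnings(
    stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                   family = stats::binomial())
  )
  beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  structure(list(beta = beta, columns = colnames(X),
                 converged = fit$converged, X = X, y = y),
            class = c("glm_sdm", "sdm_model"))
}

#' @export
predict_probability.glm_sdm <- function(model, X) {
  X <- check_columns(model, X)
  as.numeric(inv_logit(model$beta[1] + X %*% model$beta[-1]))
}

#' Prevalence bootstrap experiment
#'
#' Resamples a labeled presence/absence dataset to fixed total sample size
#' and a grid of prevalences (exact class counts, drawn without
#' replacement within each replicate), fits a logistic model to each
#' resample, and records training AUC and k-fold cross-validation AUC.
#' Cell means over the bootstrap replicates expose the U-shaped response
#' of training AUC to prevalence — an artifact of the Bernoulli variance
#' peaking at 0.5 — and its absence in cross-validation.
#'
#' @param dataset list with predictor matrix \code{X} and 0/1 \code{y}
#' @param n_total total resample size (presences + absences)
#' @param prevalence_grid prevalences in (0,1)
#' @param n_boot bootstrap replicates per grid point
#' @param cv_k cross-validation folds
#' @param fit_fun model recipe, default plain logistic
#' @param seed integer master seed
#' @return object of class \code{prevalence_experiment}: per-cell data
#'   frame of mean/sd training and cv AUC; cells with insufficient records
#'   are flagged, never fabricated
#' @export
prevalence_experiment <- function(dataset, n_total = 100,
                                  prevalence_grid = seq(0.1, 0.9, by = 0.1),
                                  n_boot = 100, cv_k = 10,
                                  fit_fun = fit_glm_logistic, seed = 1L) {
  X <- as.matrix(dataset$X)
  y <- dataset$y
  check_binary_labels(y)
  if (any(prevalence_grid <= 0 | prevalence_grid >= 1)) {
    stop_arg("prevalence_grid must lie in (0,1)")
  }
  pres <- which(y == 1)
  abs_ <- which(y == 0)

  cells <- lapply(seq_along(prevalence_grid), function(gi) {
    p <- prevalence_grid[gi]
    n_pres <- round(p * n_total)
    n_abs <- n_total - n_pres
    if (n_pres > length(pres) || n_abs > length(abs_) ||
        n_pres < cv_k || n_abs < cv_k) {
      return(data.frame(prevalence = p, n_pres = n_pres, n_abs = n_abs,
                        mean_auc_train = NA_real_, sd_auc_train = NA_real_,
                        mean_auc_cv = NA_real_, sd_auc_cv = NA_real_,
                        n_boot = 0L, insufficient = TRUE))
    }
    tr <- cv <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      s <- child_seed(seed, gi * 10000 + b)
      set.seed(s)
      idx <- c(sample(pres, n_pres), sample(abs_, n_abs))
      Xi <- X[idx, , drop = FALSE]
      yi <- y[idx]
      res <- kfold_cv(fit_fun, Xi, yi, k = cv_k, seed = s)
      tr[b] <- res$auc_train
      cv[b] <- res$auc_cv
    }
    data.frame(prevalence = p, n_pres = n_pres, n_abs = n_abs,
               mean_auc_train = mean(tr), sd_auc_train = stats::sd(tr),
               mean_auc_cv = mean(cv), sd_auc_cv = stats::sd(cv),
               n_boot = n_boot, insufficient = FALSE)
  })
  structure(list(cells = do.call(rbind, cells), n_total = n_total,
                 cv_k = cv_k, seed = seed),
            class = "prevalence_experiment")
}

#' @export
print.prevalence_experiment <- function(x, ...) {
  cat("Prevalence bootstrap, n_total =", x$n_total, "\n")
  print(x$cells, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Box-Cox transformation
#'
#' \eqn{(v^\lambda - 1)/\lambda} for \eqn{\lambda \ne 0}, \eqn{\ln v} for
#' \eqn{\lambda = 0}. When \code{lambda} is NULL it is chosen by profile
#' maximum likelihood on a fixed grid (via \code{MASS::boxcox} of the
#' intercept-only model).
#'
#' @param values strictly positive numeric vector
#' @param lambda transform parameter, or NULL for automatic selection
#' @param grid search grid for automatic selection
#' @return list with \code{values} (transformed) and \code{lambda}
#' @export
boxcox_transform <- function(values, lambda = NULL,
                             grid = seq(-2, 2, by = 0.01)) {
  if (any(values <= 0)) stop_arg("Box-Cox requires strictly positive values")
  if (is.null(lambda)) {
    prof <- MASS::boxcox(values ~ 1, lambda = grid, plotit = FALSE)
    lambda <- prof$x[which.max(prof$y)]
  }
  transformed <- if (lambda == 0) log(values) else (values^lambda - 1) / lambda
  list(values = transformed, lambda = lambda)
}

ancova_default_terms <- c("model_type", "spatial", "rarity_type",
                          "resolution", "basin", "species_id",
                          "family_number")

#' Blocked ANCOVA on model-performance AUC
#'
#' Linear model of (Box-Cox transformed) cross-validation AUC with
#' additive terms for the treatment factors (model type, spatial flag,
#' rarity type, resolution), the blocking factors (basin, species — only
#' models of the same species x basin dataset are directly comparable),
#' and the family-number covariate as a phylogeny surrogate. Sums of
#' squares are sequential (Type I) in the listed term order; F ratios use
#' the residual mean square. Terms with a single observed level are
#' dropped with a warning, as are aliased columns (e.g. species fully
#' nested in rarity), whose degrees of freedom the fit absorbs.
#'
#' @param results long-format data frame with one row per fitted model and
#'   the columns named in \code{terms} plus the response
#' @param response response column, default cross-validation AUC
#' @param terms model terms in sequential order
#' @param use_boxcox transform the response first
#' @param boxcox_lambda fixed transform parameter (NULL = profile ML)
#' @return object of class \code{ancova_result}: ANCOVA \code{table}
#'   (source, df, sum_sq, mean_sq, F, p), \code{boxcox_lambda}, the fitted
#'   \code{model}, and the analysis \code{data}
#' @export
ancova_auc <- function(results, response = "auc_cv",
                       terms = ancova_default_terms,
                       use_boxcox = TRUE, boxcox_lambda = NULL) {
  terms <- intersect(terms, names(results))
  if (!length(terms)) stop_arg("no model terms present in results")
  df <- results[stats::complete.cases(results[, c(terms, response)]),
                c(terms, response), drop = FALSE]
  for (tm in setdiff(terms, "family_number")) df[[tm]] <- factor(df[[tm]])

  single <- terms[vapply(terms, function(tm) {
    is.factor(df[[tm]]) && nlevels(droplevels(df[[tm]])) < 2
  }, TRUE)]
  if (length(single)) {
    warning("dropping single-level term(s): ", paste(single, collapse = ", "),
            call. = FALSE)
    terms <- setdiff(terms, single)
  }

  v <- df[[response]]
  lambda <- NA_real_
  if (use_boxcox) {
    bc <- boxcox_transform(v, lambda = boxcox_lambda)
    v <- bc$values
    lambda <- bc$lambda
  }
  df$.response <- v
  fml <- stats::reformulate(terms, response = ".response")
  fit <- stats::lm(fml, data = df)
  if (anyNA(stats::coef(fit))) {
    warning("aliased term levels dropped (rank-deficient design)",
            call. = FALSE)
  }
  at <- stats::anova(fit)
  table <- data.frame(source = rownames(at), df = at$Df,
                      sum_sq = at$`Sum Sq`, mean_sq = at$`Mean Sq`,
                      F = at$`F value`, p = at$`Pr(>F)`,
                      stringsAsFactors = FALSE)
  structure(list(table = table, boxcox_lambda = lambda, model = fit,
                 data = df, formula = fml, response = response),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA on %s (Box-Cox lambda = %.2f)\n",
              x$response, x$boxcox_lambda))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tukey HSD contrasts after the ANCOVA
#'
#' All pairwise level differences of a factor with family-wise
#' studentized-range intervals, from the analysis-of-variance refit of the
#' ANCOVA model.
#'
#' @param ancova an \code{ancova_result}
#' @param factor factor name with at least 2 levels
#' @param conf_level family-wise confidence level
#' @return object of class \code{tukey_result}: data frame with pair,
#'   difference, lower, upper, p_adj
#' @export
tukey_hsd_auc <- function(ancova, factor = "model_type", conf_level = 0.95) {
  stopifnot(inherits(ancova, "ancova_result"))
  df <- ancova$data
  if (!factor %in% names(df)) stop_arg("factor not in the analysis data: ", factor)
  if (nlevels(droplevels(df[[factor]])) < 2) {
    stop_arg("factor needs >= 2 levels: ", factor)
  }
  a <- stats::aov(ancova$formula, data = df)
  th <- suppressWarnings(
    stats::TukeyHSD(a, which = factor, conf.level = conf_level)
  )[[factor]]
  structure(list(
    table = data.frame(pair = rownames(th), difference = th[, "diff"],
                       lower = th[, "lwr"], upper = th[, "upr"],
                       p_adj = th[, "p adj"], stringsAsFactors = FALSE,
                       row.names = NULL),
    factor = factor, conf_level = conf_level
  ), class = "tukey_result")
}

#' @export
print.tukey_result <- function(x, ...) {
  cat("Tukey HSD on", x$factor, "\n")
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Type-I error calibration of the Moran's I permutation test
#'
#' Simulates spatially random variables on a fixed random site layout and
#' reports the rejection rate at \code{alpha}, which should match
#' \code{alpha} when the permutation test is calibrated.
#'
#' @param n_vars number of independent null variables
#' @param n_sites number of sites
#' @param alpha nominal level
#' @param n_permutations permutations per test
#' @param seed integer seed
#' @return list with \code{rejection_rate}, \code{n_vars}, \code{alpha}
#' @export
moran_type1_calibration <- function(n_vars = 500, n_sites = 100,
                                    alpha = 0.05, n_permutations = 999,
                                    seed = 1L) {
  set.seed(seed)
  coords <- cbind(stats::runif(n_sites), stats::runif(n_sites))
  d <- as.matrix(stats::dist(coords))
  t0 <- mst_longest_edge(d)
  w <- (d <= t0) * 1
  diag(w) <- 0
  rejected <- vapply(seq_len(n_vars), function(i) {
    v <- stats::rnorm(n_sites)
    moran_i(v, w, n_permutations = n_permutations,
            seed = child_seed(seed, i))$p_value <= alpha
  }, TRUE)
  list(rejection_rate = mean(rejected), n_vars = n_vars, alpha = alpha,
       n_permutations = n_permutations)
}

#' Null calibration of the blocked ANCOVA
#'
#' Simulates balanced factorial AUC tables whose response is independent
#' of every factor and returns the mean F statistic per treatment factor
#' across tables; calibrated F ratios average about 1 under the null.
#'
#' @param n_tables number of simulated tables
#' @param n_species,n_basins factorial dimensions per table
#' @param seed integer seed
#' @return list with per-treatment mean F (\code{mean_F}) and the grid size
#' @export
ancova_null_calibration <- function(n_tables = 200, n_species = 8,
                                    n_basins = 2, seed = 1L) {
  treatment <- c("model_type", "spatial", "rarity_type", "resolution")
  Fs <- matrix(NA_real_, n_tables, length(treatment),
               dimnames = list(NULL, treatment))
  for (i in seq_len(n_tables)) {
    set.seed(child_seed(seed, i))
    species <- sprintf("sp%02d", seq_len(n_species))
    grid <- expand.grid(species_id = species,
                        basin = paste0("b", seq_len(n_basins)),
                        model_type = c("lasso", "brt", "maxent"),
                        spatial = c("no", "yes"),
                        resolution = c("segment", "unit"),
                        stringsAsFactors = FALSE)
    rar <- sample(LETTERS[1:8], n_species, replace = TRUE)
    grid$rarity_type <- rar[match(grid$species_id, species)]
    fam <- sample.int(5, n_species, replace = TRUE)
    grid$family_number <- fam[match(grid$species_id, species)]
    grid$auc_cv <- pmax(stats::rnorm(nrow(grid), 0.7, 0.05), 1e-3)
    an <- suppressWarnings(ancova_auc(grid))
    tab <- an$table
    for (tm in treatment) {
      j <- match(tm, tab$source)
      if (!is.na(j)) Fs[i, tm] <- tab$F[j]
    }
  }
  list(mean_F = colMeans(Fs, na.rm = TRUE), n_tables = n_tables)
}
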