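#' Fit a Lasso-penalized logistic species distribution model
#'
#' Logistic regression of presence/absence on habitat predictors under the
#' L1 (Lasso) penalty: coefficients maximize
#' \eqn{\log L(\beta) - \lambda \sum_j |\beta_j|} with the intercept
#' unpenalized and predictors standardized internally (reported
#' coefficients are on the original scale). The penalty parameter
#' \eqn{\lambda} is tuned by stratified k-fold cross-validated binomial
#' deviance over a log-spaced path; either the deviance-minimizing
#' \eqn{\lambda} (default) or the one-standard-error rule can be used.
#' Fitting is delegated to glmnet's coordinate descent.
#'
#' @param X numeric predictor matrix with column names, no missing values
#' @param y 0/1 response with both classes present
#' @param lambda_path optional decreasing penalty path; a single value
#'   (including 0) skips cross-validation and fits at that penalty
#' @param cv_folds folds for penalty tuning
#' @param seed integer seed (fold assignment)
#' @param rule "min" or "1se"
#' @return object of class \code{lasso_sdm} with elements \code{beta}
#'   (named, incl. \code{(Intercept)}), \code{lambda}, \code{lambda_path},
#'   \code{cv_deviance}, and the training columns
#' @export
fit_lasso_logistic <- function(X, y, lambda_path = NULL, cv_folds = 5,
                               seed = 1L, rule = c("min", "1se")) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  check_binary_labels(y)
  if (anyNA(X)) stop_arg("X must not contain missing values")
  orig_cols <- colnames(X)
  # the coordinate-descent backend needs >= 2 columns; pad a zero column
  # (zero variance, so its coefficient is identically 0) and drop it after
  if (ncol(X) == 1) X <- cbind(X, `.pad0` = 0)

  if (!is.null(lambda_path) && length(lambda_path) == 1) {
    fit <- glmnet::glmnet(X, y, family = "binomial", lambda = lambda_path,
                          standardize = TRUE, thresh = 1e-12, maxit = 1e6)
    lambda <- lambda_path
    cvm <- NULL
  } else {
    foldid <- make_folds(y, k = cv_folds, seed = seed)
    fit <- glmnet::cv.glmnet(X, y, family = "binomial",
                             type.measure = "deviance", foldid = foldid,
                             lambda = lambda_path, standardize = TRUE)
    lambda <- if (rule == "min") fit$lambda.min else fit$lambda.1se
    cvm <- fit$cvm
    lambda_path <- fit$lambda
  }
  beta <- as.numeric(stats::coef(fit, s = lambda))
  names(beta) <- c("(Intercept)", colnames(X))
  beta <- beta[c("(Intercept)", orig_cols)]
  X <- X[, orig_cols, drop = FALSE]
  # at zero penalty, perfect classification by the fitted hyperplane means
  # the data are linearly separable and the unpenalized MLE is unbounded;
  # the backend's bounded iterations return finite coefficients regardless
  eta <- as.numeric(beta[1] + X %*% beta[-1])
  separated <- lambda == 0 && all(eta != 0) && all((eta > 0) == (y == 1))
  if (separated || max(abs(beta)) > 1e3) {
    warning("data appear separable at this penalty: ",
            "coefficients are not maximum-likelihood estimates",
            call. = FALSE)
  }
  structure(list(beta = beta, lambda = lambda, lambda_path = lambda_path,
                 cv_deviance = cvm, rule = rule, fit = fit,
                 columns = orig_cols, X = X, y = y),
            class = c("lasso_sdm", "sdm_model"))
}

#' Predicted probability of presence
#'
#' Common prediction contract for all model kinds: probability of presence
#' at each row of \code{X}, via the inverse-logit of the model's linear
#' predictor (or tree-ensemble logit for boosted trees).
#'
#' @param model a fitted SDM
#' @param X predictor matrix with the training columns
#' @return numeric vector of probabilities in (0,1)
#' @export
predict_probability <- function(model, X) UseMethod("predict_probability")

check_columns <- function(model, X) {
  X <- as.matrix(X)
  missing_cols <- setdiff(model$columns, colnames(X))
  if (length(missing_cols)) {
    stop_arg("prediction matrix missing column(s): ",
             paste(missing_cols, collapse = ", "))
  }
  X[, model$columns, drop = FALSE]
}

#' @export
predict_probability.lasso_sdm <- function(model, X) {
  X <- check_columns(model, X)
  as.numeric(inv_logit(model$beta[1] + X %*% model$beta[-1]))
}

#' Fit a boosted regression tree species distribution model
#'
#' Stagewise additive regression trees on the logit scale minimizing
#' Bernoulli deviance, with shrinkage (\code{learning_rate}), limited tree
#' depth (\code{tree_complexity}), and per-iteration bagging: rows (and
#' optionally predictors) subsampled without replacement. The optimal
#' number of trees is the held-out-deviance minimum, tracked by internal
#' k-fold cross-validation over a growth schedule evaluated in blocks of
#' \code{block} trees. Relative influence of each predictor is the
#' squared-improvement (gain) attributed to its splits across all trees of
#' the selected ensemble, normalized to sum to 100. Boosting is delegated
#' to xgboost (single-threaded, seeded, exact splits) behind this surface.
#'
#' @param X numeric predictor matrix with column names
#' @param y 0/1 response
#' @param learning_rate shrinkage per tree
#' @param tree_complexity maximum tree depth (interaction order)
#' @param bag_fraction fraction of rows subsampled per tree, in (0,1]
#' @param predictor_fraction fraction of predictors subsampled per tree
#' @param n_trees_max largest ensemble size explored
#' @param block tree-count granularity at which held-out deviance is read
#' @param cv_folds folds for the deviance tracking
#' @param seed integer seed
#' @return object of class \code{brt_sdm}: booster, \code{n_trees_opt},
#'   \code{relative_influence} (percent, sums to 100), held-out and
#'   training deviance logs, hyperparameters
#' @export
fit_brt <- function(X, y, learning_rate = 0.005, tree_complexity = 3,
                    bag_fraction = 0.5, predictor_fraction = 1,
                    n_trees_max = 2000, block = 50, cv_folds = 5,
                    seed = 1L) {
  X <- as.matrix(X)
  check_binary_labels(y)
  if (nrow(X) < 20) stop_arg("need sample size >= 20 for boosting")
  if (bag_fraction <= 0 || bag_fraction > 1) {
    stop_arg("bag_fraction must be in (0,1]")
  }
  params <- list(objective = "binary:logistic", eta = learning_rate,
                 max_depth = tree_complexity, subsample = bag_fraction,
                 colsample_bytree = predictor_fraction,
                 lambda = 0, alpha = 0, tree_method = "exact",
                 nthread = 1, seed = seed)
  dm <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)

  set.seed(seed)  # xgb.cv fold assignment uses the R RNG
  cv <- xgboost::xgb.cv(params = params, data = dm, nrounds = n_trees_max,
                        nfold = cv_folds, metrics = "logloss",
                        stratified = TRUE, verbose = 0)
  heldout <- cv$evaluation_log$test_logloss_mean
  grid <- seq(block, n_trees_max, by = block)
  n_trees_opt <- grid[which.min(heldout[grid])]

  booster <- xgboost::xgb.train(params = params, data = dm,
                                nrounds = n_trees_opt,
                                evals = list(train = dm), verbose = 0)
  # gain share aggregated from the tree dump (equivalent to the importance
  # helper, but also defined for single-feature and no-split ensembles)
  dt <- xgboost::xgb.model.dt.tree(model = booster)
  splits <- dt[dt$Feature != "Leaf", , drop = FALSE]
  influence <- stats::setNames(rep(0, ncol(X)), colnames(X))
  if (nrow(splits)) {
    gain <- tapply(splits$Gain, splits$Feature, sum)
    influence[names(gain)] <- 100 * gain / sum(gain)
  }

  structure(list(
    booster = booster, n_trees_opt = n_trees_opt,
    relative_influence = influence,
    heldout_deviance = 2 * heldout,      # logloss -> mean Bernoulli deviance
    train_deviance = 2 * attributes(booster)$evaluation_log$train_logloss,
    learning_rate = learning_rate, tree_complexity = tree_complexity,
    bag_fraction = bag_fraction, block = block, seed = seed,
    columns = colnames(X), X = X, y = y
  ), class = c("brt_sdm", "sdm_model"))
}

#' @export
predict_probability.brt_sdm <- function(model, X) {
  X <- check_columns(model, X)
  as.numeric(stats::predict(model$booster,
                            xgboost::xgb.DMatrix(X, nthread = 1)))
}

#' Ranked variable importance of a boosted regression tree model
#'
#' Per-variable summed squared split improvements across the trees of the
#' selected ensemble, normalized to percentages and sorted descending.
#' Variables never chosen for a split score 0.
#'
#' @param model a \code{brt_sdm}
#' @return data frame: variable, influence (percent)
#' @export
variable_importance <- function(model) {
  stopifnot(inherits(model, "brt_sdm"))
  inf <- sort(model$relative_influence, decreasing = TRUE)
  data.frame(variable = names(inf), influence = as.numeric(inf),
             stringsAsFactors = FALSE)
}

#' Partial dependence curve
#'
#' Mean predicted probability over the training rows as one predictor is
#' forced across a regular grid while all other predictors keep their
#' observed values. An ecological threshold is flagged when the curve has
#' an unusually sharp step: the largest absolute first difference must
#' exceed \code{threshold_multiple} times the median absolute difference;
#' the reported threshold is the midpoint of the steepest grid interval.
#'
#' @param model a fitted SDM storing its training data
#' @param variable predictor name
#' @param n_grid grid size over the observed range
#' @param threshold_multiple sharpness factor for threshold detection
#' @return object of class \code{partial_dependence}: data frame
#'   \code{curve} (grid, response), \code{variable},
#'   \code{detected_threshold} (NA when no sharp step)
#' @export
partial_dependence <- function(model, variable, n_grid = 50,
                               threshold_multiple = 3) {
  if (!(variable %in% model$columns)) {
    stop_arg("unknown variable: ", variable)
  }
  X <- model$X
  grid <- seq(min(X[, variable]), max(X[, variable]), length.out = n_grid)
  response <- vapply(grid, function(g) {
    Xg <- X
    Xg[, variable] <- g
    mean(predict_probability(model, Xg))
  }, 0)
  diffs <- abs(diff(response))
  detected <- NA_real_
  if (max(diffs) > 0 &&
      max(diffs) > threshold_multiple * stats::median(diffs)) {
    i <- which.max(diffs)
    detected <- (grid[i] + grid[i + 1]) / 2
  }
  structure(list(curve = data.frame(grid = grid, response = response),
                 variable = variable, detected_threshold = detected),
            class = "partial_dependence")
}

#' @export
print.partial_dependence <- function(x, ...) {
  cat("Partial dependence of", x$variable,
      sprintf("over [%.3g, %.3g]", min(x$curve$grid), max(x$curve$grid)))
  if (!is.na(x$detected_threshold)) {
    cat(sprintf("; threshold detected near %.3g", x$detected_threshold))
  }
  cat("\n")
  invisible(x)
}

#' Fit a presence-background surrogate model
#'
#' Penalized logistic regression of presences against a negative class, on
#' a linear + quadratic feature expansion — a transparent surrogate for
#' presence-only (maximum-entropy style) modeling whose comparison of
#' interest is the construction of the negative class: community-inferred
#' absences (\code{mode = "inferred_absence"}) versus background points
#' drawn from the landscape (\code{mode = "random_background"}). The
#' prediction contract is identical to the other model kinds.
#'
#' @param X_presence predictor rows at presence sites
#' @param X_negative predictor rows of the negative class (inferred
#'   absences or background draws)
#' @param mode how the negative class was constructed (recorded, and used
#'   for reporting only)
#' @param cv_folds folds for penalty tuning
#' @param seed integer seed
#' @return object of class \code{pb_sdm}
#' @export
fit_presence_background <- function(X_presence, X_negative,
                                    mode = c("inferred_absence",
                                             "random_background"),
                                    cv_folds = 5, seed = 1L) {
  mode <- match.arg(mode)
  X_presence <- as.matrix(X_presence)
  X_negative <- as.matrix(X_negative)
  if (nrow(X_negative) == 0) stop_arg("need at least one negative row")
  if (nrow(X_presence) == 0) stop_arg("need at least one presence row")
  X <- rbind(X_presence, X_negative)
  y <- c(rep(1L, nrow(X_presence)), rep(0L, nrow(X_negative)))

  Xe <- expand_quadratic(X)
  foldid <- make_folds(y, k = cv_folds, seed = seed)
  fit <- glmnet::cv.glmnet(Xe, y, family = "binomial",
                           type.measure = "deviance", foldid = foldid,
                           standardize = TRUE)
  beta <- as.numeric(stats::coef(fit, s = fit$lambda.min))
  names(beta) <- c("(Intercept)", colnames(Xe))
  structure(list(beta = beta, lambda = fit$lambda.min, mode = mode,
                 n_background = nrow(X_negative), fit = fit,
                 columns = colnames(X), X = X, y = y),
            class = c("pb_sdm", "sdm_model"))
}

expand_quadratic <- function(X) {
  Xsq <- X^2
  colnames(Xsq) <- paste0(colnames(X), "_sq")
  cbind(X, Xsq)
}

#' @export
predict_probability.pb_sdm <- function(model, X) {
  X <- check_columns(model, X)
  Xe <- expand_quadratic(X)
  as.numeric(inv_logit(model$beta[1] + Xe %*% model$beta[-1]))
}

#' Draw random background rows from a landscape
#'
#' Samples segments uniformly (without replacement when possible) from the
#' full landscape excluding the focal species' presence segments — the
#' default pseudo-absence construction of presence-only models.
#'
#' @param habitat segments x variables matrix with segment rownames
#' @param exclude segment ids to exclude (focal presences)
#' @param n number of background rows
#' @param seed integer seed
#' @return matrix of background predictor rows
#' @export
sample_background <- function(habitat, exclude, n, seed = 1L) {
  pool <- setdiff(rownames(habitat), exclude)
  if (length(pool) == 0) stop_arg("no background segments available")
  set.seed(seed)
  idx <- sample(pool, n, replace = n > length(pool))
  habitat[idx, , drop = FALSE]
}
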