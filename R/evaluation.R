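#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation of the AUC: the probability that a
#' randomly chosen presence outscores a randomly chosen absence, with tied
#' scores contributing 1/2. Equivalent to the area under the plot of
#' sensitivity against 1 - specificity across all thresholds.
#'
#' @param scores numeric predicted scores
#' @param labels 0/1 observed labels, both classes present
#' @return AUC in [0, 1]
#' @export
roc_auc <- function(scores, labels) {
  check_binary_labels(labels)
  if (length(scores) != length(labels)) stop_arg("length mismatch")
  r <- rank(scores)   # midranks handle ties as 1/2
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Assign k-fold cross-validation folds
#'
#' Stratified by default: presences and absences are split into folds
#' separately so per-fold prevalence tracks overall prevalence.
#'
#' @param y 0/1 labels
#' @param k fold count
#' @param seed integer seed
#' @param stratified stratify on the labels
#' @return integer fold index per row
#' @export
make_folds <- function(y, k = 5, seed = 1L, stratified = TRUE) {
  n <- length(y)
  if (k < 2 || k > n) stop_arg("k must be in [2, n]")
  set.seed(seed)
  fold <- integer(n)
  if (stratified) {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(k), n))
  }
  fold
}

#' Training and k-fold cross-validation AUC of a model recipe
#'
#' Refits the supplied model recipe on each training split — including any
#' internal hyperparameter selection it performs — and scores the held-out
#' fold, so the cross-validated AUC reflects the full fitting procedure.
#' Folds are stratified by default. The cross-validated AUC is the mean of
#' per-fold AUCs (a pooled-scores variant is available); the training AUC
#' comes from a fit on the full data.
#'
#' @param fit_fun function(X, y) returning a model that answers
#'   \code{\link{predict_probability}}
#' @param X predictor matrix
#' @param y 0/1 labels; each class needs at least \code{k} rows
#' @param k fold count
#' @param seed integer seed for fold assignment
#' @param stratified stratify folds on the labels
#' @param pooled also/instead compute AUC on the pooled held-out scores
#' @return object of class \code{auc_result}: auc_train, auc_cv,
#'   per_fold_auc, (auc_cv_pooled), k, seed
#' @export
kfold_cv <- function(fit_fun, X, y, k = 5, seed = 1L, stratified = TRUE,
                     pooled = FALSE) {
  X <- as.matrix(X)
  check_binary_labels(y)
  if (min(table(y)) < k) {
    stop_arg("cross-validation not feasible: minority class has fewer ",
             "than k = ", k, " rows")
  }
  fold <- make_folds(y, k = k, seed = seed, stratified = stratified)
  full <- fit_fun(X, y)
  auc_train <- roc_auc(predict_probability(full, X), y)

  scores <- numeric(length(y))
  per_fold <- vapply(seq_len(k), function(f) {
    test <- fold == f
    m <- fit_fun(X[!test, , drop = FALSE], y[!test])
    scores[test] <<- predict_probability(m, X[test, , drop = FALSE])
    roc_auc(scores[test], y[test])
  }, 0)

  out <- list(auc_train = auc_train, auc_cv = mean(per_fold),
              per_fold_auc = per_fold, k = k, fold_seed = seed,
              stratified = stratified)
  if (pooled) out$auc_cv_pooled <- roc_auc(scores, y)
  structure(out, class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC: train %.3f, %d-fold cv %.3f (folds: %s)\n",
              x$auc_train, x$k, x$auc_cv,
              paste(sprintf("%.3f", x$per_fold_auc), collapse = " ")))
  invisible(x)
}

#' Bernoulli deviance residuals
#'
#' Signed square root of each observation's contribution to the Bernoulli
#' deviance: \eqn{\mathrm{sign}(y - p)\sqrt{-2[y \ln p + (1-y)\ln(1-p)]}}.
#' Probabilities of exactly 0 or 1 that disagree with the observation are
#' clamped with a warning.
#'
#' @param y 0/1 observations
#' @param p predicted probabilities
#' @return numeric residuals
#' @export
deviance_residuals <- function(y, p) {
  if (length(y) != length(p)) stop_arg("length mismatch")
  bad <- (p <= 0 & y == 1) | (p >= 1 & y == 0)
  if (any(bad)) {
    warning("clamping degenerate probabilities discordant with observations",
            call. = FALSE)
  }
  # clamp inside the active log term only, so exact concordant
  # probabilities (y = 1, p = 1 and y = 0, p = 0) give residual 0
  active <- ifelse(y == 1, pmax(p, 1e-12), pmax(1 - p, 1e-12))
  sign(y - p) * sqrt(-2 * log(active))
}

#' Moran's I test on model deviance residuals
#'
#' The spatial diagnostic for a fitted presence-absence model: significant
#' Moran's I in the deviance residuals indicates spatial autocorrelation
#' the predictors have not absorbed; after refitting on spatialized
#' predictors the test should become non-significant when the spatial
#' eigenfunctions capture the structure.
#'
#' @param model a fitted SDM answering \code{\link{predict_probability}}
#' @param X predictor matrix (training rows)
#' @param y 0/1 observations aligned with \code{X}
#' @param weights spatial weight matrix aligned with the rows
#' @param ... passed to \code{\link{moran_i}} (n_permutations, seed, ...)
#' @return a \code{spatial_diagnostics} object
#' @export
residual_moran_test <- function(model, X, y, weights, ...) {
  p <- predict_probability(model, X)
  res <- deviance_residuals(y, p)
  moran_i(res, weights, ...)
}
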