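# Independent oracles and shared toy fixtures used across the test files.

# Brute-force AUC: count concordant positive-negative pairs, ties as 1/2.
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Unpenalized logistic MLE by Newton-Raphson (independent of glm/glmnet).
newton_raphson_logistic <- function(X, y, max_iter = 100, tol = 1e-10) {
  Xd <- cbind(1, X)
  beta <- rep(0, ncol(Xd))
  for (i in seq_len(max_iter)) {
    eta <- as.numeric(Xd %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- p * (1 - p)
    grad <- t(Xd) %*% (y - p)
    hess <- t(Xd) %*% (Xd * w)
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  as.numeric(beta)
}

# A small labeled logistic dataset with a known signal, for model tests.
toy_logistic_data <- function(n = 50, seed = 7, beta = c(-0.5, 1.2, -0.8)) {
  set.seed(seed)
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  eta <- beta[1] + X %*% beta[-1]
  y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  if (length(unique(y)) < 2) stop("degenerate toy draw; change seed")
  list(X = X, y = as.integer(y))
}

# Hand-designed occurrence records: 3 species over 2 segments.
#   seg_a: sp1, sp2        seg_b: sp2, sp3
toy_records <- function() {
  data.frame(
    species_id = c("sp1", "sp2", "sp2", "sp3"),
    segment_id = c("seg_a", "seg_a", "seg_b", "seg_b"),
    basin = c("b1", "b1", "b2", "b2"),
    year = c(1990L, 1991L, 1990L, 1992L),
    source = "museum",
    stringsAsFactors = FALSE
  )
}

toy_species_meta <- function() {
  data.frame(
    species_id = c("sp1", "sp2", "sp3", "game1"),
    family_number = c(1L, 1L, 2L, 3L),
    is_game = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

# Manually assembled linear-logit model honouring the common prediction
# contract, for closed-form prediction and partial-dependence checks.
manual_linear_sdm <- function(beta, columns) {
  structure(list(beta = stats::setNames(beta, c("(Intercept)", columns)),
                 columns = columns),
            class = c("lasso_sdm", "sdm_model"))
}
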