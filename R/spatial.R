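#' Moran's I with permutation test
#'
#' Computes Moran's I,
#' \deqn{I = \frac{n}{W}\,\frac{\sum_i\sum_j w_{ij} z_i z_j}{\sum_i z_i^2},}
#' with \eqn{z} the centered values and \eqn{W} the total weight, and tests
#' the null of no spatial autocorrelation (expected value
#' \eqn{E[I] = -1/(n-1)}) by permuting the values over the sites. The
#' permutation p-value is \eqn{(1 + \#\{|I^* - E[I]| \ge |I - E[I]|\}) /
#' (1 + n_{perm})} for the two-sided test, so it can never fall below
#' \eqn{1/(1+n_{perm})}. A normal-approximation alternative using the
#' Cliff-Ord randomization moments of I is available; the statistic depends
#' on the weight matrix exactly as supplied (no internal
#' row-standardization).
#'
#' @param values numeric vector, non-constant
#' @param weights square nonnegative weight matrix, zero diagonal
#' @param n_permutations number of permutations (>= 99)
#' @param seed integer seed for the permutations
#' @param alternative "two.sided" or "greater" (clustering only)
#' @param method "permutation" (default) or "normal"
#' @return list of class \code{spatial_diagnostics}: moran_i, expected_i,
#'   p_value, n_permutations
#' @export
moran_i <- function(values, weights, n_permutations = 999, seed = 1L,
                    alternative = c("two.sided", "greater"),
                    method = c("permutation", "normal")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  n <- length(values)
  if (n < 3) stop_arg("need >= 3 values")
  if (stats::sd(values) == 0) stop_arg("Moran's I undefined for constant values")
  weights <- as.matrix(weights)
  if (any(weights < 0) || any(diag(weights) != 0) || all(weights == 0)) {
    stop_arg("weights must be nonnegative with zero diagonal and not all zero")
  }
  W <- sum(weights)
  expected <- -1 / (n - 1)
  stat <- function(z) (n / W) * sum(z * (weights %*% z)) / sum(z^2)
  z0 <- values - mean(values)
  I <- stat(z0)

  if (method == "normal") {
    # Cliff-Ord moments of I under randomization (kurtosis-corrected)
    s1 <- 0.5 * sum((weights + t(weights))^2)
    s2 <- sum((rowSums(weights) + colSums(weights))^2)
    k <- (sum(z0^4) / n) / (sum(z0^2) / n)^2
    var_i <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * W^2) -
                k * (n * (n - 1) * s1 - 2 * n * s2 + 6 * W^2)) /
      ((n - 1) * (n - 2) * (n - 3) * W^2) - expected^2
    zscore <- (I - expected) / sqrt(var_i)
    p <- if (alternative == "two.sided") {
      2 * stats::pnorm(-abs(zscore))
    } else {
      stats::pnorm(zscore, lower.tail = FALSE)
    }
    n_permutations <- 0L
  } else {
    if (n_permutations < 99) stop_arg("use >= 99 permutations")
    set.seed(seed)
    # vectorized: columns of Z are permuted centered values
    Z <- vapply(seq_len(n_permutations), function(i) sample(z0), z0)
    Istar <- (n / W) * colSums(Z * (weights %*% Z)) / sum(z0^2)
    exceed <- if (alternative == "two.sided") {
      abs(Istar - expected) >= abs(I - expected) - 1e-12
    } else {
      Istar >= I - 1e-12
    }
    p <- (1 + sum(exceed)) / (1 + n_permutations)
  }
  structure(list(moran_i = I, expected_i = expected, p_value = p,
                 n_permutations = n_permutations, method = method,
                 alternative = alternative),
            class = "spatial_diagnostics")
}

#' @export
print.spatial_diagnostics <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f), p = %.4g [%s]\n",
              x$moran_i, x$expected_i, x$p_value, x$method))
  invisible(x)
}

#' PCNM spatial eigenvector basis
#'
#' Principal coordinates of neighbour matrices. Pairwise Euclidean
#' distances beyond the truncation threshold \eqn{t} are replaced by
#' \eqn{4t} (the classical large-distance surrogate); the truncated matrix
#' \eqn{D^*} is transformed as \eqn{A = -D^{*2}/2} and double-centered
#' (Gower), and its full eigendecomposition taken. Eigenvectors are unit
#' norm and mutually orthogonal. The threshold defaults to the longest edge
#' of the Euclidean minimum spanning tree over the sites, which keeps the
#' neighbour graph connected. For each eigenvector with a non-degenerate
#' eigenvalue, Moran's I is computed against the binary within-threshold
#' neighbour weights (\eqn{w_{ij} = 1} iff \eqn{d_{ij} \le t}).
#'
#' @param coords n x 2 matrix of planar site coordinates
#' @param truncation_t truncation distance; default longest MST edge
#' @param n_permutations permutations for the per-vector Moran tests
#' @param seed integer seed
#' @param alternative per-vector Moran test sidedness; positive spatial
#'   autocorrelation ("greater") is the screening default
#' @return object of class \code{spatial_eigenbasis}: eigenvalues
#'   (descending), unit-norm eigenvectors, per-vector moran_i and moran_p,
#'   \code{selected} flags (all NA until \code{\link{select_vectors}}),
#'   truncation_t, and the neighbour weight matrix
#' @export
pcnm <- function(coords, truncation_t = NULL, n_permutations = 999,
                 seed = 1L, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 3) stop_arg("need >= 3 sites")
  if (any(!is.finite(coords))) stop_arg("coordinates must be finite")
  d <- as.matrix(stats::dist(coords))
  if (max(d) == 0) stop_arg("degenerate geometry: all sites coincident")
  if (is.null(truncation_t)) truncation_t <- mst_longest_edge(d)

  dtrunc <- d
  dtrunc[dtrunc > truncation_t] <- 4 * truncation_t
  A <- -0.5 * dtrunc^2
  rmeans <- rowMeans(A)
  G <- A - outer(rmeans, rmeans, "+") + mean(A)   # double centering
  eig <- eigen(G, symmetric = TRUE)

  tol <- 1e-10 * max(abs(eig$values))
  nondeg <- abs(eig$values) > tol
  weights <- (d <= truncation_t) * 1
  diag(weights) <- 0

  m_i <- rep(NA_real_, n)
  m_p <- rep(NA_real_, n)
  for (j in which(nondeg)) {
    mt <- moran_i(eig$vectors[, j], weights, n_permutations = n_permutations,
                  seed = child_seed(seed, j), alternative = alternative)
    m_i[j] <- mt$moran_i
    m_p[j] <- mt$p_value
  }

  structure(list(
    truncation_t = truncation_t,
    eigenvalues = eig$values,
    vectors = eig$vectors,
    moran_i = m_i, moran_p = m_p,
    selected = rep(NA, n),
    nondegenerate = nondeg,
    weights = weights,
    n_permutations = n_permutations, seed = seed
  ), class = "spatial_eigenbasis")
}

# longest edge of the Euclidean minimum spanning tree (Prim's algorithm)
mst_longest_edge <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- d[1, ]
  longest <- 0
  for (i in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    longest <- max(longest, best[j])
    in_tree[j] <- TRUE
    best <- pmin(best, d[j, ])
  }
  longest
}

#' @export
print.spatial_eigenbasis <- function(x, ...) {
  cat("PCNM eigenbasis:", sum(x$nondegenerate), "non-degenerate vectors of",
      length(x$eigenvalues), sprintf("(truncation t = %.3f)", x$truncation_t))
  if (!all(is.na(x$selected))) cat(";", sum(x$selected, na.rm = TRUE), "selected")
  cat("\n")
  invisible(x)
}

#' Select spatial eigenvectors
#'
#' Flags the eigenvectors to keep for the spatial predictor matrix:
#' positive eigenvalue, significant Moran's I at \code{alpha}, and (by
#' default) positive spatial autocorrelation, i.e. observed I above its
#' null expectation \eqn{-1/(n-1)}.
#'
#' @param basis a \code{spatial_eigenbasis}
#' @param alpha significance level for the Moran tests
#' @param positive_only keep only positive-autocorrelation vectors
#' @return the basis with \code{selected} flags set
#' @export
select_vectors <- function(basis, alpha = 0.05, positive_only = TRUE) {
  stopifnot(inherits(basis, "spatial_eigenbasis"))
  tol <- 1e-10 * max(abs(basis$eigenvalues))
  n <- length(basis$eigenvalues)
  sel <- basis$eigenvalues > tol &
    !is.na(basis$moran_p) & basis$moran_p <= alpha
  if (positive_only) {
    sel <- sel & !is.na(basis$moran_i) & basis$moran_i > -1 / (n - 1)
  }
  basis$selected <- sel
  basis$alpha <- alpha
  basis
}

#' Spatialize environmental predictors
#'
#' Replaces each environmental variable by its least-squares fitted values
#' from a regression on the selected spatial eigenvectors (plus intercept).
#' The result is the spatially structured component of each predictor; the
#' residual (spatially independent) component is discarded, so downstream
#' models see only variation the spatial eigenfunctions can express.
#' The operation is an orthogonal projection: idempotent, and it can only
#' shrink each variable's variance.
#'
#' @param habitat numeric matrix, sites x variables, rows aligned with the
#'   basis sites
#' @param basis a \code{spatial_eigenbasis} with selection flags set
#' @return matrix of fitted ("spatialized") habitat values, same dimensions
#' @export
spatialize <- function(habitat, basis) {
  stopifnot(inherits(basis, "spatial_eigenbasis"))
  if (all(is.na(basis$selected))) {
    stop_arg("run select_vectors() on the basis first")
  }
  sel <- which(basis$selected)
  if (length(sel) == 0) {
    stop_arg("no spatial eigenvectors selected; fit the non-spatial model instead")
  }
  habitat <- as.matrix(habitat)
  if (nrow(habitat) != nrow(basis$vectors)) {
    stop_arg("habitat rows must align with the basis sites")
  }
  X <- cbind(1, basis$vectors[, sel, drop = FALSE])
  fit <- stats::lm.fit(X, habitat)
  fitted <- habitat - fit$residuals
  dimnames(fitted) <- dimnames(habitat)
  fitted
}
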