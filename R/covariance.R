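#' Ledoit-Wolf shrinkage covariance estimator
#'
#' Shrinks the sample covariance toward a scaled identity with the
#' analytically optimal intensity of Ledoit & Wolf (2004). With columns
#' centered and `S = X'X / T`, the target is `mu I` with `mu = tr(S)/p`, and
#' the intensity is `min(beta_bar / delta2, 1)` where
#' `beta_bar = sum_t ||x_t x_t' - S||_F^2 / T^2` and
#' `delta2 = ||S - mu I||_F^2`. The result is symmetric positive definite
#' even when `T < p`.
#'
#' @param series Numeric `T x p` matrix of observations (rows = time points).
#' @return `p x p` shrunk covariance with attributes `shrinkage` (intensity)
#'   and `mu` (target scale).
#' @export
shrinkage_covariance <- function(series) {
  series <- as.matrix(series)
  abort_if(!all(is.finite(series)), "series must be finite")
  T_ <- nrow(series); p <- ncol(series)
  abort_if(T_ < 2, "need at least 2 time points")
  X <- sweep(series, 2, colMeans(series))
  abort_if(all(apply(X, 2, function(v) all(v == 0))),
           "constant series: covariance undefined")
  S <- crossprod(X) / T_
  mu <- sum(diag(S)) / p
  delta2 <- sum((S - diag(mu, p))^2)
  ## beta_bar = (1/T^2) * sum_t ||x_t x_t' - S||_F^2
  ##          = (1/T) * mean_t ||x_t x_t'||_F^2 - ||S||_F^2 / T
  x2 <- rowSums(X^2)
  beta_bar <- (sum(x2^2) - T_ * sum(S^2)) / T_^2
  shrinkage <- if (delta2 > 0) min(max(beta_bar / delta2, 0), 1) else 0
  out <- (1 - shrinkage) * S + diag(shrinkage * mu, p)
  dimnames(out) <- list(colnames(series), colnames(series))
  structure(out, shrinkage = shrinkage, mu = mu)
}

## symmetric matrix function via eigendecomposition
sym_fun <- function(M, f) {
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  eg$vectors %*% (f(eg$values) * t(eg$vectors))
}

sym_logm <- function(M) {
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  abort_if(min(eg$values) <= 0, "matrix log requires a positive definite matrix")
  eg$vectors %*% (log(eg$values) * t(eg$vectors))
}

sym_sqrtm_pair <- function(M) {
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  abort_if(min(eg$values) <= 0, "matrix square root requires positive definite input")
  list(half = eg$vectors %*% (sqrt(eg$values) * t(eg$vectors)),
       invhalf = eg$vectors %*% ((1 / sqrt(eg$values)) * t(eg$vectors)))
}

check_spd <- function(M, what = "matrix") {
  abort_if(!isSymmetric(unclass(M), tol = 1e-8), "%s must be symmetric", what)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  abort_if(min(ev) <= 0, "%s must be positive definite", what)
  invisible(TRUE)
}

#' Affine-invariant geometric mean of SPD matrices
#'
#' Fixed-point iteration `R <- R^{1/2} exp(mean_i log(R^{-1/2} C_i R^{-1/2})) R^{1/2}`
#' starting from the arithmetic mean, stopped when the Frobenius norm of the
#' mean log term falls below `tol`.
#'
#' @param covs List of SPD matrices of common dimension.
#' @param tol Convergence tolerance on the Frobenius norm of the step.
#' @param max_iter Maximum number of iterations.
#' @return SPD matrix with attributes `iterations` and `residual`.
#' @export
geometric_mean_spd <- function(covs, tol = 1e-6, max_iter = 200) {
  stopifnot(is.list(covs), length(covs) >= 1)
  p <- nrow(covs[[1]])
  abort_if(!all(vapply(covs, function(m) nrow(m) == p && ncol(m) == p, TRUE)),
           "covariance dimension mismatch")
  R <- Reduce(`+`, covs) / length(covs)
  res <- Inf
  for (it in seq_len(max_iter)) {
    rs <- sym_sqrtm_pair(R)
    logs <- lapply(covs, function(C) sym_logm(rs$invhalf %*% C %*% rs$invhalf))
    step <- Reduce(`+`, logs) / length(logs)
    res <- sqrt(sum(step^2))
    if (res < tol) {
      return(structure(R, iterations = it - 1L, residual = res))
    }
    R <- rs$half %*% sym_fun(step, exp) %*% rs$half
    R <- (R + t(R)) / 2
  }
  stop(sprintf("geometric mean did not converge in %d iterations (residual %.2e)",
               max_iter, res), call. = FALSE)
}

#' Tangent-space embedding of covariance matrices
#'
#' Maps SPD covariance matrices into a Euclidean space by whitening with the
#' affine-invariant geometric mean `R` of the *training* covariances and
#' taking the matrix logarithm: `logm(R^{-1/2} C R^{-1/2})`. The strictly
#' lower-triangular part is vectorized into `p(p-1)/2` connectivity features.
#' The reference is computed from training subjects only, so applying the
#' embedding to held-out covariances leaks no information.
#'
#' @param train_covs List of SPD matrices used to fit the reference.
#' @param test_covs Optional list of SPD matrices to embed with the fitted
#'   reference (e.g. held-out subjects).
#' @param tol,max_iter Passed to [geometric_mean_spd()].
#' @return List with `reference` (SPD matrix), `train_vectors` and
#'   `test_vectors` (matrices, one row per subject, `p(p-1)/2` columns),
#'   `iterations`, and `residual`.
#' @export
tangent_embed <- function(train_covs, test_covs = NULL, tol = 1e-6, max_iter = 200) {
  lapply(train_covs, check_spd, what = "training covariance")
  if (!is.null(test_covs)) lapply(test_covs, check_spd, what = "test covariance")
  R <- geometric_mean_spd(train_covs, tol = tol, max_iter = max_iter)
  rs <- sym_sqrtm_pair(R)
  embed1 <- function(C) {
    vectorize_offdiag(sym_logm(rs$invhalf %*% C %*% rs$invhalf),
                      check_symmetry = FALSE)
  }
  tr <- do.call(rbind, lapply(train_covs, embed1))
  te <- if (is.null(test_covs)) NULL else do.call(rbind, lapply(test_covs, embed1))
  rownames(tr) <- names(train_covs)
  if (!is.null(te)) rownames(te) <- names(test_covs)
  list(reference = R, train_vectors = tr, test_vectors = te,
       iterations = attr(R, "iterations"), residual = attr(R, "residual"))
}

#' Vectorize the strictly lower triangle of a symmetric matrix
#'
#' Entries are taken in row-major order over the strictly lower triangle:
#' (2,1), (3,1), (3,2), (4,1), ... — length `p(p-1)/2`. The diagonal is
#' discarded.
#'
#' @param matrix Symmetric `p x p` matrix.
#' @param tol Symmetry tolerance.
#' @param check_symmetry Set to `FALSE` to skip the symmetry check.
#' @return Numeric vector of length `p(p-1)/2` named `v<i>_<j>`.
#' @export
vectorize_offdiag <- function(matrix, tol = 1e-8, check_symmetry = TRUE) {
  p <- nrow(matrix)
  if (check_symmetry) {
    abort_if(max(abs(matrix - t(matrix))) > tol, "matrix is asymmetric beyond tolerance")
  }
  if (p < 2) return(numeric(0))
  i <- rep(2:p, times = seq_len(p - 1))
  j <- unlist(lapply(2:p, function(r) seq_len(r - 1)), use.names = FALSE)
  stats::setNames(matrix[cbind(i, j)], sprintf("v%d_%d", i, j))
}
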