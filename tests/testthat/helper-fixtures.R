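# shared fixtures, built in code and memoized per test session

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small non-default layout: fast to generate, keeps every block non-trivial
tiny_layout <- c(MS = 5, AS = 2, LS = 6, EDU = 2, EL = 3, sMRI = 8, dMRI = 10)

tiny_config <- function(n = 300, seed = 7, missing_rate = 0,
                        series_length = 60, ...) {
  generative_config(n, seed = seed, block_sizes = tiny_layout,
                    n_components = 6, series_length = series_length,
                    missing_rate = missing_rate, ...)
}

tiny_cohort <- function() {
  memo("tiny_cohort", generate_cohort(tiny_config()))
}

# random SPD matrix of dimension p
random_spd <- function(p, scale = 1) {
  A <- matrix(rnorm(p * p), p, p)
  crossprod(A) / p + diag(scale, p)
}

# independently coded Ledoit-Wolf shrinkage (explicit loops over time points)
lw_oracle <- function(X) {
  T_ <- nrow(X); p <- ncol(X)
  X <- sweep(X, 2, colMeans(X))
  S <- matrix(0, p, p)
  for (t in seq_len(T_)) S <- S + tcrossprod(X[t, ])
  S <- S / T_
  mu <- mean(diag(S))
  delta2 <- sum((S - diag(mu, p))^2)
  beta_bar <- 0
  for (t in seq_len(T_)) beta_bar <- beta_bar + sum((tcrossprod(X[t, ]) - S)^2)
  beta_bar <- beta_bar / T_^2
  rho <- min(beta_bar / delta2, 1)
  (1 - rho) * S + diag(rho * mu, p)
}

# closed-form OLS via normal equations
ols_oracle <- function(X, y) solve(crossprod(X), crossprod(X, y))

# exact paired-swap p-value by enumerating all 2^n swap patterns
exact_swap_p <- function(y, a, b, statistic = "R2") {
  n <- length(y)
  obs <- evaluate(y, a, statistic) - evaluate(y, b, statistic)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  stats <- apply(patterns, 1, function(sw) {
    a2 <- ifelse(sw, b, a); b2 <- ifelse(sw, a, b)
    evaluate(y, a2, statistic) - evaluate(y, b2, statistic)
  })
  mean(abs(stats) >= abs(obs))
}

# minimal hand-built prediction_set for cv_bag unit tests
fake_prediction_set <- function(val_pred, gen_pred, validation_ids) {
  structure(list(validation_predictions = val_pred,
                 generalization_predictions = gen_pred,
                 validation_ids = validation_ids),
            class = "prediction_set")
}
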