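new_comparison_result <- function(statistic, observed, p_value = NA_real_,
                                  ci = c(NA_real_, NA_real_), n_resamples = NA_integer_,
                                  n_subjects = NA_integer_, extra = list()) {
  structure(c(list(statistic = statistic, observed = observed,
                   p_value = p_value, ci_lower = ci[1], ci_upper = ci[2],
                   n_resamples = n_resamples, n_subjects = n_subjects), extra),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s = %.4f", x$statistic, x$observed))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.4g", x$p_value))
  if (!is.na(x$ci_lower)) cat(sprintf(", 95%% CI [%.4f, %.4f]", x$ci_lower, x$ci_upper))
  cat(sprintf(" (n = %d)\n", x$n_subjects))
  invisible(x)
}

#' Permutation test against the chance baseline
#'
#' Could the observed out-of-sample performance be explained by chance? The
#' targets are permuted `n_perm` times and the statistic recomputed under
#' each permutation. The p-value uses add-one smoothing,
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`, so the attainable
#' minimum is `1/(n_perm + 1)`.
#'
#' @param y_true Observed targets (labels low/high for AUC).
#' @param y_pred CV-bagged predictions (scores for AUC).
#' @param statistic `"R2"` or `"AUC"`.
#' @param n_perm Number of permutations (study default 10000).
#' @param seed Integer seed.
#' @return A `comparison_result` with the permutation p-value and the stored
#'   null distribution in `$null`.
#' @export
permutation_test_baseline <- function(y_true, y_pred, statistic = c("R2", "AUC"),
                                      n_perm = 10000, seed = 1) {
  statistic <- match.arg(statistic)
  abort_if(n_perm < 1, "n_perm must be >= 1")
  observed <- evaluate(y_true, y_pred, statistic)
  set.seed(as.integer(seed))
  n <- length(y_true)
  null <- vapply(seq_len(n_perm), function(b) {
    evaluate(y_true[sample.int(n)], y_pred, statistic)
  }, numeric(1))
  p <- (1 + sum(null >= observed)) / (n_perm + 1)
  new_comparison_result(statistic, observed, p_value = p,
                        n_resamples = as.integer(n_perm), n_subjects = n,
                        extra = list(null = null))
}

#' Non-parametric bootstrap confidence interval for a performance statistic
#'
#' Resamples `(y_true, y_pred)` pairs jointly with replacement and reports
#' the 2.5 and 97.5 percentiles of the recomputed statistic. Degenerate
#' resamples (a single class for AUC) are redrawn and counted.
#'
#' @inheritParams permutation_test_baseline
#' @param n_boot Number of bootstrap resamples (study default 10000).
#' @return A `comparison_result` with the interval, the stored bootstrap
#'   vector in `$boot`, and `$n_redrawn`.
#' @export
bootstrap_ci <- function(y_true, y_pred, statistic = c("R2", "AUC"),
                         n_boot = 10000, seed = 1) {
  statistic <- match.arg(statistic)
  n <- length(y_true)
  abort_if(n < 2, "need at least 2 subjects")
  observed <- evaluate(y_true, y_pred, statistic)
  set.seed(as.integer(seed))
  boot <- numeric(n_boot)
  redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, replace = TRUE)
      val <- tryCatch(evaluate(y_true[idx], y_pred[idx], statistic),
                      error = function(e) NA_real_)
      if (!is.na(val)) break
      redrawn <- redrawn + 1L
      abort_if(redrawn > 100L * n_boot, "too many degenerate bootstrap resamples")
    }
    boot[b] <- val
  }
  ci <- unname(stats::quantile(boot, c(0.025, 0.975)))
  new_comparison_result(statistic, observed, ci = ci,
                        n_resamples = as.integer(n_boot), n_subjects = n,
                        extra = list(boot = boot, n_redrawn = redrawn))
}

#' Paired swap test comparing two models on the same held-out subjects
#'
#' The observed statistic is `stat(A) - stat(B)`. Subjects for which only one
#' model has a prediction are omitted. The null distribution is built by
#' independently swapping each subject's (A, B) prediction pair with
#' probability 1/2 and recomputing the difference; the p-value is two-sided
#' via absolute values with add-one smoothing. The paired bootstrap interval
#' resamples both models with identical indices.
#'
#' @param y_true Observed targets.
#' @param pred_A,pred_B Bagged predictions from the two models (`NA` where a
#'   model has no prediction for a subject).
#' @param statistic `"R2"` or `"AUC"`.
#' @param n_perm Number of swap patterns (study default 10000).
#' @param n_boot Number of paired bootstrap resamples.
#' @param seed Integer seed.
#' @return A `comparison_result` for the difference, with `$null` and `$boot`.
#' @export
paired_swap_test <- function(y_true, pred_A, pred_B, statistic = c("R2", "AUC"),
                             n_perm = 10000, n_boot = n_perm, seed = 1) {
  statistic <- match.arg(statistic)
  keep <- !is.na(pred_A) & !is.na(pred_B)
  abort_if(!any(keep), "no subjects with predictions from both models")
  y <- y_true[keep]; a <- pred_A[keep]; b <- pred_B[keep]
  n <- length(y)
  observed <- evaluate(y, a, statistic) - evaluate(y, b, statistic)
  set.seed(as.integer(seed))
  null <- vapply(seq_len(n_perm), function(i) {
    sw <- stats::runif(n) < 0.5
    a2 <- ifelse(sw, b, a)
    b2 <- ifelse(sw, a, b)
    evaluate(y, a2, statistic) - evaluate(y, b2, statistic)
  }, numeric(1))
  p <- (1 + sum(abs(null) >= abs(observed))) / (n_perm + 1)
  boot <- NULL
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boot <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, replace = TRUE)
      tryCatch(evaluate(y[idx], a[idx], statistic) -
                 evaluate(y[idx], b[idx], statistic),
               error = function(e) NA_real_)
    }, numeric(1))
    ci <- unname(stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  }
  new_comparison_result(paste0("delta_", statistic), observed, p_value = p,
                        ci = ci, n_resamples = as.integer(n_perm),
                        n_subjects = n, extra = list(null = null, boot = boot))
}

habit_forms <- c("Eq4", "Eq5", "Eq6", "Eq7", "marginal")

form_predictors <- function(form, marginal_proxy = NULL) {
  switch(form,
    Eq4 = c(deconfounder_age = "dec_age", brain_age_delta = "brain_age_delta",
            pred_fluid_intelligence = "predicted_fluid_intelligence",
            pred_neuroticism = "predicted_neuroticism"),
    Eq5 = c(deconfounder_age = "dec_age", brain_age = "predicted_age",
            pred_fluid_intelligence = "predicted_fluid_intelligence",
            pred_neuroticism = "predicted_neuroticism"),
    Eq6 = c(deconfounder_age = "dec_age", brain_age = "predicted_age",
            deconfounder_fi = "dec_fluid_intelligence",
            pred_fluid_intelligence = "predicted_fluid_intelligence",
            deconfounder_n = "dec_neuroticism",
            pred_neuroticism = "predicted_neuroticism"),
    Eq7 = c(age = "age", brain_age = "predicted_age",
            fluid_intelligence = "fluid_intelligence",
            pred_fluid_intelligence = "predicted_fluid_intelligence",
            neuroticism = "neuroticism",
            pred_neuroticism = "predicted_neuroticism"),
    marginal = {
      abort_if(is.null(marginal_proxy), "marginal form needs marginal_proxy")
      stats::setNames(marginal_proxy, marginal_proxy)
    },
    stop(sprintf("unknown model form '%s'", form), call. = FALSE))
}

#' Standardized multiple regression of a habit on proxies
#'
#' Builds the design for the chosen model form, drops rows with any missing
#' input (complete-case deletion), z-scores outcome and all predictors on
#' exactly those rows (n-1 denominator), and fits ordinary least squares
#' with an intercept. Forms: `Eq4` (deconfounder, brain age delta, predicted
#' fluid intelligence, predicted neuroticism), `Eq5` (brain-predicted age in
#' place of the delta), `Eq6` (proxy-specific deconfounders for all three
#' targets), `Eq7` (proxies and observed targets jointly), `marginal` (one
#' proxy at a time).
#'
#' @param habit Numeric vector of the habit, aligned to `proxy_table` rows.
#' @param proxy_table Data frame from [build_proxy_table()] (generalization
#'   rows only).
#' @param deconfounders Named list of deconfounder value vectors for this
#'   habit (elements `age`, and for Eq6 also `fluid_intelligence`,
#'   `neuroticism`), aligned to `proxy_table` rows.
#' @param form One of `"Eq4"`, `"Eq5"`, `"Eq6"`, `"Eq7"`, `"marginal"`.
#' @param habit_name Label stored with the fit.
#' @param marginal_proxy For `form = "marginal"`: the proxy column to use.
#' @return An object of class `habit_regression_fit` with standardized
#'   coefficients (`beta1`, `beta2`, ... in form order), residual standard
#'   deviation `sigma`, and stored design metadata for the parametric
#'   bootstrap.
#' @export
habit_regression <- function(habit, proxy_table, deconfounders = list(),
                             form = habit_forms, habit_name = "habit",
                             marginal_proxy = NULL) {
  form <- match.arg(form)
  preds <- form_predictors(form, marginal_proxy)
  df <- proxy_table
  for (t in names(deconfounders)) df[[paste0("dec_", t)]] <- deconfounders[[t]]
  abort_if(!all(preds %in% names(df)),
           "missing predictor column(s): %s",
           paste(setdiff(preds, names(df)), collapse = ", "))
  X_raw <- as.matrix(df[, preds, drop = FALSE])
  keep <- stats::complete.cases(X_raw) & !is.na(habit)
  X_raw <- X_raw[keep, , drop = FALSE]
  y_raw <- habit[keep]
  n <- nrow(X_raw); k <- ncol(X_raw) + 1L
  abort_if(n < k, "fewer rows (%d) than coefficients (%d)", n, k)
  sds <- apply(X_raw, 2, stats::sd)
  abort_if(any(sds == 0) || stats::sd(y_raw) == 0,
           "zero-variance predictor or outcome after complete-case deletion")
  X <- cbind(intercept = 1, scale(X_raw))
  y <- as.numeric(scale(y_raw))
  fit <- stats::lm.fit(X, y)
  beta <- stats::setNames(fit$coefficients,
                          c("intercept", paste0("beta", seq_along(preds))))
  sigma <- sqrt(sum(fit$residuals^2) / (n - k))
  structure(list(habit = habit_name, form = form,
                 coefficients = beta,
                 predictor_labels = stats::setNames(names(preds), names(beta)[-1]),
                 sigma = sigma, n = n, df_residual = n - k,
                 X = X, y = y),
            class = "habit_regression_fit")
}

#' @export
print.habit_regression_fit <- function(x, ...) {
  cat(sprintf("<habit_regression_fit> %s ~ %s (n = %d, sigma = %.3f)\n",
              x$habit, x$form, x$n, x$sigma))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Parametric bootstrap of regression coefficients
#'
#' The Gelman-Hill "sim" procedure: per draw, the residual scale is drawn
#' from its scaled inverse-chi-square sampling distribution,
#' `sigma_draw = sigma_hat * sqrt(df / chisq(df))`, then the coefficient
#' vector from a multivariate normal centered at the OLS estimates with
#' covariance `sigma_draw^2 (X'X)^{-1}`. The draws can be read as posterior
#' samples under a uniform prior.
#'
#' @param fit A `habit_regression_fit`.
#' @param n_draws Number of draws (study default 10000).
#' @param seed Integer seed.
#' @return An object of class `habit_regression_draws`: `draws` is an
#'   `n_draws x k` matrix (intercept included).
#' @export
parametric_bootstrap <- function(fit, n_draws = 10000, seed = 1) {
  stopifnot(inherits(fit, "habit_regression_fit"))
  XtX <- crossprod(fit$X)
  R <- tryCatch(chol(solve(XtX)),
                error = function(e) stop("non-invertible design cross-product",
                                         call. = FALSE))
  k <- ncol(fit$X)
  set.seed(as.integer(seed))
  sigma_draw <- fit$sigma * sqrt(fit$df_residual /
                                   stats::rchisq(n_draws, fit$df_residual))
  Z <- matrix(stats::rnorm(n_draws * k), n_draws, k)
  draws <- sweep(Z %*% R, 1, sigma_draw, `*`)
  draws <- sweep(draws, 2, fit$coefficients, `+`)
  colnames(draws) <- names(fit$coefficients)
  structure(list(habit = fit$habit, form = fit$form, draws = draws,
                 sigma_draws = sigma_draw, estimates = fit$coefficients,
                 seed = as.integer(seed)),
            class = "habit_regression_draws")
}

#' Summarize parametric-bootstrap draws
#'
#' @param object A `habit_regression_draws`.
#' @param ... Unused.
#' @return Data frame with one row per coefficient: estimate, draw mean and
#'   SD, and percentile 2.5/97.5 interval.
#' @export
summary.habit_regression_draws <- function(object, ...) {
  q <- apply(object$draws, 2, stats::quantile, probs = c(0.025, 0.975))
  data.frame(habit = object$habit, form = object$form,
             coefficient = colnames(object$draws),
             estimate = unname(object$estimates),
             mean = unname(colMeans(object$draws)),
             sd = unname(apply(object$draws, 2, stats::sd)),
             ci_lower = unname(q[1, ]), ci_upper = unname(q[2, ]),
             row.names = NULL)
}

#' Tidy long-format coefficient draws
#'
#' @param draws A `habit_regression_draws`.
#' @return Data frame with columns `habit`, `form`, `coefficient`, `draw`,
#'   `value`, suitable for plotting uncertainty distributions.
#' @export
tidy_draws <- function(draws) {
  stopifnot(inherits(draws, "habit_regression_draws"))
  d <- draws$draws
  data.frame(habit = draws$habit, form = draws$form,
             coefficient = rep(colnames(d), each = nrow(d)),
             draw = rep(seq_len(nrow(d)), times = ncol(d)),
             value = as.vector(d), row.names = NULL)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)`, where `R2_j` comes from regressing predictor j
#' on all other predictors (intercept included). Values above 5 or 10 are
#' conventional multicollinearity thresholds; perfect collinearity is
#' reported as `Inf`.
#'
#' @param design Numeric matrix of predictors (no intercept column).
#' @return Named numeric vector of per-predictor factors.
#' @export
vif <- function(design) {
  design <- as.matrix(design)
  p <- ncol(design)
  abort_if(p < 2, "need at least 2 predictors")
  out <- numeric(p)
  for (j in seq_len(p)) {
    yj <- design[, j]
    Xj <- cbind(1, design[, -j, drop = FALSE])
    fit <- stats::lm.fit(Xj, yj)
    sst <- sum((yj - mean(yj))^2)
    abort_if(sst == 0, "constant predictor column %d", j)
    r2 <- 1 - sum(fit$residuals^2) / sst
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  names(out) <- colnames(design)
  out
}
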