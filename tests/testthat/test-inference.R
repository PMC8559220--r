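test_that("permutation p attains its smoothed minimum for a perfect model", {
  set.seed(61)
  y <- rnorm(200)
  res <- permutation_test_baseline(y, y, "R2", n_perm = 999, seed = 1)
  expect_equal(res$observed, 1)
  expect_equal(res$p_value, 1 / 1000)
  expect_length(res$null, 999)
})

test_that("a constant prediction is never beaten under permutation", {
  set.seed(62)
  y <- rnorm(100)
  res <- permutation_test_baseline(y, rep(2, 100), "R2", n_perm = 200, seed = 1)
  expect_gt(res$p_value, 0.9)
})

test_that("bootstrap interval is degenerate for an invariant statistic", {
  set.seed(63)
  y <- rnorm(50)
  res <- bootstrap_ci(y, y, "R2", n_boot = 200, seed = 2)
  expect_equal(res$ci_lower, 1)
  expect_equal(res$ci_upper, 1)
  # endpoints are the percentiles of the stored bootstrap vector
  y2 <- rnorm(50); p2 <- y2 + rnorm(50)
  res2 <- bootstrap_ci(y2, p2, "R2", n_boot = 500, seed = 3)
  expect_equal(c(res2$ci_lower, res2$ci_upper),
               unname(quantile(res2$boot, c(0.025, 0.975))))
  # degenerate AUC resamples are redrawn, not returned
  lab <- c("high", rep("low", 9))
  res3 <- bootstrap_ci(lab, rnorm(10), "AUC", n_boot = 100, seed = 4)
  expect_true(all(is.finite(res3$boot)))
  expect_gt(res3$n_redrawn, 0)
})

test_that("swap test is symmetric and null for identical models", {
  set.seed(64)
  y <- rnorm(60); a <- y + rnorm(60)
  res <- paired_swap_test(y, a, a, "R2", n_perm = 100, n_boot = 0, seed = 1)
  expect_equal(res$observed, 0)
  expect_equal(res$p_value, 1)
  b <- y + rnorm(60, sd = 2)
  r_ab <- paired_swap_test(y, a, b, "R2", n_perm = 500, n_boot = 0, seed = 5)
  r_ba <- paired_swap_test(y, b, a, "R2", n_perm = 500, n_boot = 0, seed = 5)
  expect_equal(r_ab$observed, -r_ba$observed)
  expect_equal(r_ab$p_value, r_ba$p_value)
  # subjects with only one model's prediction are omitted
  a_na <- a; a_na[1:5] <- NA
  r_na <- paired_swap_test(y, a_na, b, "R2", n_perm = 50, n_boot = 0, seed = 1)
  expect_identical(r_na$n_subjects, 55L)
  expect_error(paired_swap_test(y, rep(NA_real_, 60), b, "R2"), "no subjects")
})

test_that("paired bootstrap uses one shared index stream for both models", {
  set.seed(65)
  y <- rnorm(40); a <- y + rnorm(40); b <- a  # identical models
  res <- paired_swap_test(y, a, b, "R2", n_perm = 10, n_boot = 200, seed = 7)
  # same indices on both sides: every bootstrap difference is exactly zero
  expect_true(all(res$boot == 0))
})

test_that("habit regression recovers an exact linear dependence on the delta", {
  set.seed(66)
  n <- 200
  pt <- data.frame(subject_id = as.character(1:n),
                   age = runif(n, 40, 70),
                   fluid_intelligence = sample(0:13, n, TRUE),
                   neuroticism = sample(0:12, n, TRUE),
                   predicted_age = runif(n, 40, 70),
                   predicted_fluid_intelligence = rnorm(n, 6),
                   predicted_neuroticism = rnorm(n, 6))
  pt$brain_age_delta <- pt$predicted_age - pt$age
  dec <- list(age = rnorm(n))
  habit <- 0.5 * pt$brain_age_delta
  fit <- habit_regression(habit, pt, dec, form = "Eq4", habit_name = "toy")
  co <- fit$coefficients
  expect_equal(unname(co["beta2"]), 1, tolerance = 1e-8)
  expect_equal(unname(co[c("intercept", "beta1", "beta3", "beta4")]),
               rep(0, 4), tolerance = 1e-8)
  expect_equal(fit$sigma, 0, tolerance = 1e-7)
})

test_that("habit regression equals a closed-form OLS oracle on a hand toy", {
  pt <- data.frame(subject_id = as.character(1:6),
                   age = c(44, 51, 56, 60, 63, 69),
                   fluid_intelligence = c(3, 5, 7, 9, 10, 12),
                   neuroticism = c(1, 4, 6, 7, 9, 11),
                   predicted_age = c(47, 50, 58, 59, 66, 66),
                   predicted_fluid_intelligence = c(4, 6, 6, 8, 11, 11),
                   predicted_neuroticism = c(2, 3, 7, 8, 8, 10))
  pt$brain_age_delta <- pt$predicted_age - pt$age
  habit <- c(2.0, 3.5, 2.8, 4.9, 5.1, 6.0)
  dec <- list(age = c(1.1, 0.8, 2.0, 1.5, 0.4, 1.7))
  fit <- habit_regression(habit, pt, dec, form = "Eq4", habit_name = "toy")
  X <- cbind(1, scale(cbind(dec$age, as.matrix(
    pt[, c("brain_age_delta", "predicted_fluid_intelligence",
           "predicted_neuroticism")]))))
  beta <- ols_oracle(X, as.numeric(scale(habit)))
  expect_equal(unname(fit$coefficients), as.numeric(beta), tolerance = 1e-8)
})

test_that("complete-case deletion and scaling happen on the analysis rows", {
  set.seed(67)
  n <- 100
  pt <- data.frame(subject_id = as.character(1:n),
                   age = runif(n, 40, 70),
                   fluid_intelligence = sample(0:13, n, TRUE),
                   neuroticism = sample(0:12, n, TRUE),
                   predicted_age = runif(n, 40, 70),
                   predicted_fluid_intelligence = rnorm(n),
                   predicted_neuroticism = rnorm(n))
  pt$brain_age_delta <- pt$predicted_age - pt$age
  habit <- rnorm(n)
  habit[1:10] <- NA
  fit <- habit_regression(habit, pt, list(age = rnorm(n)), form = "Eq4")
  expect_identical(fit$n, 90L)
  # design columns are standardized with the n-1 denominator on kept rows
  expect_equal(unname(colMeans(fit$X[, -1])), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(apply(fit$X[, -1], 2, sd)), rep(1, 4), tolerance = 1e-10)
  expect_error(habit_regression(habit[1:5], pt[1:5, ], list(age = rnorm(5)),
                                form = "Eq4"), "fewer rows")
})

test_that("Eq6 and marginal forms expose the documented coefficient sets", {
  set.seed(68)
  n <- 80
  pt <- data.frame(subject_id = as.character(1:n),
                   age = runif(n, 40, 70),
                   fluid_intelligence = sample(0:13, n, TRUE),
                   neuroticism = sample(0:12, n, TRUE),
                   predicted_age = runif(n, 40, 70),
                   predicted_fluid_intelligence = rnorm(n),
                   predicted_neuroticism = rnorm(n))
  pt$brain_age_delta <- pt$predicted_age - pt$age
  dec <- list(age = rnorm(n), fluid_intelligence = rnorm(n),
              neuroticism = rnorm(n))
  habit <- rnorm(n)
  f6 <- habit_regression(habit, pt, dec, form = "Eq6")
  expect_length(f6$coefficients, 7)  # intercept + 6
  f_m <- habit_regression(habit, pt, dec, form = "marginal",
                          marginal_proxy = "brain_age_delta")
  expect_length(f_m$coefficients, 2)
  expect_error(habit_regression(habit, pt, dec, form = "marginal"),
               "marginal_proxy")
})

test_that("parametric bootstrap collapses to the estimates as noise vanishes", {
  set.seed(69)
  n <- 50
  x <- rnorm(n)
  pt <- data.frame(subject_id = as.character(1:n),
                   age = x, fluid_intelligence = rnorm(n),
                   neuroticism = rnorm(n), predicted_age = rnorm(n),
                   predicted_fluid_intelligence = rnorm(n),
                   predicted_neuroticism = rnorm(n))
  pt$brain_age_delta <- pt$predicted_age - pt$age
  habit <- 0.7 * x + 1e-8 * rnorm(n)
  fit <- habit_regression(habit, pt, form = "Eq7")
  dr <- parametric_bootstrap(fit, n_draws = 500, seed = 1)
  expect_lt(max(abs(sweep(dr$draws, 2, fit$coefficients))), 1e-5)
})

test_that("draw moments match OLS theory", {
  set.seed(70)
  n <- 500
  pt <- data.frame(subject_id = as.character(1:n),
                   age = runif(n, 40, 70),
                   fluid_intelligence = sample(0:13, n, TRUE),
                   neuroticism = sample(0:12, n, TRUE),
                   predicted_age = runif(n, 40, 70),
                   predicted_fluid_intelligence = rnorm(n),
                   predicted_neuroticism = rnorm(n))
  pt$brain_age_delta <- pt$predicted_age - pt$age
  habit <- 0.3 * scale(pt$age)[, 1] + rnorm(n)
  fit <- habit_regression(habit, pt, list(age = rnorm(n)), form = "Eq4")
  dr <- parametric_bootstrap(fit, n_draws = 10000, seed = 2)
  se_classic <- fit$sigma * sqrt(diag(solve(crossprod(fit$X))))
  draw_sd <- apply(dr$draws, 2, sd)
  mc_se <- draw_sd / sqrt(nrow(dr$draws))
  expect_true(all(abs(colMeans(dr$draws) - fit$coefficients) < 3.5 * mc_se))
  expect_true(all(abs(draw_sd / se_classic - 1) < 0.05))
  # summary and tidy exports agree with the draw matrix
  sm <- summary(dr)
  expect_identical(nrow(sm), 5L)
  expect_equal(sm$ci_lower,
               unname(apply(dr$draws, 2, quantile, 0.025)))
  td <- tidy_draws(dr)
  expect_identical(nrow(td), 10000L * 5L)
})

test_that("VIF matches its closed form and an auxiliary-regression oracle", {
  set.seed(71)
  n <- 400
  x1 <- as.numeric(scale(rnorm(n)))
  e <- rnorm(n)
  e_orth <- as.numeric(scale(residuals(lm(e ~ x1))))
  x2 <- 0.8 * x1 + sqrt(1 - 0.64) * e_orth  # empirical correlation exactly 0.8
  v <- vif(cbind(a = x1, b = x2))
  expect_equal(unname(v), rep(1 / (1 - 0.64), 2), tolerance = 0.01)
  # orthogonal predictors have VIF 1
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, -1]
  expect_equal(unname(vif(q)), rep(1, 3), tolerance = 1e-10)
  # three-predictor toy against car's implementation
  X3 <- data.frame(y = rnorm(n), p1 = rnorm(n), p2 = x1, p3 = x2)
  v_pkg <- vif(as.matrix(X3[, c("p1", "p2", "p3")]))
  v_car <- car::vif(lm(y ~ p1 + p2 + p3, data = X3))
  expect_equal(unname(v_pkg), unname(v_car), tolerance = 1e-8)
  # perfect collinearity is reported as infinite
  expect_identical(unname(vif(cbind(x1, 2 * x1))), c(Inf, Inf))
  expect_error(vif(cbind(x1)), "2 predictors")
})
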