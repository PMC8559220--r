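test_that("split-half partitions are disjoint, balanced, and reproducible", {
  s10 <- split_half(sprintf("S%02d", 1:10), seed = 1)
  expect_length(s10$validation, 5)
  expect_length(s10$generalization, 5)
  expect_length(intersect(s10$validation, s10$generalization), 0)
  expect_identical(split_half(sprintf("S%02d", 1:10), seed = 1), s10)
  s1001 <- split_half(as.character(1:1001), seed = 2)
  expect_setequal(c(length(s1001$validation), length(s1001$generalization)),
                  c(500, 501))
  expect_error(split_half(character(0), 1), "2 subjects")
})

test_that("Monte-Carlo splits have the documented geometry and coverage", {
  subj <- sprintf("S%03d", 1:100)
  splits <- make_mc_splits(subj, n_splits = 100, test_fraction = 0.1, seed = 4)
  expect_length(splits, 100)
  expect_true(all(vapply(splits, function(s) length(s$test), 1L) == 10))
  expect_true(all(vapply(splits, function(s)
    length(intersect(s$train, s$test)), 1L) == 0))
  # each subject appears in test sets Binomial(100, 0.1) times: 10 +/- 4 sigma
  counts <- table(factor(unlist(lapply(splits, `[[`, "test")), levels = subj))
  expect_true(all(counts >= 0 & counts <= 22))
  expect_lt(abs(mean(counts) - 10), 1.5)
  expect_error(make_mc_splits(subj[1:5], test_fraction = 0.1), "degenerate")
})

test_that("the full grid enumerates 5 depths x 5 feature-subset options", {
  g <- model_grid()
  st <- grid_settings(g, p = 2074)
  expect_identical(nrow(st), 25L)
  expect_setequal(unique(st$max_depth), c(5, 10, 20, 40, Inf))
  expect_setequal(st$mtry[st$subset == "1"], 1L)
  expect_setequal(st$mtry[st$subset == "5"], 5L)
  expect_setequal(st$mtry[st$subset == "log2"], floor(log2(2074)))
  expect_setequal(st$mtry[st$subset == "sqrt"], floor(sqrt(2074)))
  expect_setequal(st$mtry[st$subset == "all"], 2074L)
  expect_error(model_grid(max_depths = numeric(0)), "non-empty")
})

test_that("strong linear signal is recovered and permuted targets are not", {
  set.seed(41)
  n <- 500
  ids <- sprintf("S%03d", 1:n)
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(ids, paste0("x", 1:5)))
  y <- setNames(2 * X[, 1] + 1, ids)
  plan <- split_plan(ids, seed = 6, n_splits = 5)
  grid <- model_grid(n_trees = 100, max_depths = Inf, feature_subsets = "all")
  ps <- fit_predict_model(X, y, grid, plan, "regression", seed = 8)
  expect_gt(mean(ps$validation_scores), 0.9)
  y_perm <- setNames(sample(y), ids)
  ps0 <- fit_predict_model(X, y_perm, grid, plan, "regression", seed = 8)
  expect_lte(mean(ps0$validation_scores), 0.05)
  # reproducibility with fixed seeds
  ps2 <- fit_predict_model(X, y, grid, plan, "regression", seed = 8)
  expect_identical(ps$generalization_predictions, ps2$generalization_predictions)
  expect_identical(ps$plan_hash, plan$hash)
})

test_that("nested tuning picks the better depth on step-function data", {
  set.seed(42)
  n <- 240
  ids <- sprintf("S%03d", 1:n)
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(ids, paste0("x", 1:3)))
  y <- setNames(as.numeric(X[, 1] > 0) + 0.05 * rnorm(n), ids)
  plan <- split_plan(ids, seed = 1, n_splits = 3)
  grid <- model_grid(n_trees = 50, max_depths = c(5, Inf),
                     feature_subsets = c("1", "all"))
  ps <- fit_predict_model(X, y, grid, plan, "regression", seed = 3)
  expect_identical(nrow(ps$chosen), 3L)
  expect_true(all(ps$chosen$mtry %in% c(1L, 3L)))
  expect_gt(mean(ps$validation_scores), 0.5)
})

test_that("CV-bagging averages duplicates and reduces error", {
  vp <- data.frame(split = c(1, 1, 2, 2),
                   subject_id = c("A", "B", "A", "C"),
                   prediction = c(1, 7, 3, 5))
  gp <- matrix(c(7, 7, 7, 0, 7, 4), 2, 3, byrow = TRUE,
               dimnames = list(c("G1", "G2"), NULL))
  ps <- fake_prediction_set(vp, gp, validation_ids = c("A", "B", "C", "D"))
  bag <- cv_bag(ps)
  expect_equal(bag$validation[["A"]], 2)  # mean(1, 3)
  expect_equal(bag$validation[["B"]], 7)
  expect_equal(bag$generalization[["G1"]], 7)  # all splits agree
  expect_equal(bag$generalization[["G2"]], mean(c(7, 0, 4)))
  expect_identical(bag$missing_validation, "D")

  # averaging across noisy split predictions beats single splits on average
  set.seed(43)
  y <- rnorm(50)
  wins <- vapply(1:50, function(r) {
    preds <- sapply(1:100, function(s) y + rnorm(50, sd = 1))
    mse_bag <- mean((rowMeans(preds) - y)^2)
    mse_each <- colMeans((preds - y)^2)
    mse_bag <= min(mse_each)
  }, logical(1))
  expect_gt(mean(wins), 0.9)
})

test_that("bagged predictions are invariant to split order", {
  set.seed(44)
  n <- 80
  ids <- sprintf("S%03d", 1:n)
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(ids, paste0("x", 1:3)))
  y <- setNames(X[, 1] + rnorm(n, sd = 0.2), ids)
  plan <- split_plan(ids, seed = 9, n_splits = 4)
  grid <- model_grid(n_trees = 30, max_depths = Inf, feature_subsets = "all")
  ps <- fit_predict_model(X, y, grid, plan, "regression", seed = 5)
  perm <- sample(ncol(ps$generalization_predictions))
  ps_shuffled <- ps
  ps_shuffled$generalization_predictions <- ps$generalization_predictions[, perm]
  ps_shuffled$validation_predictions <-
    ps$validation_predictions[order(ps$validation_predictions$subject_id), ]
  bag1 <- cv_bag(ps)
  bag2 <- cv_bag(ps_shuffled)
  expect_equal(bag1$generalization, bag2$generalization)
  expect_equal(bag1$validation, bag2$validation)
})

test_that("extreme-group discretization follows the 33/66 percentile rule", {
  d <- discretize_extremes(1:100)
  expect_identical(which(d$labels == "low"), 1:33)
  expect_identical(which(d$labels == "high"), 67:100)
  expect_identical(d$kept, !is.na(d$labels))
  # symmetric distribution gives balanced groups
  d2 <- discretize_extremes(seq(-1, 1, length.out = 201))
  expect_lt(abs(sum(d2$labels == "low", na.rm = TRUE) -
                  sum(d2$labels == "high", na.rm = TRUE)), 3)
  # ties at the 33rd percentile value all go to the low group
  v <- c(rep(0, 10), rep(1, 30), rep(5, 60))
  q33 <- quantile(v, 0.33, names = FALSE)
  d3 <- discretize_extremes(v)
  expect_identical(q33, 1)
  expect_true(all(d3$labels[v == 1] == "low"))
  expect_error(discretize_extremes(rep(3, 10)), "distinct")
})

test_that("evaluation metrics match definitions and a rank-based oracle", {
  y <- c(3, 1, 4, 1, 5)
  expect_equal(evaluate(y, y, "R2"), 1)
  expect_equal(evaluate(y, y, "MAE"), 0)
  p <- c(2, 2, 3, 0, 6)
  sst <- sum((y - mean(y))^2)
  expect_equal(evaluate(y, p, "R2"), 1 - sum((y - p)^2) / sst)
  expect_equal(evaluate(y, p, "MAE"), mean(abs(y - p)))
  # null AUC is 1/2
  set.seed(45)
  lab <- rep(c("low", "high"), each = 5000)
  expect_lt(abs(evaluate(lab, rnorm(10000), "AUC") - 0.5), 0.02)
  # rank-statistic AUC equals the pROC oracle including ties
  lab2 <- sample(c("low", "high"), 200, TRUE)
  sc <- sample(1:20, 200, TRUE)
  expect_equal(evaluate(lab2, sc, "AUC"),
               as.numeric(pROC::auc(pROC::roc(lab2, sc, levels = c("low", "high"),
                                              direction = "<", quiet = TRUE))))
  expect_error(evaluate(rep("high", 5), rnorm(5), "AUC"), "both classes")
  expect_error(evaluate(rep(2, 5), rnorm(5), "R2"), "zero-variance")
})

test_that("learning curve reproduces the full fit and stays flat under the null", {
  set.seed(46)
  n <- 200
  ids <- sprintf("S%03d", 1:n)
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(ids, paste0("x", 1:3)))
  y <- setNames(X[, 1] + rnorm(n, sd = 0.3), ids)
  plan <- split_plan(ids, seed = 3, n_splits = 3)
  grid <- model_grid(n_trees = 40, max_depths = Inf, feature_subsets = "all")
  ps <- fit_predict_model(X, y, grid, plan, "regression", seed = 4)
  full_n <- length(plan$splits[[1]]$train)
  lc <- learning_curve(X, y, sizes = c(30, full_n), plan, grid, seed = 4)
  expect_equal(lc$mean_score[lc$size == full_n], mean(ps$validation_scores))
  expect_lt(lc$mean_score[lc$size == 30], lc$mean_score[lc$size == full_n])
  y0 <- setNames(rnorm(n), ids)
  lc0 <- learning_curve(X, y0, sizes = c(30, full_n), plan, grid, seed = 4)
  expect_true(all(lc0$mean_score < 0.15))
  expect_error(learning_curve(X, y, sizes = 5, plan, grid), ">= 10")
})
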