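#' Random split-half partition of subjects
#'
#' @param subjects Character vector of subject ids.
#' @param seed Integer seed.
#' @return List with `validation` and `generalization` id vectors (disjoint,
#'   sizes differing by at most one).
#' @export
split_half <- function(subjects, seed) {
  abort_if(length(subjects) < 2, "need at least 2 subjects")
  set.seed(as.integer(seed))
  n <- length(subjects)
  val <- sort(sample.int(n, floor(n / 2)))
  list(validation = subjects[val], generalization = subjects[-val])
}

#' Monte-Carlo (shuffle-split) train/test splits over the validation set
#'
#' Each split draws `floor(n * test_fraction)` test subjects without
#' replacement, independently across splits. The same splits are reused by
#' every model so that paired comparisons are meaningful.
#'
#' @param subjects Validation subject ids.
#' @param n_splits Number of Monte-Carlo splits (study default 100).
#' @param test_fraction Fraction held out per split (study default 0.1).
#' @param seed Integer seed.
#' @return List of `n_splits` lists with `train` and `test` id vectors.
#' @export
make_mc_splits <- function(subjects, n_splits = 100, test_fraction = 0.1, seed = 1) {
  n <- length(subjects)
  n_test <- floor(n * test_fraction)
  abort_if(n_test < 1, "degenerate test size 0: n * test_fraction must be >= 1")
  set.seed(as.integer(seed))
  lapply(seq_len(n_splits), function(s) {
    te <- sort(sample.int(n, n_test))
    list(train = subjects[-te], test = subjects[te])
  })
}

#' Build the full split plan: split-half plus shared Monte-Carlo splits
#'
#' @param subjects All subject ids.
#' @param seed Integer seed (drives both the half split and the MC splits).
#' @param n_splits,test_fraction Passed to [make_mc_splits()].
#' @return An object of class `split_plan` with `validation`,
#'   `generalization`, `splits`, `seed`, and a content `hash` recorded in
#'   every prediction set derived from it.
#' @export
split_plan <- function(subjects, seed, n_splits = 100, test_fraction = 0.1) {
  halves <- split_half(subjects, seed)
  splits <- make_mc_splits(halves$validation, n_splits, test_fraction,
                           seed = seed + 1L)
  plan <- list(validation = halves$validation,
               generalization = halves$generalization,
               splits = splits, seed = as.integer(seed),
               n_splits = n_splits, test_fraction = test_fraction)
  plan$hash <- object_hash(plan[c("validation", "generalization", "splits", "seed")])
  structure(plan, class = "split_plan")
}

#' Serialize a split plan to JSON
#' @param plan A `split_plan`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a split plan written by [write_split_plan()]
#' @param path JSON path.
#' @return A `split_plan`.
#' @export
read_split_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$splits <- lapply(seq_len(nrow(x$splits)), function(i) {
    list(train = x$splits$train[[i]], test = x$splits$test[[i]])
  })
  structure(x, class = "split_plan")
}

#' Random-forest hyperparameter grid
#'
#' The number of trees is fixed (not tuned); maximum depth and the number of
#' features considered per split are tuned by exhaustive search with internal
#' 5-fold cross-validation. The subset labels `"1"` and `"5"` are absolute
#' feature counts; `"log2"`/`"sqrt"` are functions of the feature count;
#' `"all"` uses every feature.
#'
#' @param n_trees Trees per forest (study default 250).
#' @param max_depths Numeric vector of depth limits; `Inf` = unrestricted.
#' @param feature_subsets Character vector of subset labels.
#' @return An object of class `model_grid`.
#' @export
model_grid <- function(n_trees = 250,
                       max_depths = c(5, 10, 20, 40, Inf),
                       feature_subsets = c("1", "5", "log2", "sqrt", "all")) {
  abort_if(length(max_depths) == 0 || length(feature_subsets) == 0,
           "grid must be non-empty")
  structure(list(n_trees = as.integer(n_trees), max_depths = max_depths,
                 feature_subsets = feature_subsets),
            class = "model_grid")
}

#' Enumerate candidate settings of a grid for a given feature count
#' @param grid A [model_grid()].
#' @param p Number of features.
#' @return Data frame with columns `max_depth`, `subset`, `mtry`.
#' @export
grid_settings <- function(grid, p) {
  resolve_mtry <- function(lab) {
    switch(lab,
           "1" = 1L,
           "5" = min(5L, p),
           "log2" = max(1L, floor(log2(p))),
           "sqrt" = max(1L, floor(sqrt(p))),
           "all" = p,
           stop(sprintf("unknown feature subset label '%s'", lab), call. = FALSE))
  }
  out <- expand.grid(max_depth = grid$max_depths, subset = grid$feature_subsets,
                     stringsAsFactors = FALSE)
  out$mtry <- vapply(out$subset, function(s) as.integer(resolve_mtry(s)), 1L)
  out
}

## fit one tuned forest on the given training subjects; return the fitted
## model and the chosen setting
fit_one_split <- function(X, y, train_ids, task, grid, seed, inner_folds = 5) {
  settings <- grid_settings(grid, ncol(X))
  Xtr <- X[train_ids, , drop = FALSE]
  ytr <- y[train_ids]
  if (task == "classification") {
    abort_if(length(unique(as.character(ytr))) < 2,
             "single-class training labels in classification")
  }
  set.seed(seed)
  chosen <- settings[1, ]
  if (nrow(settings) > 1) {
    fold <- sample(rep(seq_len(inner_folds), length.out = length(train_ids)))
    score <- numeric(nrow(settings))
    for (k in seq_len(nrow(settings))) {
      fold_scores <- numeric(inner_folds)
      for (f in seq_len(inner_folds)) {
        inn <- fold != f
        if (task == "classification" &&
            length(unique(as.character(ytr[inn]))) < 2) {
          fold_scores[f] <- NA_real_
          next
        }
        fit <- fit_forest(Xtr[inn, , drop = FALSE], ytr[inn], task,
                          grid$n_trees, settings$mtry[k], settings$max_depth[k],
                          seed)
        pr <- predict_forest(fit, Xtr[!inn, , drop = FALSE], task)
        fold_scores[f] <- if (task == "regression") {
          -mean((ytr[!inn] - pr)^2)
        } else {
          evaluate(ytr[!inn], pr, "AUC")
        }
      }
      score[k] <- mean(fold_scores, na.rm = TRUE)
    }
    chosen <- settings[which.max(score), ]
  }
  final <- fit_forest(Xtr, ytr, task, grid$n_trees, chosen$mtry,
                      chosen$max_depth, seed)
  list(model = final, chosen = chosen)
}

fit_forest <- function(X, y, task, n_trees, mtry, max_depth, seed) {
  depth <- if (is.infinite(max_depth)) 0L else as.integer(max_depth)
  if (task == "classification") {
    ranger::ranger(x = X, y = factor(y, levels = c("low", "high")),
                   num.trees = n_trees, mtry = mtry, max.depth = depth,
                   probability = TRUE, num.threads = 1L, seed = seed,
                   verbose = FALSE)
  } else {
    ranger::ranger(x = X, y = y, num.trees = n_trees, mtry = mtry,
                   max.depth = depth, num.threads = 1L, seed = seed,
                   verbose = FALSE)
  }
}

predict_forest <- function(fit, X, task) {
  pr <- stats::predict(fit, data = X, num.threads = 1L, verbose = FALSE)$predictions
  if (task == "classification") pr[, "high"] else pr
}

#' Fit a proxy model over all Monte-Carlo splits and collect predictions
#'
#' For each split, hyperparameters are chosen by exhaustive search over the
#' grid with internal 5-fold cross-validation on the training part
#' (squared-error for regression, AUC for classification), the forest is
#' refit on the full training part, and predictions are recorded for the
#' split's test subjects and for all generalization subjects. CV-bagged
#' per-subject predictions are the mean across splits.
#'
#' @param features Numeric matrix with rownames = subject ids covering all
#'   plan subjects; no missing values (impute first).
#' @param target Named numeric vector (regression) or named factor/character
#'   with levels low/high (classification).
#' @param grid A [model_grid()].
#' @param plan A [split_plan()].
#' @param task `"regression"` or `"classification"`.
#' @param name Model name recorded in the result.
#' @param seed Integer seed for tuning folds and forest randomness.
#' @return An object of class `prediction_set`.
#' @export
fit_predict_model <- function(features, target, grid, plan,
                              task = c("regression", "classification"),
                              name = "model", seed = 1L) {
  task <- match.arg(task)
  stopifnot(inherits(plan, "split_plan"), inherits(grid, "model_grid"))
  abort_if(!all(is.finite(features)), "non-finite feature values")
  abort_if(is.null(rownames(features)), "features must have subject-id rownames")
  subj <- c(plan$validation, plan$generalization)
  if (task == "classification") {
    ## classification keeps only labeled (extreme-group) subjects
    subj <- intersect(subj, names(target)[!is.na(target)])
  }
  abort_if(!all(subj %in% rownames(features)), "features missing for plan subjects")
  gen_ids <- intersect(plan$generalization, subj)
  Xg <- features[gen_ids, , drop = FALSE]

  n_splits <- length(plan$splits)
  val_pred <- vector("list", n_splits)
  gen_pred <- matrix(NA_real_, length(gen_ids), n_splits,
                     dimnames = list(gen_ids, NULL))
  val_scores <- numeric(n_splits)
  chosen <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    tr <- intersect(plan$splits[[s]]$train, subj)
    te <- intersect(plan$splits[[s]]$test, subj)
    fitted <- fit_one_split(features, target, tr, task, grid,
                            seed = as.integer(seed) + s)
    pr_te <- predict_forest(fitted$model, features[te, , drop = FALSE], task)
    gen_pred[, s] <- predict_forest(fitted$model, Xg, task)
    val_pred[[s]] <- data.frame(split = s, subject_id = te, prediction = pr_te)
    val_scores[s] <- tryCatch(
      evaluate(target[te], pr_te, if (task == "regression") "R2" else "AUC"),
      error = function(e) NA_real_)
    chosen[[s]] <- fitted$chosen
  }
  out <- structure(
    list(name = name, target_name = attr(target, "target_name") %||% "target",
         task = task, plan_hash = plan$hash,
         validation_predictions = do.call(rbind, val_pred),
         generalization_predictions = gen_pred,
         validation_scores = val_scores,
         chosen = do.call(rbind, chosen),
         y = target[subj], validation_ids = intersect(plan$validation, subj),
         generalization_ids = gen_ids, seed = as.integer(seed)),
    class = "prediction_set")
  out$bagged <- cv_bag(out)
  out
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set> model '%s' (%s), %d splits, plan %s\n",
              x$name, x$task, ncol(x$generalization_predictions),
              substr(x$plan_hash, 1, 8)))
  cat(sprintf("  mean validation score: %.3f | generalization subjects: %d\n",
              mean(x$validation_scores), length(x$generalization_ids)))
  invisible(x)
}

#' CV-bag predictions: one out-of-sample value per subject
#'
#' Generalization predictions are averaged across all split models;
#' validation-side duplicate predictions (the same subject landing in several
#' Monte-Carlo test sets) are likewise averaged to one value per subject.
#' Validation subjects never drawn into any test set are reported and
#' excluded.
#'
#' @param pred A `prediction_set`.
#' @return List with named vectors `generalization` and `validation`, plus
#'   `missing_validation` (ids with zero predictions).
#' @export
cv_bag <- function(pred) {
  stopifnot(inherits(pred, "prediction_set"))
  gen <- rowMeans(pred$generalization_predictions)
  vp <- pred$validation_predictions
  val <- tapply(vp$prediction, vp$subject_id, mean)
  val <- stats::setNames(as.numeric(val), names(val))
  missing <- setdiff(pred$validation_ids, names(val))
  list(generalization = gen, validation = val, missing_validation = missing)
}

#' Discretize a continuous target into extreme groups
#'
#' Low = values at or below the 33rd percentile, high = values at or above
#' the 66th percentile; the middle band is excluded. Ties at either boundary
#' are inclusive, so all values equal to the 33rd-percentile value go to the
#' low group.
#'
#' @param values Numeric vector.
#' @return List with `labels` (factor low/high, `NA` for the excluded
#'   middle), `kept` (logical mask), and the two `thresholds`.
#' @export
discretize_extremes <- function(values) {
  abort_if(length(unique(values[!is.na(values)])) < 3,
           "need at least 3 distinct values to form extreme groups")
  q <- stats::quantile(values, c(0.33, 0.66), na.rm = TRUE, names = FALSE)
  low <- values <= q[1]
  high <- values >= q[2]
  labels <- factor(ifelse(low, "low", ifelse(high, "high", NA)),
                   levels = c("low", "high"))
  list(labels = labels, kept = !is.na(labels), thresholds = q)
}

#' Evaluate predictions
#'
#' `R2` is 1 - SSE/SST, `MAE` the mean absolute error, `AUC` the rank
#' statistic (Mann-Whitney form, ties averaged) of the score for the "high"
#' class.
#'
#' @param y_true Observed values (factor/character low/high for AUC).
#' @param y_pred Predictions (scores for AUC).
#' @param metric `"R2"`, `"MAE"`, or `"AUC"`.
#' @return Numeric scalar.
#' @export
evaluate <- function(y_true, y_pred, metric = c("R2", "MAE", "AUC")) {
  metric <- match.arg(metric)
  abort_if(length(y_true) != length(y_pred) || length(y_true) == 0,
           "y_true and y_pred must be aligned non-empty vectors")
  if (metric == "AUC") {
    pos <- as.character(y_true) == "high"
    abort_if(!any(pos) || all(pos), "AUC requires both classes present")
    r <- rank(y_pred)
    n1 <- sum(pos); n0 <- sum(!pos)
    return((sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0))
  }
  y_true <- as.numeric(y_true)
  if (metric == "MAE") return(mean(abs(y_true - y_pred)))
  sst <- sum((y_true - mean(y_true))^2)
  abort_if(sst == 0, "R2 undefined for zero-variance y_true")
  1 - sum((y_true - y_pred)^2) / sst
}

#' Learning curve over training-set sizes
#'
#' For each size, each Monte-Carlo split's training part is subsampled to
#' that size, the tuned forest is refit, and the split's test score is
#' recorded. At the full training size this reproduces
#' [fit_predict_model()]'s split scores (same seeds, same tuning).
#'
#' @param features,target,grid,plan,task As in [fit_predict_model()].
#' @param sizes Integer vector of training sizes (each >= 10).
#' @param n_splits_used Number of plan splits to use per size (default all).
#' @param seed Integer seed (must match the fit for reproduction at full n).
#' @return Data frame with columns `size`, `mean_score`, `sd_score`.
#' @export
learning_curve <- function(features, target, sizes, plan, grid,
                           task = "regression", n_splits_used = NULL, seed = 1L) {
  abort_if(any(sizes < 10), "sizes must be >= 10")
  use <- seq_len(min(n_splits_used %||% length(plan$splits), length(plan$splits)))
  rows <- lapply(sizes, function(sz) {
    sc <- vapply(use, function(s) {
      tr <- plan$splits[[s]]$train
      te <- plan$splits[[s]]$test
      abort_if(sz > length(tr), "size %d exceeds available training n %d",
               sz, length(tr))
      set.seed(as.integer(seed) + 1000L * s + sz)
      tr_s <- if (sz < length(tr)) sample(tr, sz) else tr
      fitted <- fit_one_split(features, target, tr_s, task, grid,
                              seed = as.integer(seed) + s)
      pr <- predict_forest(fitted$model, features[te, , drop = FALSE], task)
      if (task == "regression") evaluate(target[te], pr, "R2")
      else evaluate(target[te], pr, "AUC")
    }, numeric(1))
    data.frame(size = sz, mean_score = mean(sc), sd_score = stats::sd(sc))
  })
  do.call(rbind, rows)
}
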