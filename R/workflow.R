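#' Built-in execution profiles
#'
#' `"test"` is the desk-scale profile (20 Monte-Carlo splits, 100 trees, a
#' reduced tuning grid, 200 resamples, 1000 coefficient draws); `"paper"` is
#' the study-faithful profile (100 splits, 250 trees, the full Table-3 grid,
#' 10000 resamples and draws).
#'
#' @param profile `"test"` or `"paper"`.
#' @return Named list of profile settings.
#' @export
profile_settings <- function(profile = c("test", "paper")) {
  profile <- match.arg(profile)
  if (profile == "paper") {
    list(n_splits = 100L, test_fraction = 0.1,
         grid = model_grid(n_trees = 250),
         n_perm = 10000L, n_boot = 10000L, n_draws = 10000L)
  } else {
    list(n_splits = 20L, test_fraction = 0.1,
         grid = model_grid(n_trees = 100, max_depths = c(10, Inf),
                           feature_subsets = "sqrt"),
         n_perm = 200L, n_boot = 200L, n_draws = 1000L)
  }
}

pipeline_stages <- c("simulate", "split", "features", "fit", "proxies",
                     "infer", "report")

#' Pipeline configuration
#'
#' @param outdir Output directory for all artifacts.
#' @param generative A [generative_config()] for the synthetic cohort, or
#'   `NULL` to read a previously written cohort from `outdir`.
#' @param seed Integer global seed (stochastic stages derive child seeds).
#' @param profile `"test"` or `"paper"`; supplies defaults for splits, grid,
#'   and resample counts, each overridable below.
#' @param model_specs Character vector of model names from [model_catalog()]
#'   to fit (expected widths are not enforced for non-default layouts).
#' @param proxy_model Model whose bagged predictions become the proxies.
#' @param stages Character vector of enabled stages (subset of
#'   simulate, split, features, fit, proxies, infer, report); disabled stages
#'   are served from cached artifacts in `outdir`.
#' @param classification_targets Targets additionally fit as extreme-group
#'   classification (default `"age"`; set `character()` to skip).
#' @param n_splits,test_fraction,grid,n_perm,n_boot,n_draws Overrides of the
#'   profile defaults.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            generative = NULL,
                            seed = 1L,
                            profile = c("test", "paper"),
                            model_specs = "combined",
                            proxy_model = model_specs[1],
                            stages = pipeline_stages,
                            classification_targets = "age",
                            n_splits = NULL, test_fraction = NULL,
                            grid = NULL, n_perm = NULL, n_boot = NULL,
                            n_draws = NULL) {
  profile <- match.arg(profile)
  prof <- profile_settings(profile)
  catalog <- model_catalog()
  abort_if(!all(model_specs %in% names(catalog)),
           "unknown model spec(s): %s",
           paste(setdiff(model_specs, names(catalog)), collapse = ", "))
  abort_if(!proxy_model %in% model_specs, "proxy_model must be one of model_specs")
  abort_if(!all(stages %in% pipeline_stages), "unknown stage name")
  structure(
    list(outdir = outdir, generative = generative, seed = as.integer(seed),
         profile = profile, model_specs = model_specs, proxy_model = proxy_model,
         stages = stages, classification_targets = classification_targets,
         n_splits = n_splits %||% prof$n_splits,
         test_fraction = test_fraction %||% prof$test_fraction,
         grid = grid %||% prof$grid,
         n_perm = n_perm %||% prof$n_perm,
         n_boot = n_boot %||% prof$n_boot,
         n_draws = n_draws %||% prof$n_draws),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the [pipeline_config()] arguments; the
#' `generative` block is passed to [generative_config()].
#'
#' @param path YAML file path.
#' @param outdir Optional override of the configured output directory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, outdir = NULL) {
  y <- yaml::read_yaml(path)
  gen <- NULL
  if (!is.null(y$generative)) {
    ga <- y$generative
    if (!is.null(ga$block_sizes)) ga$block_sizes <- unlist(ga$block_sizes)
    if (!is.null(ga$target_effects)) ga$target_effects <- lapply(y$generative$target_effects, unlist)
    if (!is.null(ga$habit_effects)) ga$habit_effects <- lapply(y$generative$habit_effects, unlist)
    gen <- do.call(generative_config, ga)
  }
  args <- y[setdiff(names(y), "generative")]
  args$generative <- gen
  if (!is.null(outdir)) args$outdir <- outdir
  do.call(pipeline_config, args)
}

file_hash <- function(path) {
  object_hash(readChar(path, file.info(path)$size, useBytes = TRUE))
}

targets_all <- c("age", "fluid_intelligence", "neuroticism")

#' Run the proxy-measure pipeline
#'
#' Executes the enabled stages in dependency order: simulate the cohort and
#' component series, derive the split plan, build features (median
#' imputation fitted on validation rows; tangent connectivity with the
#' reference fitted on validation covariances only), fit the forest models
#' over the shared Monte-Carlo splits with CV-bagging, assemble proxies and
#' validation-fitted deconfounders, run the inference layer, and write a
#' report. Disabled stages are served from artifacts cached in `outdir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the artifact `manifest` (paths, content
#'   hashes, seeds) and the in-memory stage `state`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env(parent = emptyenv())
  manifest <- list()
  seeds <- spawn_seeds(config$seed, c("plan", "fit", "infer"))
  on_stage <- function(s) s %in% config$stages
  path_of <- function(f) file.path(config$outdir, f)
  record <- function(name, path, seed = NA) {
    manifest[[name]] <<- list(path = path, hash = file_hash(path), seed = seed)
  }

  ## -- simulate ---------------------------------------------------------
  if (on_stage("simulate")) {
    abort_if(is.null(config$generative), "simulate stage needs a generative config")
    gen <- generate_cohort(config$generative)
    state$cohort <- gen$cohort
    state$truth <- gen$truth
    state$series <- generate_component_timeseries(gen$cohort, config$generative)
    write_cohort(gen$cohort, path_of("cohort.csv"))
    write_truth(gen$truth, path_of("truth.json"))
    record("cohort", path_of("cohort.csv"), config$generative$seed)
    record("truth", path_of("truth.json"), config$generative$seed)
  } else {
    abort_if(!file.exists(path_of("cohort.csv")),
             "simulate disabled but no cached cohort in outdir")
    state$cohort <- read_cohort(path_of("cohort.csv"))
    if (!is.null(config$generative)) {
      state$series <- generate_component_timeseries(state$cohort, config$generative)
    }
  }
  cohort <- state$cohort

  ## -- split ------------------------------------------------------------
  if (on_stage("split")) {
    state$plan <- split_plan(cohort$data$subject_id, seed = seeds[["plan"]],
                             n_splits = config$n_splits,
                             test_fraction = config$test_fraction)
    write_split_plan(state$plan, path_of("plan.json"))
    record("plan", path_of("plan.json"), seeds[["plan"]])
  } else if (file.exists(path_of("plan.json"))) {
    state$plan <- read_split_plan(path_of("plan.json"))
  } else {
    abort_if(any(c("features", "fit", "proxies", "infer") %in% config$stages),
             "split disabled but no cached plan in outdir")
  }
  plan <- state$plan

  ## -- features ---------------------------------------------------------
  if (on_stage("features")) {
    imp <- impute_median_with_indicators(cohort, fit_rows = plan$validation)
    state$cohort_imputed <- imp$cohort
    state$imputer <- imp$imputer
    conn <- NULL
    if (!is.null(state$series)) {
      covs <- lapply(state$series$series, shrinkage_covariance)
      emb <- tangent_embed(covs[plan$validation], covs[plan$generalization])
      conn <- rbind(emb$train_vectors, emb$test_vectors)
      state$tangent_reference <- emb$reference
    }
    state$connectivity <- conn
    if (!is.null(conn)) {
      utils::write.csv(data.frame(subject_id = rownames(conn), conn,
                                  check.names = FALSE),
                       path_of("connectivity.csv"), row.names = FALSE)
      record("connectivity", path_of("connectivity.csv"))
    }
  }

  ## -- fit --------------------------------------------------------------
  if (on_stage("fit")) {
    abort_if(is.null(state$cohort_imputed), "fit stage needs the features stage")
    state$fits <- list()
    bag_rows <- list()
    score_rows <- list()
    split_rows <- list()
    catalog <- model_catalog()
    for (mname in config$model_specs) {
      spec <- model_spec(mname, catalog[[mname]]$blocks)  # widths not enforced
      for (t in targets_all) {
        X <- assemble_model_matrix(spec, state$cohort_imputed,
                                   connectivity = state$connectivity, target = t)
        y <- stats::setNames(cohort$data[[t]], cohort$data$subject_id)
        ps <- fit_predict_model(X, y, config$grid, plan, task = "regression",
                                name = mname, seed = seeds[["fit"]])
        abort_if(!identical(ps$plan_hash, plan$hash), "plan-hash mismatch")
        state$fits[[paste(mname, t, sep = ".")]] <- ps
        bag_rows[[length(bag_rows) + 1L]] <- data.frame(
          model = mname, target = t, task = "regression",
          side = rep(c("generalization", "validation"),
                     c(length(ps$bagged$generalization), length(ps$bagged$validation))),
          subject_id = c(names(ps$bagged$generalization), names(ps$bagged$validation)),
          prediction = c(ps$bagged$generalization, ps$bagged$validation))
        vp <- ps$validation_predictions
        split_rows[[length(split_rows) + 1L]] <- data.frame(
          model = mname, target = t, task = "regression", vp)
        yt <- y[names(ps$bagged$generalization)]
        score_rows[[length(score_rows) + 1L]] <- data.frame(
          model = mname, target = t, task = "regression",
          mean_validation_R2 = mean(ps$validation_scores, na.rm = TRUE),
          bagged_R2 = evaluate(yt, ps$bagged$generalization, "R2"),
          bagged_MAE = evaluate(yt, ps$bagged$generalization, "MAE"),
          bagged_AUC = NA_real_)
        if (t %in% config$classification_targets) {
          disc <- discretize_extremes(cohort$data[[t]])
          yl <- stats::setNames(as.character(disc$labels), cohort$data$subject_id)
          yl <- yl[!is.na(yl)]
          psc <- fit_predict_model(X, yl, config$grid, plan,
                                   task = "classification", name = mname,
                                   seed = seeds[["fit"]])
          state$fits[[paste(mname, t, "class", sep = ".")]] <- psc
          gen_lab <- yl[names(psc$bagged$generalization)]
          score_rows[[length(score_rows) + 1L]] <- data.frame(
            model = mname, target = t, task = "classification",
            mean_validation_R2 = NA_real_, bagged_R2 = NA_real_,
            bagged_MAE = NA_real_,
            bagged_AUC = evaluate(gen_lab, psc$bagged$generalization, "AUC"))
          bag_rows[[length(bag_rows) + 1L]] <- data.frame(
            model = mname, target = t, task = "classification",
            side = "generalization",
            subject_id = names(psc$bagged$generalization),
            prediction = psc$bagged$generalization)
        }
      }
    }
    state$bagged <- do.call(rbind, c(bag_rows, list(make.row.names = FALSE)))
    state$scores <- do.call(rbind, c(score_rows, list(make.row.names = FALSE)))
    utils::write.csv(state$bagged, path_of("predictions_bagged.csv"), row.names = FALSE)
    utils::write.csv(do.call(rbind, c(split_rows, list(make.row.names = FALSE))),
                     path_of("predictions_splits.csv"), row.names = FALSE)
    utils::write.csv(state$scores, path_of("scores.csv"), row.names = FALSE)
    record("predictions_bagged", path_of("predictions_bagged.csv"), seeds[["fit"]])
    record("predictions_splits", path_of("predictions_splits.csv"), seeds[["fit"]])
    record("scores", path_of("scores.csv"), seeds[["fit"]])
  } else if (file.exists(path_of("predictions_bagged.csv"))) {
    state$bagged <- utils::read.csv(path_of("predictions_bagged.csv"))
    if (file.exists(path_of("scores.csv"))) {
      state$scores <- utils::read.csv(path_of("scores.csv"))
    }
  }

  ## -- proxies ----------------------------------------------------------
  if (on_stage("proxies")) {
    abort_if(is.null(state$bagged), "proxies stage needs fit artifacts")
    state$proxies <- proxy_table_from_bagged(state$bagged, config$proxy_model,
                                             cohort, plan)
    state$deconfounders <- fit_all_deconfounders(cohort, plan, state$proxies)
    utils::write.csv(state$proxies, path_of("proxies.csv"), row.names = FALSE)
    jsonlite::write_json(
      lapply(state$deconfounders, function(byt) lapply(byt, function(m) unclass(m$model))),
      path_of("deconfounders.json"), auto_unbox = TRUE, digits = NA)
    record("proxies", path_of("proxies.csv"))
    record("deconfounders", path_of("deconfounders.json"))
  } else if (file.exists(path_of("proxies.csv"))) {
    state$proxies <- utils::read.csv(path_of("proxies.csv"))
    state$deconfounders <- fit_all_deconfounders(cohort, plan, state$proxies)
  }

  ## -- infer ------------------------------------------------------------
  if (on_stage("infer")) {
    abort_if(is.null(state$proxies), "infer stage needs proxies")
    inf <- run_inference(cohort, plan, state$proxies, state$deconfounders,
                         state$bagged, config, seed = seeds[["infer"]])
    state$inference <- inf
    jsonlite::write_json(inf$records, path_of("inference.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(inf$draws, path_of("draws.csv"), row.names = FALSE)
    record("inference", path_of("inference.json"), seeds[["infer"]])
    record("draws", path_of("draws.csv"), seeds[["infer"]])
  }

  ## -- report -----------------------------------------------------------
  if (on_stage("report")) {
    rep <- report(config$outdir)
    state$report <- rep
    jsonlite::write_json(rep, path_of("report.json"), auto_unbox = TRUE, digits = NA)
    record("report", path_of("report.json"))
  }

  manifest_path <- path_of("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, state = state))
}

## reshape bagged long predictions into the per-subject proxy table
proxy_table_from_bagged <- function(bagged, proxy_model, cohort, plan) {
  b <- bagged[bagged$model == proxy_model & bagged$task == "regression" &
                bagged$side == "generalization", ]
  abort_if(nrow(b) == 0, "no bagged generalization predictions for model '%s'",
           proxy_model)
  preds <- list()
  for (t in targets_all) {
    bt <- b[b$target == t, ]
    preds[[t]] <- list(plan_hash = plan$hash,
                       bagged = list(generalization =
                                       stats::setNames(bt$prediction, bt$subject_id)))
  }
  ids <- plan$generalization
  rows <- match(ids, cohort$data$subject_id)
  out <- data.frame(subject_id = ids,
                    age = cohort$data$age[rows],
                    fluid_intelligence = cohort$data$fluid_intelligence[rows],
                    neuroticism = cohort$data$neuroticism[rows])
  for (t in targets_all) {
    out[[paste0("predicted_", t)]] <- unname(preds[[t]]$bagged$generalization[ids])
  }
  out$brain_age_delta <- brain_age_delta(out$predicted_age, out$age)
  out
}

## validation-fitted quadratic deconfounders for every (habit, confounder)
fit_all_deconfounders <- function(cohort, plan, proxies) {
  val_rows <- match(plan$validation, cohort$data$subject_id)
  gen_rows <- match(proxies$subject_id, cohort$data$subject_id)
  out <- list()
  for (h in cohort$habit_cols) {
    out[[h]] <- list()
    for (t in targets_all) {
      m <- fit_quadratic_deconfounder(cohort$data[[h]][val_rows],
                                      cohort$data[[t]][val_rows],
                                      confounder_name = t,
                                      fit_split = "validation")
      out[[h]][[t]] <- list(model = m,
                            values = apply_deconfounder(m, cohort$data[[t]][gen_rows]))
    }
  }
  out
}

run_inference <- function(cohort, plan, proxies, deconfounders, bagged,
                          config, seed = 1L) {
  records <- list()
  draws_rows <- list()
  gen_rows <- match(proxies$subject_id, cohort$data$subject_id)

  ## habit regressions (Eq4) with parametric bootstrap
  for (h in cohort$habit_cols) {
    habit_vals <- cohort$data[[h]][gen_rows]
    dec <- lapply(deconfounders[[h]], `[[`, "values")
    fit <- habit_regression(habit_vals, proxies, dec, form = "Eq4",
                            habit_name = h)
    dr <- parametric_bootstrap(fit, n_draws = config$n_draws, seed = seed)
    sm <- summary(dr)
    sm$label <- c("intercept", unname(fit$predictor_labels))
    records[[paste0("habit_", h)]] <- sm
    draws_rows[[h]] <- tidy_draws(dr)
  }

  ## Eq7 joint proxy+target model and its VIFs, on the first habit
  h1 <- cohort$habit_cols[1]
  fit7 <- habit_regression(cohort$data[[h1]][gen_rows], proxies,
                           form = "Eq7", habit_name = h1)
  records$vif_eq7 <- as.list(vif(fit7$X[, -1, drop = FALSE]))

  ## permutation + bootstrap for each regression model/target
  if (!is.null(bagged)) {
    breg <- bagged[bagged$task == "regression" & bagged$side == "generalization", ]
    perf <- list()
    for (key in unique(paste(breg$model, breg$target))) {
      parts <- strsplit(key, " ")[[1]]
      bt <- breg[breg$model == parts[1] & breg$target == parts[2], ]
      y <- cohort$data[[parts[2]]][match(bt$subject_id, cohort$data$subject_id)]
      pt <- permutation_test_baseline(y, bt$prediction, "R2",
                                      n_perm = config$n_perm, seed = seed)
      bc <- bootstrap_ci(y, bt$prediction, "R2", n_boot = config$n_boot,
                         seed = seed)
      perf[[key]] <- list(model = parts[1], target = parts[2],
                          R2 = pt$observed, p_permutation = pt$p_value,
                          ci_lower = bc$ci_lower, ci_upper = bc$ci_upper,
                          n = pt$n_subjects)
    }
    records$performance <- unname(perf)
  }
  list(records = records,
       draws = do.call(rbind, c(draws_rows, list(make.row.names = FALSE))))
}

#' Summary tables from pipeline artifacts
#'
#' Regenerates the report purely from the artifacts on disk, so a report
#' recomputed from a manifest equals the original.
#'
#' @param outdir Pipeline output directory containing the artifacts.
#' @return List with `scores` (per model/target approximation scores),
#'   `habit_coefficients` (one row per habit and proxy coefficient, Eq4
#'   form), and `classification` (AUC table) data frames.
#' @export
report <- function(outdir) {
  sc_path <- file.path(outdir, "scores.csv")
  inf_path <- file.path(outdir, "inference.json")
  abort_if(!file.exists(inf_path) || !file.exists(sc_path),
           "inference artifacts not present in '%s'", outdir)
  scores <- utils::read.csv(sc_path)
  inf <- jsonlite::read_json(inf_path, simplifyVector = TRUE)
  habit_tabs <- inf[grep("^habit_", names(inf))]
  coefs <- do.call(rbind, c(habit_tabs, list(make.row.names = FALSE)))
  proxy_labels <- c("brain_age_delta", "pred_fluid_intelligence",
                    "pred_neuroticism")
  list(scores = scores[scores$task == "regression",
                       c("model", "target", "mean_validation_R2",
                         "bagged_R2", "bagged_MAE")],
       habit_coefficients = coefs[coefs$label %in% proxy_labels, ],
       habit_coefficients_full = coefs,
       classification = scores[scores$task == "classification",
                               c("model", "target", "bagged_AUC")],
       vif_eq7 = inf$vif_eq7)
}
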