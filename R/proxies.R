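#' Brain age delta
#'
#' The difference between predicted and chronological age; positive values
#' indicate an older-appearing brain.
#'
#' @param predicted_age Numeric vector of predicted ages.
#' @param age Numeric vector of chronological ages.
#' @return Numeric vector `predicted_age - age`.
#' @export
brain_age_delta <- function(predicted_age, age) {
  abort_if(length(predicted_age) != length(age), "length mismatch")
  predicted_age - age
}

#' Fit a quadratic deconfounder on validation data
#'
#' Ordinary least squares of a measure of interest (e.g. sleep duration) on
#' the confounder and its square, fitted exclusively on validation-split
#' rows. The confounder is centered before squaring to reduce collinearity
#' between the linear and quadratic terms; the centering constant is stored
#' so application is consistent. An intercept is included (an OLS quadratic
#' without one is a biased residualizer); it is absorbed downstream by the
#' habit regression's own intercept.
#'
#' @param measure Numeric vector of the measure on validation rows.
#' @param confounder Numeric vector of the confounder (e.g. age) on the same
#'   rows.
#' @param confounder_name Label stored with the model.
#' @param center Center the confounder before squaring (default TRUE).
#' @param fit_split Optional id/hash of the validation split, stored for the
#'   leakage audit trail.
#' @return An object of class `deconfounder_model` with coefficients
#'   `intercept`, `beta1` (linear), `beta2` (quadratic), and `center`.
#' @export
fit_quadratic_deconfounder <- function(measure, confounder,
                                       confounder_name = "age",
                                       center = TRUE, fit_split = NULL) {
  keep <- !is.na(measure) & !is.na(confounder)
  measure <- measure[keep]; confounder <- confounder[keep]
  abort_if(length(measure) < 3, "need at least 3 validation rows")
  abort_if(stats::sd(confounder) == 0, "constant confounder: rank-deficient design")
  c0 <- if (center) mean(confounder) else 0
  x <- confounder - c0
  fit <- stats::lm.fit(cbind(1, x, x^2), measure)
  structure(list(confounder = confounder_name,
                 intercept = unname(fit$coefficients[1]),
                 beta1 = unname(fit$coefficients[2]),
                 beta2 = unname(fit$coefficients[3]),
                 center = c0, n_fit = length(measure),
                 fit_split = fit_split),
            class = "deconfounder_model")
}

#' Evaluate a fitted deconfounder on new confounder values
#'
#' Evaluates the stored validation-fitted polynomial on (typically
#' generalization) confounder values; never refits.
#'
#' @param model A `deconfounder_model`.
#' @param confounder Numeric vector of confounder values.
#' @return Numeric vector of deconfounder values.
#' @export
apply_deconfounder <- function(model, confounder) {
  stopifnot(inherits(model, "deconfounder_model"))
  abort_if(is.null(model$beta1) || is.na(model$beta1), "unfitted deconfounder model")
  x <- confounder - model$center
  model$intercept + model$beta1 * x + model$beta2 * x^2
}

#' Serialize a deconfounder model to JSON
#' @param model A `deconfounder_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_deconfounder <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a deconfounder model written by [write_deconfounder()]
#' @param path JSON path.
#' @return A `deconfounder_model`.
#' @export
read_deconfounder <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "deconfounder_model")
}

#' Assemble the proxy table for generalization subjects
#'
#' Combines CV-bagged out-of-sample predictions for the three targets with
#' the observed targets and the brain age delta. Rows are restricted to
#' generalization subjects; the leakage guard asserts that no prediction set
#' was fit under a different split plan.
#'
#' @param preds Named list of `prediction_set` objects with elements `age`,
#'   `fluid_intelligence`, `neuroticism` (regression task).
#' @param cohort The `cohort_table`.
#' @param plan The `split_plan` the predictions were fit under.
#' @return Data frame (one row per generalization subject) with observed
#'   targets, `predicted_*` columns, and `brain_age_delta`.
#' @export
build_proxy_table <- function(preds, cohort, plan) {
  needed <- c("age", "fluid_intelligence", "neuroticism")
  abort_if(!all(needed %in% names(preds)), "preds must cover all three targets")
  for (t in needed) {
    abort_if(!identical(preds[[t]]$plan_hash, plan$hash),
             "prediction set '%s' was fit under a different split plan", t)
  }
  ids <- plan$generalization
  rows <- match(ids, cohort$data$subject_id)
  out <- data.frame(subject_id = ids,
                    age = cohort$data$age[rows],
                    fluid_intelligence = cohort$data$fluid_intelligence[rows],
                    neuroticism = cohort$data$neuroticism[rows])
  for (t in needed) {
    bag <- preds[[t]]$bagged$generalization
    out[[paste0("predicted_", t)]] <- unname(bag[ids])
  }
  out$brain_age_delta <- brain_age_delta(out$predicted_age, out$age)
  out
}
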