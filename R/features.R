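#' Median imputation with missingness indicators
#'
#' Column-wise replacement of missing values with the median computed from
#' the observed part of the variable *on the fitting rows only*; the fitted
#' medians are reused on every other row. A binary indicator column
#' (`<col>_imputed`) is appended for each block-tagged column containing
#' missing values among the fitting rows, so downstream models can exploit
#' the missingness pattern. Columns missing only outside the fitting rows
#' reuse the fitted medians and receive no indicator, keeping train/test
#' column sets identical.
#'
#' @param cohort A `cohort_table`.
#' @param fit_rows Subject ids (character) or row indices used to fit medians;
#'   defaults to all rows.
#' @return List with `cohort` (imputed, indicators appended and tagged with
#'   their parent's block) and `imputer` (medians + indicator column names).
#' @export
impute_median_with_indicators <- function(cohort, fit_rows = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  idx <- resolve_rows(cohort, fit_rows)
  cols <- names(cohort$blocks)
  medians <- numeric(0)
  indicators <- character(0)
  for (col in cols) {
    fit_vals <- cohort$data[[col]][idx]
    abort_if(all(is.na(fit_vals)), "column '%s' is fully missing on the fitting rows", col)
    med <- stats::median(fit_vals, na.rm = TRUE)
    medians[col] <- med
    miss_all <- is.na(cohort$data[[col]])
    if (any(is.na(fit_vals))) {
      ind_col <- paste0(col, "_imputed")
      cohort$data[[ind_col]] <- as.integer(miss_all)
      cohort$blocks[ind_col] <- cohort$blocks[[col]]
      indicators <- c(indicators, ind_col)
    }
    if (any(miss_all)) cohort$data[[col]][miss_all] <- med
  }
  list(cohort = cohort,
       imputer = list(medians = medians, indicator_cols = indicators,
                      fit_rows = cohort$data$subject_id[idx]))
}

resolve_rows <- function(cohort, rows) {
  if (is.null(rows)) return(seq_len(n_subjects(cohort)))
  if (is.character(rows)) {
    idx <- match(rows, cohort$data$subject_id)
    abort_if(anyNA(idx), "unknown subject id in fit_rows")
    return(idx)
  }
  as.integer(rows)
}

#' Model specification: which blocks feed a predictive model
#'
#' @param name Model name.
#' @param blocks Character vector of member blocks (subset of MS, AS, LS,
#'   EDU, EL, sMRI, dMRI, fMRI).
#' @param expected Optional expected column count (checked at assembly; the
#'   fMRI block contributes `p(p-1)/2` connectivity features).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name, blocks, expected = NULL) {
  valid <- c("MS", "AS", "LS", "EDU", "EL", "sMRI", "dMRI", "fMRI")
  abort_if(!all(blocks %in% valid), "unknown block name in model spec '%s'", name)
  structure(list(name = name, blocks = blocks, expected = expected),
            class = "model_spec")
}

#' Catalog of the study's model specifications
#'
#' The seven imaging assemblies (sMRI 157, dMRI 432, fMRI 1485, and their
#' combinations up to full MRI 2074 at the default layout), the five
#' single-block sociodemographic models, all sociodemographic (86), and the
#' combined full model (2160). Expected counts refer to the default layout.
#'
#' @return Named list of `model_spec` objects.
#' @export
model_catalog <- function() {
  socio <- c("MS", "AS", "LS", "EDU", "EL")
  specs <- list(
    model_spec("sMRI", "sMRI", 157),
    model_spec("dMRI", "dMRI", 432),
    model_spec("fMRI", "fMRI", 1485),
    model_spec("sMRI_dMRI", c("sMRI", "dMRI"), 589),
    model_spec("sMRI_fMRI", c("sMRI", "fMRI"), 1642),
    model_spec("dMRI_fMRI", c("dMRI", "fMRI"), 1917),
    model_spec("full_mri", c("sMRI", "dMRI", "fMRI"), 2074),
    model_spec("MS", "MS", 25),
    model_spec("AS", "AS", 5),
    model_spec("LS", "LS", 45),
    model_spec("EDU", "EDU", 2),
    model_spec("EL", "EL", 9),
    model_spec("all_socio", socio, 86),
    model_spec("combined", c(socio, "sMRI", "dMRI", "fMRI"), 2160))
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Assemble a model-ready feature matrix
#'
#' Concatenates the member blocks column-wise in declared order. When the
#' prediction target is age, the age/sex (AS) block is removed from
#' sociodemographic assemblies so the model cannot read its own target. The
#' assembled width is checked against the spec's expected count (adjusted
#' for the AS removal) when the cohort carries no imputation indicators.
#'
#' @param spec A [model_spec()].
#' @param cohort A `cohort_table` (imputed if it had missing values).
#' @param connectivity Optional matrix of tangent connectivity vectors with
#'   rownames = subject ids (required when the spec includes `fMRI`).
#' @param target Optional target name; `"age"` triggers the AS removal.
#' @return Numeric matrix, rows aligned to cohort subjects (rownames =
#'   subject ids).
#' @export
assemble_model_matrix <- function(spec, cohort, connectivity = NULL, target = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(cohort, "cohort_table"))
  blocks <- spec$blocks
  dropped_as <- FALSE
  if (identical(target, "age") && "AS" %in% blocks && length(setdiff(blocks, "fMRI")) > 0) {
    blocks <- setdiff(blocks, "AS")
    dropped_as <- TRUE
  }
  parts <- list()
  for (b in blocks) {
    if (b == "fMRI") {
      abort_if(is.null(connectivity), "spec '%s' needs connectivity vectors", spec$name)
      idx <- match(cohort$data$subject_id, rownames(connectivity))
      abort_if(anyNA(idx), "connectivity vectors missing for some subjects")
      parts[[b]] <- connectivity[idx, , drop = FALSE]
    } else {
      cols <- block_columns(cohort, b)
      abort_if(length(cols) == 0, "block '%s' has no columns in the cohort", b)
      parts[[b]] <- as.matrix(cohort$data[cols])
    }
  }
  out <- do.call(cbind, parts)
  rownames(out) <- cohort$data$subject_id
  has_indicators <- any(grepl("_imputed$", names(cohort$blocks)))
  if (!is.null(spec$expected) && !has_indicators) {
    expected <- spec$expected
    if (dropped_as) expected <- expected - length(block_columns(cohort, "AS"))
    abort_if(ncol(out) != expected,
             "assembled width %d != expected %d for spec '%s'",
             ncol(out), expected, spec$name)
  }
  out
}

#' Block intercorrelation structure of the sociodemographic variables
#'
#' Applies a per-column Yeo-Johnson power transform (maximum-likelihood
#' lambda) to symmetrize the marginals, then computes all pairwise Pearson
#' correlations and summarizes mean within- versus between-block absolute
#' correlation. Constant columns are excluded with a warning.
#'
#' @param cohort A `cohort_table`.
#' @param blocks Block labels to include (default: the five sociodemographic
#'   blocks).
#' @return List with `correlation` (matrix), `lambda` (fitted transform
#'   parameters), `within`, `between` (mean absolute correlations), and
#'   `excluded` (constant columns dropped).
#' @export
block_intercorrelation <- function(cohort, blocks = socio_blocks) {
  stopifnot(inherits(cohort, "cohort_table"))
  cols <- block_columns(cohort, blocks)
  abort_if(length(cols) < 2, "need at least 2 columns")
  keep <- character(0); excluded <- character(0)
  lambda <- numeric(0)
  tx <- list()
  for (col in cols) {
    x <- cohort$data[[col]]
    x <- x[!is.na(x)]
    if (stats::sd(x) == 0 || length(unique(x)) < 2) {
      excluded <- c(excluded, col)
      next
    }
    lam <- tryCatch(
      as.numeric(stats::coef(car::powerTransform(cohort$data[[col]],
                                                 family = "yjPower"))),
      error = function(e) 1)
    lambda[col] <- lam
    tx[[col]] <- car::yjPower(cohort$data[[col]], lam)
    keep <- c(keep, col)
  }
  if (length(excluded)) {
    warning(sprintf("excluded constant column(s): %s",
                    paste(excluded, collapse = ", ")), call. = FALSE)
  }
  M <- do.call(cbind, tx)
  colnames(M) <- keep
  R <- stats::cor(M, use = "pairwise.complete.obs")
  lab <- cohort$blocks[keep]
  same <- outer(lab, lab, `==`)
  off <- !diag(TRUE, length(keep))
  list(correlation = R, lambda = lambda,
       within = mean(abs(R[same & off])),
       between = mean(abs(R[!same])),
       excluded = excluded)
}
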