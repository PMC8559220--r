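#' Cohort table container
#'
#' A `cohort_table` bundles the per-subject data frame with the metadata the
#' pipeline needs: which columns belong to which sociodemographic or imaging
#' block, which columns are targets (never masked), which are health habits,
#' and which make up the alcohol family feeding the compound drinking score.
#'
#' @param data Data frame with a `subject_id` column.
#' @param blocks Named character vector mapping feature column names to a
#'   block label in `MS`, `AS`, `LS`, `EDU`, `EL`, `sMRI`, `dMRI`.
#' @param target_cols Character vector of target column names.
#' @param habit_cols Character vector of habit column names.
#' @param alcohol_cols Character vector (length 6) of alcohol-family columns.
#' @param seeds Optional named integer vector of per-stage child seeds.
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(data, blocks,
                         target_cols = c("age", "fluid_intelligence", "neuroticism"),
                         habit_cols = c("drinks_per_week", "met_minutes",
                                        "pack_years", "sleep_hours"),
                         alcohol_cols = character(),
                         seeds = NULL) {
  stopifnot(is.data.frame(data), "subject_id" %in% names(data))
  abort_if(anyDuplicated(data$subject_id) > 0, "subject_id values must be unique")
  abort_if(!all(names(blocks) %in% names(data)),
           "blocks refer to columns absent from data")
  valid <- c("MS", "AS", "LS", "EDU", "EL", "sMRI", "dMRI", "fMRI")
  abort_if(!all(blocks %in% valid), "unknown block label in blocks")
  abort_if(!all(target_cols %in% names(data)), "missing target column(s)")
  abort_if(anyNA(data[target_cols]), "target columns must not contain missing values")
  structure(
    list(data = data, blocks = blocks, target_cols = target_cols,
         habit_cols = intersect(habit_cols, names(data)),
         alcohol_cols = alcohol_cols, seeds = seeds),
    class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d subjects, %d block-tagged columns\n",
              nrow(x$data), length(x$blocks)))
  tb <- table(factor(x$blocks, levels = unique(x$blocks)))
  cat("  blocks:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  cat("  targets:", paste(x$target_cols, collapse = ", "), "\n")
  cat("  habits: ", paste(x$habit_cols, collapse = ", "), "\n")
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort A `cohort_table`.
#' @return Integer count.
#' @export
n_subjects <- function(cohort) nrow(cohort$data)

#' Feature columns belonging to given blocks
#' @param cohort A `cohort_table`.
#' @param blocks Character vector of block labels.
#' @return Character vector of column names in block order.
#' @export
block_columns <- function(cohort, blocks) {
  unlist(lapply(blocks, function(b) names(cohort$blocks)[cohort$blocks == b]),
         use.names = FALSE)
}

#' Write a cohort to CSV with a JSON sidecar
#'
#' The CSV encodes a missing cell as an empty string; the sidecar declares
#' block membership, target/habit columns, and the mask encoding so the table
#' round-trips exactly.
#'
#' @param cohort A `cohort_table`.
#' @param path CSV path; the sidecar is written next to it as `<path>.json`.
#' @return Invisibly, the two paths written.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort$data, path, row.names = FALSE, na = "")
  side <- list(blocks = as.list(cohort$blocks),
               target_cols = cohort$target_cols,
               habit_cols = cohort$habit_cols,
               alcohol_cols = cohort$alcohol_cols,
               seeds = as.list(cohort$seeds),
               mask_encoding = "empty cell = missing")
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(c(path, paste0(path, ".json")))
}

#' Read a cohort written by [write_cohort()]
#' @param path CSV path (sidecar expected at `<path>.json`).
#' @return A `cohort_table`.
#' @export
read_cohort <- function(path) {
  data <- utils::read.csv(path, na.strings = "", check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  seeds <- side$seeds
  if (length(seeds)) seeds <- stats::setNames(as.integer(unlist(seeds)), names(seeds))
  cohort_table(data, blocks = unlist(side$blocks),
               target_cols = side$target_cols,
               habit_cols = side$habit_cols,
               alcohol_cols = side$alcohol_cols %||% character(),
               seeds = seeds)
}
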