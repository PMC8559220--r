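#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: sociodemographic variables organized in five intercorrelated
#' blocks (mood/sentiment MS, age/sex AS, lifestyle LS, education EDU,
#' early-life EL), structural and diffusion image-derived phenotypes, latent
#' component time series whose covariance carries target signal, habits that
#' are linear functions of the standardized targets, and (optionally)
#' lifestyle-linked missingness.
#'
#' @param n_subjects Positive integer, cohort size.
#' @param seed Integer global seed; per-stage child seeds are spawned from it.
#' @param block_sizes Named integer vector of column counts per block. The
#'   defaults mirror the study layout: MS=25, AS=5, LS=45, EDU=2, EL=9
#'   (86 sociodemographic variables in total), sMRI=157, dMRI=432.
#' @param n_components Number of latent signal components in the per-subject
#'   time series (default 55, giving 55*54/2 = 1485 connectivity features).
#' @param series_length Time points per subject series.
#' @param target_effects Named list: target -> named vector of per-block
#'   standardized signal strengths (block `fMRI` modulates the component
#'   covariance).
#' @param habit_effects Named list: habit -> length-3 numeric coefficients on
#'   the z-scored (age, fluid_intelligence, neuroticism).
#' @param noise_sd Positive residual standard deviation for features/habits.
#' @param missing_rate Fraction of maskable cells set missing in [0, 1).
#' @param age_range,age_mean,age_sd Age distribution: truncated normal.
#' @return An object of class `generative_config`.
#' @export
generative_config <- function(n_subjects,
                              seed = 1L,
                              block_sizes = c(MS = 25, AS = 5, LS = 45,
                                              EDU = 2, EL = 9,
                                              sMRI = 157, dMRI = 432),
                              n_components = 55,
                              series_length = 150,
                              target_effects = default_target_effects(),
                              habit_effects = default_habit_effects(),
                              noise_sd = 1,
                              missing_rate = 0,
                              age_range = c(40, 70),
                              age_mean = 55,
                              age_sd = 7.5) {
  abort_if(!is_count(n_subjects), "n_subjects must be a positive integer")
  abort_if(any(block_sizes <= 0), "block sizes must be positive")
  abort_if(length(block_sizes) == 0 || sum(block_sizes) == 0,
           "block_sizes must not sum to 0")
  abort_if(!is_count(n_components), "n_components must be a positive integer")
  abort_if(!is_count(series_length), "series_length must be a positive integer")
  abort_if(!(missing_rate >= 0 && missing_rate < 1), "missing_rate must be in [0, 1)")
  abort_if(noise_sd <= 0, "noise_sd must be positive")
  abort_if(!all(is.finite(unlist(habit_effects))), "habit_effects must be finite")
  structure(
    list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
         block_sizes = block_sizes, n_components = as.integer(n_components),
         series_length = as.integer(series_length),
         target_effects = target_effects, habit_effects = habit_effects,
         noise_sd = noise_sd, missing_rate = missing_rate,
         age_range = age_range, age_mean = age_mean, age_sd = age_sd),
    class = "generative_config")
}

#' Default per-block target signal strengths
#'
#' Age carries strong signal in the imaging blocks and in the age/sex block
#' (which contains age itself in the real layout); fluid intelligence loads
#' on education, mood, and imaging; neuroticism on mood/sentiment and
#' lifestyle. Standardized units.
#' @return Named list of named numeric vectors.
#' @export
default_target_effects <- function() {
  list(age = c(AS = 0.6, sMRI = 0.6, dMRI = 0.5, fMRI = 0.5),
       fluid_intelligence = c(MS = 0.25, EDU = 0.5, sMRI = 0.3, fMRI = 0.25),
       neuroticism = c(MS = 0.5, LS = 0.25, sMRI = 0.2))
}

#' Default habit coefficients on the standardized targets
#'
#' Coefficients on z-scored (age, fluid intelligence, neuroticism); positive
#' age effects on drinking and smoking exposure, negative on activity.
#' @return Named list of length-3 numeric vectors.
#' @export
default_habit_effects <- function() {
  list(drinks_per_week = c(0.3, -0.1, 0.1),
       met_minutes = c(-0.2, 0.1, -0.15),
       pack_years = c(0.3, -0.2, 0.2),
       sleep_hours = c(0.15, 0.05, -0.1))
}

socio_blocks <- c("MS", "AS", "LS", "EDU", "EL")

## affine natural-unit encodings of the standardized habit scores
habit_scales <- function() {
  list(drinks_per_week = c(offset = 8, scale = 5),
       met_minutes = c(offset = 1200, scale = 600),
       pack_years = c(offset = 10, scale = 8),
       sleep_hours = c(offset = 7, scale = 0.9))
}

stage_names <- c("targets", "features", "habits", "missing", "covariance", "series")

#' Generate a synthetic cohort with recorded ground truth
#'
#' Targets are drawn first (age from a truncated normal; integer scores by
#' quantile-binning latent Gaussians into the documented 0-13 and 0-12
#' ranges). Each feature block mixes a shared within-block latent factor,
#' per-target standardized signal, and Gaussian noise. Habits are affine
#' transforms of linear combinations of the z-scored targets plus noise; the
#' drinking habit is decomposed into six alcohol-family columns whose row sum
#' reproduces it exactly. Deterministic given the seed.
#'
#' @param config A [generative_config()].
#' @return List with elements `cohort` (a [cohort_table()]) and `truth`
#'   (a `synthetic_truth` list mirroring every value used in generation).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generative_config"))
  n <- config$n_subjects
  seeds <- spawn_seeds(config$seed, stage_names)

  ## -- targets ----------------------------------------------------------
  set.seed(seeds[["targets"]])
  lo <- stats::pnorm(config$age_range[1], config$age_mean, config$age_sd)
  hi <- stats::pnorm(config$age_range[2], config$age_mean, config$age_sd)
  age <- stats::qnorm(stats::runif(n, lo, hi), config$age_mean, config$age_sd)
  z_fi_lat <- stats::rnorm(n)
  z_n_lat <- stats::rnorm(n)
  fluid_intelligence <- pmin(floor(stats::pnorm(z_fi_lat) * 14), 13L)
  neuroticism <- pmin(floor(stats::pnorm(z_n_lat) * 13), 12L)
  zt <- cbind(age = safe_scale(age),
              fluid_intelligence = safe_scale(fluid_intelligence),
              neuroticism = safe_scale(neuroticism))

  ## -- block features ---------------------------------------------------
  set.seed(seeds[["features"]])
  block_loading <- 0.7
  feats <- list()
  blocks <- character()
  for (b in names(config$block_sizes)) {
    k <- config$block_sizes[[b]]
    f_b <- stats::rnorm(n)
    sig <- rep(0, n)
    for (t in colnames(zt)) {
      e <- config$target_effects[[t]][b]
      if (!is.na(e) && length(e)) sig <- sig + e * zt[, t]
    }
    m <- block_loading * f_b + sig +
      matrix(stats::rnorm(n * k, sd = config$noise_sd), n, k)
    cols <- sprintf("%s_%02d", b, seq_len(k))
    colnames(m) <- cols
    feats[[b]] <- m
    blocks <- c(blocks, stats::setNames(rep(b, k), cols))
  }

  ## -- habits -----------------------------------------------------------
  set.seed(seeds[["habits"]])
  scales <- habit_scales()
  habits <- list()
  for (h in names(config$habit_effects)) {
    beta <- config$habit_effects[[h]]
    z <- as.numeric(zt %*% beta) + stats::rnorm(n, sd = config$noise_sd)
    sc <- scales[[h]] %||% c(offset = 0, scale = 1)
    habits[[h]] <- sc[["offset"]] + sc[["scale"]] * z
  }
  ## six alcohol-family columns summing exactly to the drinking habit
  aw <- c(0.35, 0.20, 0.25, 0.10, 0.05, 0.05)
  alcohol_cols <- sprintf("alcohol_%d", 1:6)
  drinks <- habits$drinks_per_week %||% rep(0, n)
  alc <- matrix(0, n, 6, dimnames = list(NULL, alcohol_cols))
  for (k in 1:5) alc[, k] <- aw[k] * drinks + stats::rnorm(n, sd = 0.3)
  alc[, 6] <- drinks - rowSums(alc[, 1:5, drop = FALSE])

  data <- data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                     do.call(cbind, feats),
                     age = age, fluid_intelligence = fluid_intelligence,
                     neuroticism = neuroticism,
                     as.data.frame(habits), alc, check.names = FALSE)

  cohort <- cohort_table(data, blocks,
                         habit_cols = names(config$habit_effects),
                         alcohol_cols = alcohol_cols, seeds = seeds)
  truth <- structure(
    list(seed = config$seed, child_seeds = as.list(seeds),
         target_effects = config$target_effects,
         habit_effects = config$habit_effects,
         habit_scales = scales[names(config$habit_effects)],
         block_loading = block_loading, noise_sd = config$noise_sd,
         z_targets = zt, alcohol_weights = aw),
    class = "synthetic_truth")

  if (config$missing_rate > 0) {
    cohort <- inject_missingness(cohort, config$missing_rate,
                                 mechanism = "MAR-on-lifestyle",
                                 seed = seeds[["missing"]])
  }
  list(cohort = cohort, truth = truth)
}

#' Generate per-subject latent component time series
#'
#' Each subject's series is drawn from a zero-mean multivariate normal whose
#' covariance interpolates in log-eigenvalue space between a shared base SPD
#' matrix and a target-modulated perturbation: with base eigendecomposition
#' `Q diag(lambda) Q'`, subject i receives `Q diag(lambda * exp(m_i g)) Q'`
#' where `m_i` is the subject's standardized target signal scaled by the
#' `fMRI` entries of `target_effects`. Covariances are SPD by construction.
#'
#' @param cohort A `cohort_table` generated from the same config/seed lineage.
#' @param config The [generative_config()] used to generate the cohort.
#' @param base_covariance Optional user-supplied base SPD matrix
#'   (`n_components` square); rejected if not symmetric positive definite.
#' @return An object of class `component_series`: list with `series` (list of
#'   `series_length` x `n_components` matrices named by subject id),
#'   `covariances` (the generating SPD matrices), `base`, and `modulation`.
#' @export
generate_component_timeseries <- function(cohort, config, base_covariance = NULL) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(config, "generative_config"))
  n <- n_subjects(cohort)
  p <- config$n_components
  T_ <- config$series_length
  if (T_ < p + 1) {
    warning("series_length < n_components + 1; shrinkage covariance remains valid",
            call. = FALSE)
  }
  seeds <- cohort$seeds %||% spawn_seeds(config$seed, stage_names)

  set.seed(seeds[["covariance"]])
  if (is.null(base_covariance)) {
    Q <- qr.Q(qr(matrix(stats::rnorm(p * p), p, p)))
    lambda <- sort(exp(stats::rnorm(p, 0, 0.4)), decreasing = TRUE)
  } else {
    abort_if(!isSymmetric(base_covariance, tol = 1e-8) ||
               min(eigen(base_covariance, symmetric = TRUE,
                         only.values = TRUE)$values) <= 0,
             "base_covariance must be symmetric positive definite")
    eg <- eigen((base_covariance + t(base_covariance)) / 2, symmetric = TRUE)
    Q <- eg$vectors
    lambda <- eg$values
  }
  g <- stats::rnorm(p, 0, 0.5)

  zt <- cbind(age = safe_scale(cohort$data$age),
              fluid_intelligence = safe_scale(cohort$data$fluid_intelligence),
              neuroticism = safe_scale(cohort$data$neuroticism))
  m <- rep(0, n)
  for (t in colnames(zt)) {
    e <- config$target_effects[[t]]["fMRI"]
    if (!is.na(e) && length(e)) m <- m + e * zt[, t]
  }

  set.seed(seeds[["series"]])
  series <- vector("list", n)
  covs <- vector("list", n)
  for (i in seq_len(n)) {
    d <- lambda * exp(m[i] * g)
    sigma <- Q %*% (d * t(Q))
    sigma <- (sigma + t(sigma)) / 2
    U <- chol(sigma)
    series[[i]] <- matrix(stats::rnorm(T_ * p), T_, p) %*% U
    covs[[i]] <- sigma
  }
  names(series) <- names(covs) <- cohort$data$subject_id
  structure(list(series = series, covariances = covs,
                 base = Q %*% (lambda * t(Q)), eigvecs = Q, eigvals = lambda,
                 log_direction = g, modulation = m),
            class = "component_series")
}

#' Inject missingness into maskable cohort cells
#'
#' Under `MCAR` every maskable cell is masked independently at `rate`. Under
#' `MAR-on-lifestyle` the per-subject masking probability is a logistic
#' function of the first lifestyle (LS) column, with the intercept calibrated
#' so the marginal rate matches `rate`; the driving column itself and all
#' target columns are never masked.
#'
#' @param cohort A `cohort_table`.
#' @param rate Missingness rate in [0, 1).
#' @param mechanism `"MCAR"` or `"MAR-on-lifestyle"`.
#' @param seed Integer seed (defaults to the cohort's `missing` child seed).
#' @return The cohort with `NA` cells injected.
#' @export
inject_missingness <- function(cohort, rate,
                               mechanism = c("MCAR", "MAR-on-lifestyle"),
                               seed = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  abort_if(!(rate >= 0 && rate < 1), "rate must be in [0, 1)")
  mechanism <- match.arg(mechanism)
  if (rate == 0) return(cohort)
  seed <- seed %||% cohort$seeds[["missing"]] %||% 1L
  set.seed(seed)

  maskable <- c(names(cohort$blocks), cohort$habit_cols, cohort$alcohol_cols)
  driver <- block_columns(cohort, "LS")[1]
  if (mechanism == "MAR-on-lifestyle") {
    abort_if(is.na(driver) || is.null(driver),
             "MAR-on-lifestyle requires at least one LS column")
    maskable <- setdiff(maskable, driver)
    z <- safe_scale(cohort$data[[driver]])
    a <- stats::uniroot(function(a) mean(stats::plogis(a + z)) - rate,
                        c(-30, 30))$root
    p_subj <- stats::plogis(a + z)
  } else {
    p_subj <- rep(rate, n_subjects(cohort))
  }
  for (col in maskable) {
    hit <- stats::runif(n_subjects(cohort)) < p_subj
    cohort$data[[col]][hit] <- NA
  }
  cohort
}

#' Compound drinking score
#'
#' Row-wise sum of the six alcohol-family columns. Missing components are
#' treated as 0 before summing; rows with any missing component are flagged
#' in the `"flagged"` attribute so the missingness information is preserved.
#'
#' @param cohort A `cohort_table` with its alcohol-family columns present.
#' @return Numeric vector of per-subject scores with a logical `"flagged"`
#'   attribute.
#' @export
compound_drinking_score <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  abort_if(length(cohort$alcohol_cols) == 0 ||
             !all(cohort$alcohol_cols %in% names(cohort$data)),
           "alcohol-family columns are missing from the cohort")
  m <- as.matrix(cohort$data[cohort$alcohol_cols])
  flagged <- rowSums(is.na(m)) > 0
  m[is.na(m)] <- 0
  structure(rowSums(m), flagged = flagged)
}

#' Serialize synthetic ground truth to JSON
#' @param truth A `synthetic_truth` object.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  x <- unclass(truth)
  x$z_targets <- NULL  # derivable from seed; keep the JSON compact
  # named vectors must serialize as objects so names round-trip
  x$target_effects <- lapply(x$target_effects, as.list)
  x$habit_effects <- lapply(x$habit_effects, as.list)
  x$habit_scales <- lapply(x$habit_scales, as.list)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read synthetic ground truth written by [write_truth()]
#' @param path JSON path.
#' @return A `synthetic_truth` object (without the derivable z-target matrix).
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$child_seeds <- lapply(x$child_seeds, as.integer)
  x$target_effects <- lapply(x$target_effects, unlist)
  x$habit_effects <- lapply(x$habit_effects, unlist)
  x$habit_scales <- lapply(x$habit_scales, unlist)
  structure(x, class = "synthetic_truth")
}
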