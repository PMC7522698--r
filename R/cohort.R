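#' Configuration for a synthetic GC-MS-like case-control cohort
#'
#' Describes the statistical structure of a simulated serum-metabolome
#' cohort: sample sizes, number of detected peaks, how many peaks carry a
#' case/control signal and how strong it is, the log-scale intensity
#' distribution, random missingness, and a set of peaks engineered to fall
#' below the presence filter (emulating peaks too inconsistently detected
#' to be retained).
#'
#' The defaults mirror a screening-study training cohort: 50 cases vs 70
#' controls, 293 detected peaks of which 25 are low-presence (so 268
#' survive a 75% presence filter), log-normal intensities, and a class
#' signal spread over 20 peaks strong enough that well-tuned classifiers
#' separate the classes almost perfectly.
#'
#' @param n_cases,n_controls cohort sizes.
#' @param n_features number of detected peaks.
#' @param n_informative peaks carrying the class signal.
#' @param effect_size standardized mean shift (log scale, in units of
#'   `base_log_sd`) applied to cases on each informative peak.
#' @param base_log_mean,base_log_sd mean and sd of log intensity.
#' @param missing_rate probability a cell is missing at random, in `[0, 1)`.
#' @param low_presence_features peaks whose observed presence is forced
#'   below 0.75 (never overlapping the informative peaks).
#' @param missing_mechanism `"mcar"` (completely at random, default) or
#'   `"censor"` (the lowest `missing_rate` fraction of each peak's values
#'   is dropped, emulating concentrations below the detection limit).
#' @param block_size,block_rho optional equicorrelated feature blocks on the
#'   log scale; `block_rho = 0` (default) gives independent features.
#' @param seed integer seed; generation is fully reproducible.
#'
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_cases = 50, n_controls = 70,
                          n_features = 293, n_informative = 20,
                          effect_size = 2.5,
                          base_log_mean = 10, base_log_sd = 1,
                          missing_rate = 0.05,
                          low_presence_features = 25,
                          missing_mechanism = c("mcar", "censor"),
                          block_size = 1, block_rho = 0,
                          seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  check_that(is_count(n_cases), "n_cases", "must be a non-negative integer")
  check_that(is_count(n_controls), "n_controls", "must be a non-negative integer")
  check_that(is_count(n_features) && n_features >= 1, "n_features",
             "must be a positive integer")
  check_that(is_count(n_informative), "n_informative",
             "must be a non-negative integer")
  check_that(n_informative <= n_features, "n_informative",
             "cannot exceed n_features")
  check_that(is_count(low_presence_features), "low_presence_features",
             "must be a non-negative integer")
  check_that(low_presence_features <= n_features - n_informative,
             "low_presence_features",
             "cannot exceed n_features - n_informative")
  check_that(is.numeric(effect_size) && effect_size >= 0, "effect_size",
             "must be >= 0")
  check_that(is.numeric(base_log_mean) && is.finite(base_log_mean),
             "base_log_mean", "must be finite")
  check_that(is.numeric(base_log_sd) && base_log_sd > 0, "base_log_sd",
             "must be > 0")
  check_that(is.numeric(missing_rate) && missing_rate >= 0 && missing_rate < 1,
             "missing_rate", "must lie in [0, 1)")
  check_that(is_count(block_size) && block_size >= 1, "block_size",
             "must be a positive integer")
  check_that(is.numeric(block_rho) && block_rho >= 0 && block_rho < 1,
             "block_rho", "must lie in [0, 1)")
  check_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
             "seed", "must be a single number")
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size,
                 base_log_mean = base_log_mean,
                 base_log_sd = base_log_sd,
                 missing_rate = missing_rate,
                 low_presence_features = as.integer(low_presence_features),
                 missing_mechanism = missing_mechanism,
                 block_size = as.integer(block_size),
                 block_rho = block_rho,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a labeled synthetic cohort
#'
#' Draws a samples x peaks intensity table from the model in
#' [cohort_config()]. Log intensities are normal with mean
#' `base_log_mean` (controls) or `base_log_mean + effect_size * base_log_sd`
#' (cases, informative peaks only) and sd `base_log_sd`, then
#' exponentiated, so intensities are positive and right-skewed as GC-MS
#' peak areas are. Informative peaks occupy the first `n_informative`
#' columns; low-presence peaks the last `low_presence_features` columns.
#' Each peak uses its own deterministic random sub-stream, so adding peaks
#' never changes earlier columns.
#'
#' Low-presence peaks get an exact observed count `floor(p * n)` with
#' `p` drawn uniformly in `[0.40, 0.70]`, guaranteeing presence < 0.75.
#'
#' @param config a [cohort_config()].
#' @return A [feature_table()] with labels `"EC"` / `"control"`; cases
#'   first. Feature ids are `M001...`; informative peaks additionally carry
#'   the attribute `informative_features`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_cases + config$n_controls
  check_that(n > 0, "n_cases", "cohort must contain at least one sample")
  p <- config$n_features
  is_case <- c(rep(TRUE, config$n_cases), rep(FALSE, config$n_controls))
  shift <- config$effect_size * config$base_log_sd

  width <- max(3, nchar(as.character(p)))
  fid <- sprintf(paste0("M%0", width, "d"), seq_len(p))
  sid <- c(sprintf("EC%04d", seq_len(config$n_cases)),
           sprintf("CT%04d", seq_len(config$n_controls)))

  informative <- seq_len(config$n_informative)
  low_presence <- if (config$low_presence_features > 0)
    seq(p - config$low_presence_features + 1L, p) else integer(0)

  # Optional equicorrelated blocks: a shared standard-normal factor per
  # block, drawn from block-indexed sub-streams.
  rho <- config$block_rho
  block_of <- ((seq_len(p) - 1L) %/% config$block_size) + 1L
  block_factor <- NULL
  if (rho > 0) {
    block_factor <- vapply(unique(block_of), function(b) {
      with_seed(substream_seed(config$seed, p + b), stats::rnorm(n))
    }, numeric(n))
    colnames(block_factor) <- as.character(unique(block_of))
  }

  mat <- matrix(NA_real_, n, p, dimnames = list(sid, fid))
  for (j in seq_len(p)) {
    col <- with_seed(substream_seed(config$seed, j), {
      z <- stats::rnorm(n)
      if (rho > 0) {
        z <- sqrt(rho) * block_factor[, as.character(block_of[j])] +
          sqrt(1 - rho) * z
      }
      logx <- config$base_log_mean + config$base_log_sd * z
      if (j %in% informative) logx <- logx + shift * is_case
      x <- exp(logx)
      if (j %in% low_presence) {
        pres <- stats::runif(1, 0.40, 0.70)
        drop <- sample.int(n, n - floor(pres * n))
        x[drop] <- NA_real_
      } else if (config$missing_rate > 0) {
        if (config$missing_mechanism == "mcar") {
          x[stats::runif(n) < config$missing_rate] <- NA_real_
        } else {
          x[x <= stats::quantile(x, config$missing_rate)] <- NA_real_
        }
      }
      x
    })
    mat[, j] <- col
  }

  out <- feature_table(mat, ifelse(is_case, "EC", "control"))
  attr(out, "informative_features") <- fid[informative]
  attr(out, "low_presence_features") <- fid[low_presence]
  out
}

#' Smoking load in pack-years
#'
#' Mean cigarettes per day times years of active smoking, divided by 20
#' (the number of cigarettes in a pack).
#'
#' @param cigarettes_per_day,years_smoking non-negative reals (vectorized).
#' @return pack-years, same length as the inputs.
#' @export
#' @examples
#' pack_years(20, 30) # one pack a day for 30 years -> 30
pack_years <- function(cigarettes_per_day, years_smoking) {
  check_that(is.numeric(cigarettes_per_day) && all(cigarettes_per_day >= 0),
             "cigarettes_per_day", "must be >= 0")
  check_that(is.numeric(years_smoking) && all(years_smoking >= 0),
             "years_smoking", "must be >= 0")
  cigarettes_per_day * years_smoking / 20
}

#' NCCN smoke-related risk class
#'
#' Stratifies smoke-related risk into four classes, evaluated
#' most-severe-first:
#' \itemize{
#'   \item `very_high`: age >= 55 and >= 30 pack-years of active smoking,
#'     unless the individual quit more than 15 years ago;
#'   \item `high`: age >= 50 and >= 20 pack-years of active smoking with
#'     another risk factor (other than passive smoking);
#'   \item `moderate`: age >= 50 and >= 20 pack-years (active or secondary)
#'     without other risk factors;
#'   \item `low`: otherwise (younger than 50 or fewer than 20 pack-years).
#' }
#'
#' @param age age in years.
#' @param pack_years smoking load, see [pack_years()].
#' @param active currently smoking?
#' @param other_risk_factor another risk factor present (passive smoking
#'   does not count)?
#' @param years_since_quit years since quitting; 0 for current smokers.
#' @return factor with ordered levels `low < moderate < high < very_high`.
#' @export
smoke_risk_class <- function(age, pack_years, active = FALSE,
                             other_risk_factor = FALSE,
                             years_since_quit = 0) {
  n <- max(length(age), length(pack_years), length(active),
           length(other_risk_factor), length(years_since_quit))
  age <- rep_len(age, n); pack_years <- rep_len(pack_years, n)
  active <- rep_len(as.logical(active), n)
  other_risk_factor <- rep_len(as.logical(other_risk_factor), n)
  years_since_quit <- rep_len(years_since_quit, n)
  check_that(all(age >= 0), "age", "must be >= 0")
  check_that(all(pack_years >= 0), "pack_years", "must be >= 0")
  check_that(all(years_since_quit >= 0), "years_since_quit", "must be >= 0")

  quit_long_ago <- !active & years_since_quit > 15
  cls <- rep("low", n)
  cls[age >= 50 & pack_years >= 20] <- "moderate"
  cls[age >= 50 & pack_years >= 20 & active & other_risk_factor] <- "high"
  cls[age >= 55 & pack_years >= 30 & !quit_long_ago] <- "very_high"
  factor(cls, levels = c("low", "moderate", "high", "very_high"),
         ordered = TRUE)
}

#' Simulate demographic covariates for a screening cohort
#'
#' Generates age and smoking-history covariates typical of a postmenopausal
#' screening population (ages 50-80, about a quarter current smokers),
#' independent of the metabolome. Useful for exercising [pack_years()] and
#' [smoke_risk_class()] at cohort scale.
#'
#' @param n number of participants.
#' @param seed integer seed.
#' @return data.frame with columns `age`, `smoking_status`,
#'   `cigarettes_per_day`, `years_smoking`, `years_since_quit`,
#'   `other_risk_factor`, `pack_years`, `risk_class`.
#' @export
generate_demographics <- function(n, seed = 1L) {
  check_that(is_count(n) && n > 0, "n", "must be a positive integer")
  with_seed(seed, {
    age <- pmin(pmax(round(stats::rnorm(n, 59.7, 7.7)), 50), 80)
    status <- sample(c("current", "never", "former"), n, replace = TRUE,
                     prob = c(0.244, 0.581, 0.175))
    smoker <- status != "never"
    cpd <- ifelse(smoker, pmax(1, round(stats::rlnorm(n, log(10), 0.6))), 0)
    start_age <- round(stats::runif(n, 16, 30))
    quit <- ifelse(status == "former", round(stats::runif(n, 1, 25)), 0)
    years <- ifelse(smoker, pmax(1, age - start_age - quit), 0)
    other <- stats::runif(n) < 0.15
    py <- pack_years(cpd, years)
    data.frame(age = age, smoking_status = status,
               cigarettes_per_day = cpd, years_smoking = years,
               years_since_quit = quit, other_risk_factor = other,
               pack_years = py,
               risk_class = smoke_risk_class(age, py,
                                             active = status == "current",
                                             other_risk_factor = other,
                                             years_since_quit = quit),
               stringsAsFactors = FALSE)
  })
}

#' Write / read a cohort configuration
#'
#' Serialized as YAML or JSON (by file extension) with exactly the
#' `cohort_config` field names.
#'
#' @param config a [cohort_config()].
#' @param path file ending in `.yaml`, `.yml` or `.json`.
#' @return `path` (write) or a `cohort_config` (read).
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  lst <- unclass(config)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  lst <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  do.call(cohort_config, lst)
}
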