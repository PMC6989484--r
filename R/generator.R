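#' Default cognitive test specifications
#'
#' The five tests used to build the general cognitive factor: Stroop
#' color-word interference (seconds; higher = worse), Letter-Digit
#' Substitution Task (correct digits), verbal fluency (animals named),
#' 15-word learning test delayed recall (words), and Purdue pegboard
#' (pins placed). Means and SDs are anchored to the control group of the
#' study population this generator emulates; `loading` is the signed weight
#' of the shared latent cognition factor G on the z-scale (negative for the
#' timed Stroop task, where larger values mean worse performance), and
#' `age_slope` is the mean change in raw test units per year of age.
#'
#' The common |loading| of 0.53 plus the age slopes make the first principal
#' component of the baseline battery explain roughly half of the test
#' variance, the magnitude typical of a general cognitive factor.
#'
#' @return data.frame with columns `name`, `loading`, `age_slope`, `mean`, `sd`.
#' @export
default_test_specs <- function() {
  data.frame(
    name = c("stroop_interference", "ldst", "verbal_fluency",
             "wlt_delayed_recall", "purdue_pegboard"),
    loading = c(-0.53, 0.53, 0.53, 0.53, 0.53),
    age_slope = c(0.50, -0.25, -0.15, -0.08, -0.06),
    mean = c(44.0, 32.2, 23.8, 8.2, 10.9),
    sd = c(13.0, 6.2, 5.7, 2.8, 1.7),
    stringsAsFactors = FALSE
  )
}

#' Default biomarker feature specifications
#'
#' Baseline clinical, genetic, gait and MRI features with their hierarchy
#' category paths. Means/SDs (or prevalences for binary features, median/IQR
#' on the log scale for the white-matter-lesion volume) are anchored to the
#' control group of the emulated population. Age slopes are calibration
#' parameters chosen as plausible ageing rates: for continuous features, raw
#' units per year; for binary features, log-odds per year; for the
#' log-normal lesion volume, log-units per year.
#'
#' @param n_noise_mri number of additional pure-noise MRI features
#'   (`N(0,1)`, no age loading) to append, under category `"mri/noise"`.
#'   Useful for feature-selection experiments.
#' @return data.frame with columns `name`, `category_path`, `is_binary`,
#'   `dist` (one of `"normal"`, `"lognormal"`, `"bernoulli"`, `"ordinal"`),
#'   `mean`, `sd`, `age_slope`, `lower`, `upper` (clamp bounds for ordinal
#'   features), `missing_rate`.
#' @export
default_biomarker_specs <- function(n_noise_mri = 0L) {
  spec <- function(name, path, dist, mean, sd, slope,
                   lower = NA, upper = NA, miss = 0.02) {
    data.frame(name = name, category_path = path, is_binary = dist == "bernoulli",
               dist = dist, mean = mean, sd = sd, age_slope = slope,
               lower = lower, upper = upper, missing_rate = miss,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    spec("education", "education", "ordinal", 3.5, 1.5, -0.02, 1, 7, 0),
    spec("apoe4_carrier", "genetics", "bernoulli", 0.283, NA, 0),
    spec("mmse", "cognitive_tests/mmse", "normal", 28.4, 1.5, -0.03),
    spec("subjective_complaints", "cognitive_tests/subjective_complaints",
         "bernoulli", 0.20, NA, 0.03),
    spec("systolic_bp", "cardiovascular", "normal", 135.9, 19.6, 0.80),
    spec("diastolic_bp", "cardiovascular", "normal", 82.4, 10.6, 0.10),
    spec("bmi", "cardiovascular", "normal", 27.4, 4.1, 0.05),
    spec("total_cholesterol", "cardiovascular", "normal", 5.6, 1.1, 0.010),
    spec("hdl_cholesterol", "cardiovascular", "normal", 1.5, 0.4, 0.002),
    spec("smoking", "cardiovascular", "ordinal", 0.9, 0.75, 0, 0, 2),
    spec("alcohol_glasses_week", "cardiovascular", "lognormal", log(4), 0.9, 0),
    spec("diabetes", "cardiovascular", "bernoulli", 0.092, NA, 0.05),
    spec("bp_lowering_medication", "cardiovascular", "bernoulli", 0.119, NA, 0.08),
    spec("lipid_lowering_medication", "cardiovascular", "bernoulli", 0.213, NA, 0.06),
    spec("gait_pace", "gait", "normal", 0, 1, -0.030, miss = 0.05),
    spec("gait_rhythm", "gait", "normal", 0, 1, -0.010, miss = 0.05),
    spec("intracranial_volume", "mri/tissue_volumes", "normal", 1144, 113, 0, miss = 0.05),
    spec("white_matter_volume", "mri/tissue_volumes", "normal", 419, 57, -1.5, miss = 0.05),
    spec("gray_matter_volume", "mri/tissue_volumes", "normal", 537, 52, -1.3, miss = 0.05),
    spec("csf_volume", "mri/tissue_volumes", "normal", 186, 46, 2.0, miss = 0.05),
    spec("hippocampus_volume", "mri/region_volumes", "normal", 6.8, 0.7, -0.015, miss = 0.05),
    spec("white_matter_lesion_volume", "mri/lesions", "lognormal",
         log(2.4), 0.83, 0.06, miss = 0.05),
    spec("microbleeds", "mri/lesions", "bernoulli", 0.156, NA, 0.07, miss = 0.05),
    spec("lacunar_infarcts", "mri/lesions", "bernoulli", 0.030, NA, 0.06, miss = 0.05),
    spec("global_fa", "mri/diffusion", "normal", 0.30, 0.015, -0.0008, miss = 0.05),
    spec("global_md", "mri/diffusion", "normal", 0.70, 0.03, 0.003, miss = 0.05),
    spec("global_cortical_thickness", "mri/cortical_thickness", "normal",
         2.5, 0.1, -0.004, miss = 0.05)
  )
  n_noise_mri <- as.integer(n_noise_mri)
  if (n_noise_mri > 0L) {
    noise <- do.call(rbind, lapply(seq_len(n_noise_mri), function(i) {
      spec(sprintf("noise_mri_%02d", i), "mri/noise", "normal", 0, 1, 0, miss = 0)
    }))
    out <- rbind(out, noise)
  }
  rownames(out) <- NULL
  out
}

#' Synthetic cohort generator configuration
#'
#' Defines the study conditions the generator emulates: an ageing
#' general-population cohort (age 60.9 +/- 9.1 years on \[45, 95\], 55.6%
#' female, follow-up 5.7 +/- 0.6 years) in which each subject carries a
#' latent annual rate of global cognitive decline
#' `d_i = base - slope * (age_i - age_mean) + noise` (g-units/year), five
#' cognitive tests loading on one latent cognition factor plus that decline,
#' and age-loaded biomarkers. All decline signal is carried by age: given
#' age, biomarkers are independent of the outcome.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param seed integer seed; the same config and seed reproduce the cohort
#'   exactly.
#' @param age_mean,age_sd,age_range truncated-normal age distribution (years).
#' @param female_fraction proportion female in \[0, 1\].
#' @param followup_mean,followup_sd follow-up interval distribution (years),
#'   truncated below at 1 year.
#' @param decline_base mean annual change in g at `age_mean` (g-units/year;
#'   negative = decline).
#' @param decline_slope_per_year_of_age additional decline per year of age
#'   (g-units/year per year).
#' @param decline_noise_sd SD of the subject-specific decline noise
#'   (g-units/year).
#' @param test_specs data.frame as [default_test_specs()].
#' @param biomarker_specs data.frame as [default_biomarker_specs()].
#' @param missing_rates optional named vector of per-feature missingness
#'   proportions overriding the spec defaults (MCAR).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 2542L,
                             seed = 1L,
                             age_mean = 60.9,
                             age_sd = 9.1,
                             age_range = c(45, 95),
                             female_fraction = 0.556,
                             followup_mean = 5.7,
                             followup_sd = 0.6,
                             decline_base = -0.02,
                             decline_slope_per_year_of_age = 0.0045,
                             decline_noise_sd = 0.068,
                             test_specs = default_test_specs(),
                             biomarker_specs = default_biomarker_specs(),
                             missing_rates = NULL) {
  cfg <- list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
              age_mean = age_mean, age_sd = age_sd, age_range = age_range,
              female_fraction = female_fraction,
              followup_mean = followup_mean, followup_sd = followup_sd,
              decline_base = decline_base,
              decline_slope_per_year_of_age = decline_slope_per_year_of_age,
              decline_noise_sd = decline_noise_sd,
              test_specs = as.data.frame(test_specs),
              biomarker_specs = as.data.frame(biomarker_specs),
              missing_rates = missing_rates)
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid generator_config field `", field, "`: ", why, call. = FALSE)
  }
  if (is.na(cfg$n_subjects) || cfg$n_subjects < 2L) fail("n_subjects", "must be >= 2")
  for (f in c("age_sd", "followup_sd")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) fail(f, "must be > 0")
  }
  if (cfg$decline_noise_sd < 0) fail("decline_noise_sd", "must be >= 0")
  if (cfg$female_fraction < 0 || cfg$female_fraction > 1) {
    fail("female_fraction", "must be a proportion in [0, 1]")
  }
  if (length(cfg$age_range) != 2L || cfg$age_range[1] >= cfg$age_range[2]) {
    fail("age_range", "must be an increasing pair of years")
  }
  req_t <- c("name", "loading", "age_slope", "mean", "sd")
  if (!all(req_t %in% names(cfg$test_specs))) {
    fail("test_specs", paste("needs columns", paste(req_t, collapse = ", ")))
  }
  if (any(cfg$test_specs$sd <= 0)) fail("test_specs", "test sds must be > 0")
  if (any(abs(cfg$test_specs$loading) > 1)) {
    fail("test_specs", "loadings are on the z-scale and must lie in [-1, 1]")
  }
  req_b <- c("name", "category_path", "is_binary", "dist", "mean", "sd",
             "age_slope", "missing_rate")
  if (!all(req_b %in% names(cfg$biomarker_specs))) {
    fail("biomarker_specs", paste("needs columns", paste(req_b, collapse = ", ")))
  }
  if (any(cfg$biomarker_specs$missing_rate < 0 | cfg$biomarker_specs$missing_rate > 1)) {
    fail("biomarker_specs", "missing_rate must be in [0, 1]")
  }
  bern <- cfg$biomarker_specs$dist == "bernoulli"
  if (any(cfg$biomarker_specs$mean[bern] < 0 | cfg$biomarker_specs$mean[bern] > 1)) {
    fail("biomarker_specs", "bernoulli means are prevalences in [0, 1]")
  }
  if (any(!is.na(cfg$biomarker_specs$sd) & cfg$biomarker_specs$sd <= 0 & !bern)) {
    fail("biomarker_specs", "sds must be > 0")
  }
  if (!is.null(cfg$missing_rates)) {
    mr <- cfg$missing_rates
    if (is.null(names(mr)) || any(mr < 0 | mr > 1)) {
      fail("missing_rates", "must be a named vector of proportions in [0, 1]")
    }
  }
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic cohort generator config\n")
  cat(sprintf("  n = %d, seed = %d\n", x$n_subjects, x$seed))
  cat(sprintf("  age ~ N(%.1f, %.1f) on [%g, %g]; %.1f%% female; follow-up %.1f +/- %.1f y\n",
              x$age_mean, x$age_sd, x$age_range[1], x$age_range[2],
              100 * x$female_fraction, x$followup_mean, x$followup_sd))
  cat(sprintf("  decline/yr = %.3f - %.4f*(age - %.1f) + N(0, %.3f)\n",
              x$decline_base, x$decline_slope_per_year_of_age,
              x$age_mean, x$decline_noise_sd))
  cat(sprintf("  %d cognitive tests, %d biomarker features\n",
              nrow(x$test_specs), nrow(x$biomarker_specs)))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Draws a cohort under a [generator_config()]: truncated-normal ages,
#' Bernoulli sex, truncated-normal follow-up intervals, a latent cognition
#' factor `G ~ N(0,1)`, the per-subject annual decline
#' `d_i = base - slope*(age_i - age_mean) + noise`, baseline test scores
#' `mean + age_slope*(age - age_mean) + loading*sd*G + sqrt(1-loading^2)*sd*eps`,
#' follow-up test scores `baseline + loading*sd*d_i*followup_years`, and
#' biomarkers with their stated age slopes plus independent noise.
#' Missingness is applied independently per feature (MCAR); age, sex and the
#' test scores are complete by default.
#'
#' @param config a [generator_config()].
#' @param n_subjects,seed optional overrides of the config fields.
#' @return a [cohort_table()]. The latent decline is attached as attribute
#'   `"latent_decline"` and the config as `"generator_config"` for
#'   parameter-recovery checks; neither is used by the analysis itself.
#' @export
generate_cohort <- function(config = generator_config(), n_subjects = NULL,
                            seed = NULL) {
  if (!inherits(config, "generator_config")) {
    stop("`config` must be a generator_config", call. = FALSE)
  }
  if (!is.null(n_subjects)) config$n_subjects <- as.integer(n_subjects)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validate_generator_config(config)
  n <- config$n_subjects

  with_seed(config$seed, {
    age <- rtruncnorm(n, config$age_mean, config$age_sd,
                      config$age_range[1], config$age_range[2])
    sex <- as.numeric(stats::runif(n) < config$female_fraction)
    followup <- rtruncnorm(n, config$followup_mean, config$followup_sd,
                           1, Inf)
    g_latent <- stats::rnorm(n)
    decline <- config$decline_base -
      config$decline_slope_per_year_of_age * (age - config$age_mean) +
      stats::rnorm(n, 0, config$decline_noise_sd)

    ts <- config$test_specs
    baseline_tests <- matrix(NA_real_, n, nrow(ts),
                             dimnames = list(NULL, ts$name))
    followup_tests <- baseline_tests
    for (j in seq_len(nrow(ts))) {
      lam <- ts$loading[j]
      eps <- stats::rnorm(n, 0, sqrt(max(0, 1 - lam^2)) * ts$sd[j])
      baseline_tests[, j] <- ts$mean[j] +
        ts$age_slope[j] * (age - config$age_mean) + lam * ts$sd[j] * g_latent + eps
      followup_tests[, j] <- baseline_tests[, j] +
        lam * ts$sd[j] * decline * followup
    }

    bs <- config$biomarker_specs
    biomarkers <- matrix(NA_real_, n, nrow(bs), dimnames = list(NULL, bs$name))
    for (j in seq_len(nrow(bs))) {
      dage <- age - config$age_mean
      biomarkers[, j] <- switch(
        bs$dist[j],
        normal = bs$mean[j] + bs$age_slope[j] * dage +
          stats::rnorm(n, 0, bs$sd[j]),
        lognormal = exp(bs$mean[j] + bs$age_slope[j] * dage +
                          stats::rnorm(n, 0, bs$sd[j])),
        bernoulli = {
          logit0 <- stats::qlogis(min(max(bs$mean[j], 1e-6), 1 - 1e-6))
          p <- stats::plogis(logit0 + bs$age_slope[j] * dage)
          as.numeric(stats::runif(n) < p)
        },
        ordinal = {
          raw <- bs$mean[j] + bs$age_slope[j] * dage + stats::rnorm(n, 0, bs$sd[j])
          pmin(pmax(round(raw), bs$lower[j]), bs$upper[j])
        },
        stop("unknown biomarker dist: ", bs$dist[j], call. = FALSE)
      )
    }

    features <- data.frame(age = age, sex = sex, check.names = FALSE)
    features <- cbind(features, as.data.frame(baseline_tests), biomarkers)

    feature_meta <- rbind(
      data.frame(feature = c("age", "sex"), category_path = c("age", "sex"),
                 is_binary = c(FALSE, TRUE), stringsAsFactors = FALSE),
      data.frame(feature = ts$name,
                 category_path = "cognitive_tests/objective_tests",
                 is_binary = FALSE, stringsAsFactors = FALSE),
      data.frame(feature = bs$name, category_path = bs$category_path,
                 is_binary = bs$is_binary, stringsAsFactors = FALSE)
    )

    # MCAR missingness, per feature
    rates <- stats::setNames(rep(0, ncol(features)), names(features))
    rates[bs$name] <- bs$missing_rate
    if (!is.null(config$missing_rates)) {
      unknown <- setdiff(names(config$missing_rates), names(features))
      if (length(unknown)) {
        stop("missing_rates name unknown features: ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      rates[names(config$missing_rates)] <- config$missing_rates
    }
    for (nm in names(features)) {
      if (rates[nm] > 0) {
        features[[nm]][stats::runif(n) < rates[nm]] <- NA_real_
      }
    }

    cohort <- cohort_table(
      subject_id = sprintf("S%05d", seq_len(n)),
      age = age, sex = sex, followup_years = followup,
      baseline_tests = baseline_tests, followup_tests = followup_tests,
      features = features, feature_meta = feature_meta
    )
    attr(cohort, "latent_decline") <- decline
    attr(cohort, "generator_config") <- config
    cohort
  })
}

#' Monte-Carlo oracle AUC of age under the generator
#'
#' Simulates a fresh population from the generator's age/decline model,
#' applies the 5%-tail labelling rule to the latent annual decline, and
#' returns the Mann-Whitney AUC of age as a single predictor. This is the
#' theoretical ceiling for any age-only classifier on cohorts from this
#' generator, used as the reference in parameter-recovery checks.
#'
#' @param config a [generator_config()].
#' @param n_mc Monte-Carlo population size (>= 1e5).
#' @param tail_fraction tail rule for the positive class (default 0.05).
#' @param seed seed for the Monte-Carlo draw (default: `config$seed`).
#' @return AUC estimate in \[0, 1\].
#' @export
oracle_age_auc <- function(config = generator_config(), n_mc = 1e6,
                           tail_fraction = 0.05, seed = config$seed) {
  validate_generator_config(config)
  if (n_mc < 1e5) stop("n_mc must be >= 1e5 for a stable oracle", call. = FALSE)
  if (config$decline_noise_sd == 0 && config$decline_slope_per_year_of_age == 0) {
    stop("label-undefined: decline is constant (slope = 0 and noise sd = 0), ",
         "the 5% tail is arbitrary", call. = FALSE)
  }
  with_seed(seed, {
    age <- rtruncnorm(n_mc, config$age_mean, config$age_sd,
                      config$age_range[1], config$age_range[2])
    d <- config$decline_base -
      config$decline_slope_per_year_of_age * (age - config$age_mean) +
      stats::rnorm(n_mc, 0, config$decline_noise_sd)
    n_pos <- floor(tail_fraction * n_mc)
    labels <- logical(n_mc)
    labels[order(d)[seq_len(n_pos)]] <- TRUE
    as.numeric(auc_mw(age, labels))
  })
}

#' Mask features for a random subset of subjects
#'
#' Sets the named features to missing for a seeded random subset of exactly
#' `n_subjects_masked` subjects, emulating structured missingness such as a
#' sub-cohort whose diffusion-MRI was acquired at a different time and is
#' therefore ignored.
#'
#' @param cohort a [cohort_table()].
#' @param feature_names features to mask; must exist in the cohort.
#' @param n_subjects_masked exact number of subjects to mask.
#' @param seed integer seed for the subset draw.
#' @return a copy of `cohort` with the masked cells set to `NA`.
#' @export
mask_subset_features <- function(cohort, feature_names, n_subjects_masked,
                                 seed = 1L) {
  stopifnot(inherits(cohort, "cohort_table"))
  unknown <- setdiff(feature_names, names(cohort$features))
  if (length(unknown)) {
    stop("unknown features: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- n_subjects(cohort)
  n_subjects_masked <- as.integer(n_subjects_masked)
  if (n_subjects_masked < 0L || n_subjects_masked > n) {
    stop("n_subjects_masked must be between 0 and ", n, call. = FALSE)
  }
  if (n_subjects_masked == 0L || length(feature_names) == 0L) return(cohort)
  with_seed(seed, {
    rows <- sample.int(n, n_subjects_masked)
    cohort$features[rows, feature_names] <- NA_real_
    cohort
  })
}
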