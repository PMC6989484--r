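#' Write a cohort to CSV
#'
#' Writes two plain-text files: `<prefix>_cohort.csv` (one row per subject:
#' id, covariates, two-visit test scores, feature values, empty cell =
#' missing) and the sidecar `<prefix>_features.csv` (feature, category_path,
#' is_binary). Subject covariates are prefixed `subject_` so they never
#' collide with feature columns of the same name (age, sex).
#'
#' @param cohort a [cohort_table()].
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, prefix) {
  stopifnot(inherits(cohort, "cohort_table"))
  bt <- as.data.frame(cohort$baseline_tests)
  names(bt) <- paste0("baseline_", names(bt))
  ft <- as.data.frame(cohort$followup_tests)
  names(ft) <- paste0("followup_", names(ft))
  df <- cbind(
    data.frame(subject_id = cohort$subject_id,
               subject_age = cohort$age,
               subject_sex = cohort$sex,
               followup_years = cohort$followup_years,
               stringsAsFactors = FALSE),
    bt, ft, cohort$features
  )
  main <- paste0(prefix, "_cohort.csv")
  side <- paste0(prefix, "_features.csv")
  utils::write.csv(df, main, row.names = FALSE, na = "")
  utils::write.csv(cohort$feature_meta, side, row.names = FALSE, na = "")
  invisible(c(cohort = main, features = side))
}

#' Read a cohort from CSV
#'
#' Inverse of [write_cohort()]: reads `<prefix>_cohort.csv` plus its sidecar
#' feature-metadata file and reconstructs the typed [cohort_table()] with
#' explicit missingness. Rejects duplicate subject ids (naming them), a
#' missing sidecar, and feature columns absent from the metadata.
#'
#' @param prefix path prefix used by [write_cohort()].
#' @return a [cohort_table()].
#' @export
read_cohort <- function(prefix) {
  main <- paste0(prefix, "_cohort.csv")
  side <- paste0(prefix, "_features.csv")
  if (!file.exists(main)) stop("cohort file not found: ", main, call. = FALSE)
  if (!file.exists(side)) {
    stop("sidecar feature-metadata file not found: ", side, call. = FALSE)
  }
  df <- utils::read.csv(main, na.strings = "", stringsAsFactors = FALSE,
                        check.names = FALSE)
  meta <- utils::read.csv(side, na.strings = "", stringsAsFactors = FALSE)
  meta$is_binary <- as.logical(meta$is_binary)

  if (anyDuplicated(df$subject_id)) {
    dup <- unique(df$subject_id[duplicated(df$subject_id)])
    stop("duplicated subject_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  test_names <- sub("^baseline_", "", grep("^baseline_", names(df), value = TRUE))
  feat_cols <- setdiff(names(df),
                       c("subject_id", "subject_age", "subject_sex",
                         "followup_years",
                         paste0("baseline_", test_names),
                         paste0("followup_", test_names)))
  extra <- setdiff(feat_cols, meta$feature)
  if (length(extra)) {
    stop("feature columns absent from metadata: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  non_numeric <- feat_cols[!vapply(df[feat_cols], is.numeric, logical(1))]
  if (length(non_numeric)) {
    stop("non-numeric feature columns: ",
         paste(non_numeric, collapse = ", "), call. = FALSE)
  }
  cohort_table(
    subject_id = df$subject_id,
    age = df$subject_age, sex = df$subject_sex,
    followup_years = df$followup_years,
    baseline_tests = as.matrix(stats::setNames(df[paste0("baseline_", test_names)],
                                               test_names)),
    followup_tests = as.matrix(stats::setNames(df[paste0("followup_", test_names)],
                                               test_names)),
    features = df[feat_cols],
    feature_meta = meta[match(feat_cols, meta$feature), ]
  )
}

#' Write outcome labels to CSV
#'
#' @param labels an `outcome_labels` object.
#' @param path output CSV path (columns: subject_id, delta_g_per_year, label).
#' @return invisibly, `path`.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "outcome_labels"))
  utils::write.csv(
    data.frame(subject_id = labels$subject_id,
               delta_g_per_year = labels$delta_g_per_year,
               label = as.integer(labels$labels)),
    path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the end-to-end pipeline
#'
#' Generation (or ingest) -> g-factor -> outcome labelling -> cross-validated
#' evaluation of the requested age-handling variants -> reports. One global
#' seed fans out to stage-specific child seeds, all recorded in the returned
#' manifest, so every stage can be rerun in isolation; given the same
#' configuration and seed the numeric outputs are identical.
#'
#' @param config a [generator_config()], or a path prefix to read an
#'   existing cohort from via [read_cohort()].
#' @param out_dir output directory (created if needed); CSV and JSON reports
#'   are written there.
#' @param seed global integer seed.
#' @param variants age-handling variants to evaluate (subset of 1:4).
#' @param n_repetitions CV repetitions per variant.
#' @param features feature names to use; default all cohort features.
#' @param tail_fraction outcome tail rule.
#' @return run manifest (list; also written as `manifest.json`): seeds,
#'   paths, per-stage counts, and the per-variant AUC summaries.
#' @export
run_pipeline <- function(config = generator_config(), out_dir, seed = 1L,
                         variants = 1:4, n_repetitions = 10L,
                         features = NULL, tail_fraction = 0.05) {
  stopifnot(all(variants %in% 1:4))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  child_seeds <- list(generate = seed, cv = seed + 1000L)

  cohort <- if (inherits(config, "generator_config")) {
    generate_cohort(config, seed = child_seeds$generate)
  } else {
    read_cohort(config)
  }
  paths <- list()
  paths$cohort <- file.path(out_dir, "cohort")
  write_cohort(cohort, paths$cohort)

  labels <- label_cohort(cohort, tail_fraction = tail_fraction)
  gm <- attr(labels, "gfactor_model")
  paths$labels <- file.path(out_dir, "labels.csv")
  write_labels(labels, paths$labels)

  if (is.null(features)) features <- cohort$feature_meta$feature
  summaries <- list()
  for (v in variants) {
    spec <- experiment_spec(features, variant = v,
                            n_repetitions = n_repetitions,
                            seed = child_seeds$cv,
                            name = paste0("variant", v))
    res <- run_experiment(cohort, labels, spec)
    split_path <- file.path(out_dir, sprintf("auc_splits_variant%d.csv", v))
    utils::write.csv(
      data.frame(split = seq_along(res$per_split_auc), auc = res$per_split_auc),
      split_path, row.names = FALSE, na = "")
    summaries[[paste0("variant", v)]] <- list(
      variant = v,
      n_repetitions = spec$n_repetitions,
      n_folds = spec$n_folds,
      seed = spec$seed,
      n_features = length(spec$features),
      mean_auc = res$mean_auc, ci_low = res$ci_low, ci_high = res$ci_high,
      n_dropped_splits = res$n_dropped_splits)
    paths[[paste0("splits_variant", v)]] <- split_path
  }
  paths$summary <- file.path(out_dir, "summary.json")
  summary_obj <- list(
    settings = list(seed = seed, n_repetitions = n_repetitions,
                    variants = variants, tail_fraction = tail_fraction,
                    n_features = length(features)),
    gfactor = list(explained_variance_share = gm$explained_variance_share,
                   loadings = as.list(gm$loadings)),
    labels = list(n_positive = labels$n_positive,
                  n_negative = labels$n_negative,
                  threshold = labels$threshold),
    results = summaries)
  jsonlite::write_json(summary_obj, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  manifest <- list(
    tool = paste0("dsipredict ", as.character(utils::packageVersion("dsipredict"))),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seeds = child_seeds,
    paths = paths,
    counts = list(n_subjects = n_subjects(cohort),
                  n_features = ncol(cohort$features),
                  n_positive = labels$n_positive,
                  n_negative = labels$n_negative))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  missing_out <- !vapply(unlist(paths), function(p) {
    file.exists(p) || file.exists(paste0(p, "_cohort.csv"))
  }, logical(1))
  if (any(missing_out)) {
    stop("pipeline outputs missing at exit: ",
         paste(unlist(paths)[missing_out], collapse = ", "), call. = FALSE)
  }
  invisible(manifest)
}
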