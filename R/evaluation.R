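#' Repeated stratified 2-fold splits
#'
#' For each repetition the subjects are partitioned into two random halves,
#' stratified on the outcome label so the class ratio is preserved (per-class
#' fold sizes differ by at most one). Both orderings of each partition are
#' emitted — each half serves once as training and once as test set — so `r`
#' repetitions yield `2 r` splits and `2 r` AUC values.
#'
#' @param labels logical or 0/1 outcome labels; `NA`s are not allowed here
#'   (exclude unlabeled subjects first).
#' @param n_repetitions number of repetitions (protocol default 500).
#' @param seed integer seed; the same seed reproduces the split sequence.
#' @return list of splits, each a list with `train`, `test` (integer row
#'   indices), `repetition` and `fold`.
#' @export
stratified_2fold_splits <- function(labels, n_repetitions = 500L, seed = 1L) {
  labels <- as_binary_labels(labels)
  if (anyNA(labels)) stop("labels must not contain NA", call. = FALSE)
  idx_pos <- which(labels)
  idx_neg <- which(!labels)
  if (length(idx_pos) < 2L || length(idx_neg) < 2L) {
    stop("each class needs at least 2 members for a stratified 2-fold split",
         call. = FALSE)
  }
  with_seed(seed, {
    splits <- vector("list", 2L * n_repetitions)
    for (r in seq_len(n_repetitions)) {
      p <- sample(idx_pos)
      n <- sample(idx_neg)
      half_a <- c(p[seq_len(length(p) %/% 2L)], n[seq_len(length(n) %/% 2L)])
      half_b <- setdiff(c(p, n), half_a)
      splits[[2L * r - 1L]] <- list(train = sort(half_a), test = sort(half_b),
                                    repetition = r, fold = 1L)
      splits[[2L * r]] <- list(train = sort(half_b), test = sort(half_a),
                               repetition = r, fold = 2L)
    }
    splits
  })
}

#' Corrected resampled t confidence interval for repeated CV
#'
#' The per-split performance values of repeated k-fold cross-validation are
#' not independent: training sets overlap across repetitions. The corrected
#' resampled t-test inflates the naive variance of the mean by
#' `(1/(k r) + n2/n1)`, where `n2/n1` is the test/train size ratio (1 for
#' 2-fold), before forming a t interval with `k r - 1` degrees of freedom.
#' The resulting interval is deliberately conservative.
#'
#' @param values per-split performance values (length `k_folds * n_repetitions`).
#' @param k_folds folds per repetition (protocol-fixed at 2).
#' @param n_repetitions repetitions; defaults to `length(values) / k_folds`.
#' @param test_train_ratio `n2/n1`; defaults to `1/(k_folds - 1)`, i.e. 1
#'   for 2-fold.
#' @param level confidence level (default 0.95).
#' @return list with `mean`, `low`, `high`, `level`.
#' @export
corrected_resampled_ci <- function(values, k_folds = 2L,
                                   n_repetitions = length(values) / k_folds,
                                   test_train_ratio = 1 / (k_folds - 1),
                                   level = 0.95) {
  m_tot <- k_folds * n_repetitions
  if (length(values) < 2L) {
    stop("need at least 2 per-split values", call. = FALSE)
  }
  if (length(values) != m_tot) {
    stop("length(values) must equal k_folds * n_repetitions", call. = FALSE)
  }
  m <- mean(values)
  s2 <- stats::var(values)
  corrected_var <- s2 * (1 / m_tot + test_train_ratio)
  half <- stats::qt(1 - (1 - level) / 2, df = m_tot - 1) * sqrt(corrected_var)
  list(mean = m, low = m - half, high = m + half, level = level)
}

#' Experiment specification for the CV protocol
#'
#' @param features character vector of feature names to enter the hierarchy.
#' @param variant age-handling model variant:
#'   1 = age included, no age correction;
#'   2 = age excluded, no age correction;
#'   3 = age included, non-binary features (except age) corrected for age;
#'   4 = age excluded, non-binary features corrected for age.
#' @param n_repetitions CV repetitions (protocol default 500; each yields 2
#'   splits).
#' @param seed seed for the split sequence. Experiments to be compared with
#'   [compare_aucs()] must share it.
#' @param mri_threshold optional relevance threshold for whole-dataset MRI
#'   feature selection before the CV (see [select_mri_features()]).
#' @param correction_scope `"full"` fits the age correction once on all
#'   subjects (the protocol's single-pass reading, label-free leakage only);
#'   `"fold"` refits it on each training fold.
#' @param name optional label for reports.
#' @return object of class `experiment_spec`.
#' @export
experiment_spec <- function(features, variant = 1L, n_repetitions = 500L,
                            seed = 1L, mri_threshold = NULL,
                            correction_scope = c("full", "fold"),
                            name = NULL) {
  variant <- as.integer(variant)
  if (!variant %in% 1:4) stop("variant must be 1, 2, 3 or 4", call. = FALSE)
  correction_scope <- match.arg(correction_scope)
  structure(list(features = features, variant = variant,
                 n_folds = 2L, n_repetitions = as.integer(n_repetitions),
                 seed = as.integer(seed), mri_threshold = mri_threshold,
                 correction_scope = correction_scope,
                 name = name %||% paste0("variant", variant)),
            class = "experiment_spec")
}

#' Run one cross-validated DSI experiment
#'
#' Executes the evaluation protocol for one experiment specification:
#' optional whole-dataset MRI feature selection, the age-handling variant
#' (inclusion/exclusion of age, optional age correction of non-binary
#' features), then repeated stratified 2-fold CV — on each split the
#' hierarchy is fitted on the training half, the test half is scored, the
#' test AUC recorded, and every top-level category's trained relevance
#' logged. Splits whose test half loses a class after score exclusions get
#' an undefined AUC and are dropped with a count.
#'
#' @param cohort a [cohort_table()].
#' @param labels an `outcome_labels` object or logical vector; subjects with
#'   a missing label are excluded from the experiment.
#' @param spec an [experiment_spec()].
#' @return object of class `cv_result`: `per_split_auc`, `mean_auc`,
#'   `ci_low`, `ci_high`, `relevances` (data.frame: repetition, fold, node,
#'   relevance), `n_dropped_splits`, `spec`.
#' @export
run_experiment <- function(cohort, labels, spec) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(spec, "experiment_spec"))
  if (inherits(labels, "outcome_labels")) labels <- labels$labels
  labels <- as_binary_labels(labels)
  stopifnot(length(labels) == n_subjects(cohort))

  feats <- spec$features
  unknown <- setdiff(feats, names(cohort$features))
  if (length(unknown)) {
    stop("spec features absent from cohort: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (spec$variant %in% c(2L, 4L)) feats <- setdiff(feats, "age")
  if (length(feats) == 0L) stop("no features left to evaluate", call. = FALSE)

  keep <- !is.na(labels)
  y <- labels[keep]
  x <- cohort$features[keep, , drop = FALSE]
  age <- cohort$age[keep]
  meta <- cohort$feature_meta

  correct_feats <- if (spec$variant %in% c(3L, 4L)) {
    intersect(feats, meta$feature[!meta$is_binary & meta$feature != "age"])
  } else character(0)

  # whole-dataset MRI selection operates on the variant's view of the data:
  # in corrected variants the relevance is computed on age-corrected values
  if (!is.null(spec$mri_threshold)) {
    x_sel <- x
    if (length(correct_feats)) {
      acm <- fit_age_correction(x_sel[correct_feats], age = age)
      x_sel <- apply_age_correction(acm, x_sel, age = age)
    }
    mri <- intersect(feats, meta$feature[startsWith(meta$category_path, "mri")])
    if (length(mri)) {
      rep_sel <- select_mri_features(x_sel, y, mri_features = mri,
                                     t = spec$mri_threshold)
      feats <- setdiff(feats, attr(rep_sel, "dropped"))
      if (length(feats) == 0L) stop("selection removed every feature", call. = FALSE)
    }
  }

  correct_feats <- intersect(correct_feats, feats)
  if (length(correct_feats) && spec$correction_scope == "full") {
    acm <- fit_age_correction(x[correct_feats], age = age)
    x <- apply_age_correction(acm, x, age = age)
  }

  hierarchy <- build_hierarchy(meta, features = feats)
  splits <- stratified_2fold_splits(y, spec$n_repetitions, spec$seed)

  aucs <- rep(NA_real_, length(splits))
  rel_rows <- vector("list", length(splits))
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    xs <- x
    if (length(correct_feats) && spec$correction_scope == "fold") {
      acm <- fit_age_correction(x[correct_feats], age = age, subset = sp$train)
      xs <- apply_age_correction(acm, x, age = age)
    }
    model <- dsi_fit(xs[sp$train, feats, drop = FALSE], y[sp$train],
                     hierarchy = hierarchy)
    sc <- dsi_score(model, xs[sp$test, feats, drop = FALSE])
    aucs[i] <- suppressWarnings(as.numeric(auc_mw(sc$dsi, y[sp$test])))
    top <- dsi_relevances(model, max_depth = 1L)
    top <- top[top$depth == 1L, c("node", "relevance")]
    rel_rows[[i]] <- data.frame(repetition = sp$repetition, fold = sp$fold,
                                top, stringsAsFactors = FALSE)
  }

  ok <- !is.na(aucs)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(n_dropped, " split(s) had an undefined test AUC and were dropped")
  }
  if (sum(ok) < 2L) stop("fewer than 2 defined per-split AUCs", call. = FALSE)
  ci <- corrected_resampled_ci(aucs[ok], k_folds = spec$n_folds,
                               n_repetitions = sum(ok) / spec$n_folds)

  structure(list(per_split_auc = aucs,
                 mean_auc = ci$mean, ci_low = ci$low, ci_high = ci$high,
                 relevances = do.call(rbind, rel_rows),
                 n_dropped_splits = n_dropped,
                 spec = spec),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("CV result `%s`: %d repetitions x %d folds\n",
              x$spec$name, x$spec$n_repetitions, x$spec$n_folds))
  cat(sprintf("  mean AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$mean_auc, x$ci_low, x$ci_high))
  if (x$n_dropped_splits > 0) {
    cat("  dropped splits (undefined AUC):", x$n_dropped_splits, "\n")
  }
  invisible(x)
}

#' Compare two CV results by the corrected resampled t-test
#'
#' Feeds the per-split AUC differences through [corrected_resampled_ci()];
#' the AUCs are considered significantly different iff the confidence
#' interval of the difference does not contain zero. Both results must come
#' from the identical split sequence (same seed, repetitions and folds).
#'
#' @param result_a,result_b [run_experiment()] results.
#' @param level confidence level.
#' @return list with `mean_diff`, `ci_low`, `ci_high`, `significant`.
#' @export
compare_aucs <- function(result_a, result_b, level = 0.95) {
  stopifnot(inherits(result_a, "cv_result"), inherits(result_b, "cv_result"))
  if (result_a$spec$seed != result_b$spec$seed ||
      result_a$spec$n_repetitions != result_b$spec$n_repetitions ||
      result_a$spec$n_folds != result_b$spec$n_folds) {
    stop("results must share the split sequence (seed, repetitions, folds)",
         call. = FALSE)
  }
  d <- result_a$per_split_auc - result_b$per_split_auc
  d <- d[!is.na(d)]
  ci <- corrected_resampled_ci(d, k_folds = result_a$spec$n_folds,
                               n_repetitions = length(d) / result_a$spec$n_folds,
                               level = level)
  list(mean_diff = ci$mean, ci_low = ci$low, ci_high = ci$high,
       significant = ci$low > 0 || ci$high < 0)
}

#' Cumulative feature-set experiment specifications
#'
#' Builds one spec per prefix of a category ordering (e.g. age; age +
#' cognitive tests; age + cognitive tests + cardiovascular; ...), mirroring
#' the cumulative expansion design: each spec's feature set is nested in the
#' next.
#'
#' @param cohort a [cohort_table()].
#' @param order character vector of category names (top-level categories or
#'   deeper paths), a permutation-prefix of the available ones.
#' @param ... further arguments passed to [experiment_spec()] (variant,
#'   n_repetitions, seed, ...), shared by all specs.
#' @return list of [experiment_spec()]s named by their cumulative sets.
#' @export
cumulative_feature_sets <- function(cohort, order, ...) {
  stopifnot(inherits(cohort, "cohort_table"))
  sets <- lapply(order, function(cat) {
    f <- features_in_category(cohort, cat)
    if (length(f) == 0L) stop("unknown category: ", cat, call. = FALSE)
    f
  })
  lapply(seq_along(sets), function(i) {
    experiment_spec(features = unique(unlist(sets[seq_len(i)])),
                    name = paste(order[seq_len(i)], collapse = "+"), ...)
  })
}

#' Relevance-threshold selection sweep
#'
#' Runs the reduced CV protocol (default 10 repetitions of 2-fold CV) over a
#' grid of MRI relevance thresholds for one or more feature sets, with the
#' whole-dataset selection rule of [select_mri_features()].
#'
#' @param cohort a [cohort_table()].
#' @param labels outcome labels.
#' @param feature_sets named list of feature-name vectors; default: all
#'   features, all but age, and MRI features only.
#' @param grid thresholds to sweep (default `seq(0, 0.1, 0.01)`, which
#'   contains the reference protocol's grid including 0.07).
#' @param variant age-handling variant applied to every run.
#' @param n_repetitions CV repetitions per cell (default 10).
#' @param seed shared split seed.
#' @return data.frame with `feature_set`, `t`, `mean_auc`, `ci_low`,
#'   `ci_high`, `n_features`.
#' @export
selection_sweep <- function(cohort, labels,
                            feature_sets = NULL,
                            grid = seq(0, 0.1, by = 0.01),
                            variant = 1L, n_repetitions = 10L, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (any(grid < 0 | grid > 1)) stop("grid must lie in [0, 1]", call. = FALSE)
  if (is.null(feature_sets)) {
    all_f <- cohort$feature_meta$feature
    feature_sets <- list(
      all = all_f,
      all_minus_age = setdiff(all_f, "age"),
      mri_only = features_in_category(cohort, "mri")
    )
  }
  rows <- list()
  for (set_name in names(feature_sets)) {
    for (t in grid) {
      spec <- experiment_spec(feature_sets[[set_name]], variant = variant,
                              n_repetitions = n_repetitions, seed = seed,
                              mri_threshold = t,
                              name = sprintf("%s_t%.2f", set_name, t))
      res <- tryCatch(suppressWarnings(run_experiment(cohort, labels, spec)),
                      error = function(e) NULL)
      # a threshold can empty the feature set (possible for the MRI-only
      # set at high t); report the cell as undefined rather than aborting
      rows[[length(rows) + 1L]] <- data.frame(
        feature_set = set_name, t = t,
        mean_auc = if (is.null(res)) NA_real_ else res$mean_auc,
        ci_low = if (is.null(res)) NA_real_ else res$ci_low,
        ci_high = if (is.null(res)) NA_real_ else res$ci_high,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' AUC restricted to extreme-DSI subjects
#'
#' Subjects near the decision boundary (DSI around 0.5) are the most likely
#' to be misclassified; this restricts the evaluation to test subjects with
#' confident scores (DSI below `low` or above `high`) and reports the AUC on
#' that subgroup together with retention counts.
#'
#' @param scores a `dsi_scores` data.frame (or numeric DSI vector).
#' @param labels outcome labels aligned with `scores`.
#' @param low,high DSI cut-offs (defaults 0.2 and 0.8).
#' @return list with `auc` (`NA` if a class is absent in the subgroup),
#'   `n_retained`, `fraction_retained`.
#' @export
extreme_subgroup_auc <- function(scores, labels, low = 0.2, high = 0.8) {
  dsi <- if (is.data.frame(scores)) scores$dsi else as.numeric(scores)
  if (inherits(labels, "outcome_labels")) labels <- labels$labels
  labels <- as_binary_labels(labels)
  stopifnot(length(dsi) == length(labels))
  keep <- !is.na(dsi) & !is.na(labels) & (dsi < low | dsi > high)
  n_scored <- sum(!is.na(dsi) & !is.na(labels))
  auc <- if (sum(labels[keep]) > 0 && sum(!labels[keep]) > 0) {
    as.numeric(auc_mw(dsi[keep], labels[keep]))
  } else {
    NA_real_
  }
  list(auc = auc, n_retained = sum(keep),
       fraction_retained = if (n_scored > 0) sum(keep) / n_scored else NA_real_)
}
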