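#' Fit the general cognitive factor (g-factor)
#'
#' The g-factor is the first unrotated principal component of the cognitive
#' test battery: each test is standardized (z-scored) on the fit sample and
#' the first eigenvector of the correlation matrix gives the loadings. The
#' component is oriented so that higher g means better cognition, fixed by
#' requiring a positive loading on the memory delayed-recall test.
#'
#' Subjects with any missing test score are excluded from the fit (listwise
#' deletion); their count is reported in the returned model.
#'
#' @param baseline_tests numeric matrix (subjects x tests) of baseline
#'   scores, with column names.
#' @param orient_test name of the test whose loading is forced positive;
#'   defaults to the first column matching `"delayed"`, else the first test.
#' @return object of class `gfactor_model` with fields `test_names`,
#'   `means`, `sds`, `loadings` (unit Euclidean norm),
#'   `explained_variance_share`, `orientation` (+1 if the raw eigenvector
#'   was kept, -1 if flipped) and `n_excluded`.
#' @export
fit_gfactor <- function(baseline_tests, orient_test = NULL) {
  x <- as.matrix(baseline_tests)
  if (is.null(colnames(x))) colnames(x) <- paste0("test", seq_len(ncol(x)))
  complete <- stats::complete.cases(x)
  n_excluded <- sum(!complete)
  x <- x[complete, , drop = FALSE]
  if (nrow(x) < 6L) {
    stop("need at least 6 subjects with complete test scores", call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant test score(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  means <- colMeans(x)
  eg <- eigen(stats::cor(x), symmetric = TRUE)
  loadings <- eg$vectors[, 1]
  explained <- eg$values[1] / sum(eg$values)

  if (is.null(orient_test)) {
    hit <- grep("delayed", colnames(x), value = TRUE)
    orient_test <- if (length(hit)) hit[1] else colnames(x)[1]
  }
  if (!orient_test %in% colnames(x)) {
    stop("orient_test `", orient_test, "` is not a test column", call. = FALSE)
  }
  orientation <- if (loadings[match(orient_test, colnames(x))] < 0) -1 else 1
  loadings <- orientation * loadings

  structure(
    list(test_names = colnames(x),
         means = stats::setNames(means, colnames(x)),
         sds = stats::setNames(sds, colnames(x)),
         loadings = stats::setNames(loadings, colnames(x)),
         explained_variance_share = explained,
         orientation = orientation,
         n_excluded = n_excluded),
    class = "gfactor_model"
  )
}

#' @export
print.gfactor_model <- function(x, ...) {
  cat("g-factor model (first unrotated PC of", length(x$test_names), "tests)\n")
  cat(sprintf("  explained variance: %.1f%%\n", 100 * x$explained_variance_share))
  cat("  loadings:\n")
  for (nm in x$test_names) cat(sprintf("    %-22s %+0.3f\n", nm, x$loadings[nm]))
  if (x$n_excluded > 0) {
    cat("  subjects excluded from fit (incomplete tests):", x$n_excluded, "\n")
  }
  invisible(x)
}

#' Score subjects on a fitted g-factor
#'
#' Applies the baseline standardization and loadings to any visit's test
#' scores; the same projection serves baseline and follow-up, which is what
#' makes the change in g interpretable. Subjects with any missing test get a
#' missing g.
#'
#' @param model a [fit_gfactor()] model.
#' @param tests numeric matrix (subjects x tests) with the model's test
#'   columns.
#' @return numeric vector of g scores (`NA` where any test is missing).
#' @export
score_gfactor <- function(model, tests) {
  stopifnot(inherits(model, "gfactor_model"))
  x <- as.matrix(tests)
  missing_cols <- setdiff(model$test_names, colnames(x))
  if (length(missing_cols)) {
    stop("tests matrix lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- x[, model$test_names, drop = FALSE]
  z <- sweep(sweep(x, 2, model$means), 2, model$sds, "/")
  g <- as.numeric(z %*% model$loadings)
  g[!stats::complete.cases(x)] <- NA_real_
  g
}

#' Label significant global cognitive decline by the 5% tail rule
#'
#' Annualizes the change in g (`(g_followup - g_baseline) / followup_years`)
#' and labels as positive the `floor(tail_fraction * n)` subjects with the
#' most negative annual change among those with a complete delta. Ties
#' exactly at the cut are broken by ascending subject id for
#' reproducibility. The threshold reported is the largest (least negative)
#' annual change among the positives.
#'
#' @param g_baseline,g_followup per-subject g scores (may contain `NA`).
#' @param followup_years per-subject follow-up interval, > 0.
#' @param tail_fraction proportion in (0, 0.5); default 0.05.
#' @param subject_id optional ids used for tie-breaking and reporting.
#' @return object of class `outcome_labels`: list with
#'   `delta_g_per_year` (full length, `NA` where undefined), `labels`
#'   (logical, `NA` for excluded subjects), `threshold`, `n_positive`,
#'   `n_negative`, `n_excluded`.
#' @export
label_decline <- function(g_baseline, g_followup, followup_years,
                          tail_fraction = 0.05, subject_id = NULL) {
  n <- length(g_baseline)
  stopifnot(length(g_followup) == n, length(followup_years) == n)
  if (!(tail_fraction > 0 && tail_fraction < 0.5)) {
    stop("tail_fraction must lie in (0, 0.5)", call. = FALSE)
  }
  if (any(!is.na(followup_years) & followup_years <= 0)) {
    stop("followup_years must be > 0", call. = FALSE)
  }
  if (is.null(subject_id)) subject_id <- sprintf("S%05d", seq_len(n))

  delta <- (g_followup - g_baseline) / followup_years
  ok <- !is.na(delta)
  n_labeled <- sum(ok)
  n_pos <- as.integer(floor(tail_fraction * n_labeled))

  labels <- rep(NA, n)
  labels[ok] <- FALSE
  idx_ok <- which(ok)
  ord <- idx_ok[order(delta[idx_ok], subject_id[idx_ok])]
  pos_idx <- ord[seq_len(n_pos)]
  labels[pos_idx] <- TRUE

  structure(
    list(subject_id = subject_id,
         delta_g_per_year = delta,
         labels = labels,
         threshold = if (n_pos > 0) max(delta[pos_idx]) else NA_real_,
         n_positive = n_pos,
         n_negative = as.integer(n_labeled - n_pos),
         n_excluded = as.integer(n - n_labeled),
         tail_fraction = tail_fraction),
    class = "outcome_labels"
  )
}

#' @export
print.outcome_labels <- function(x, ...) {
  cat(sprintf("Outcome labels (%.0f%% tail rule on annual delta-g)\n",
              100 * x$tail_fraction))
  cat(sprintf("  %d positive / %d negative (threshold %.3f g/yr)",
              x$n_positive, x$n_negative, x$threshold))
  if (x$n_excluded > 0) cat(sprintf("; %d excluded (missing g)", x$n_excluded))
  cat("\n")
  invisible(x)
}

#' Construct outcome labels directly from a cohort
#'
#' Convenience wrapper: fits the g-factor on the cohort's baseline tests,
#' scores both visits with the shared projection, and applies the tail rule.
#'
#' @param cohort a [cohort_table()].
#' @param tail_fraction passed to [label_decline()].
#' @return an `outcome_labels` object with the fitted `gfactor_model`
#'   attached as attribute `"gfactor_model"`.
#' @export
label_cohort <- function(cohort, tail_fraction = 0.05) {
  stopifnot(inherits(cohort, "cohort_table"))
  gm <- fit_gfactor(cohort$baseline_tests)
  g0 <- score_gfactor(gm, cohort$baseline_tests)
  g1 <- score_gfactor(gm, cohort$followup_tests)
  out <- label_decline(g0, g1, cohort$followup_years,
                       tail_fraction = tail_fraction,
                       subject_id = cohort$subject_id)
  attr(out, "gfactor_model") <- gm
  out
}
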