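#' Fit per-feature linear age correction
#'
#' Ordinary least-squares regression of each non-binary feature on age; the
#' correction replaces feature values by their residuals, removing the
#' linear age component. Ordinal features (education, smoking) are treated
#' as numeric. Age itself and binary features are never corrected.
#'
#' @param cohort a [cohort_table()], or a data.frame of feature values (in
#'   which case `age` must be supplied).
#' @param features features to fit; defaults to all non-binary features
#'   except `age`.
#' @param age per-subject age, taken from the cohort when omitted.
#' @param subset optional row indices to fit on: `scope = "full"` in the
#'   evaluation protocol fits on all subjects, `scope = "fold"` passes the
#'   training-fold indices here.
#' @return object of class `age_correction_model`: data.frame with
#'   `feature`, `intercept`, `slope`, `n_fit`.
#' @export
fit_age_correction <- function(cohort, features = NULL, age = NULL,
                               subset = NULL) {
  if (inherits(cohort, "cohort_table")) {
    if (is.null(features)) features <- nonbinary_features(cohort)
    if (is.null(age)) age <- cohort$age
    x <- cohort$features
  } else {
    x <- as.data.frame(cohort)
    if (is.null(age)) stop("`age` is required with plain feature data", call. = FALSE)
    if (is.null(features)) features <- names(x)
  }
  unknown <- setdiff(features, names(x))
  if (length(unknown)) {
    stop("unknown features: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(subset)) {
    x <- x[subset, , drop = FALSE]
    age <- age[subset]
  }
  rows <- lapply(features, function(f) {
    y <- x[[f]]
    ok <- !is.na(y) & !is.na(age)
    if (sum(ok) < 3L) {
      stop("feature `", f, "` has fewer than 3 non-missing (value, age) pairs",
           call. = FALSE)
    }
    a <- age[ok]
    if (stats::var(a) == 0) {
      stop("age is constant in the fit sample for feature `", f, "`", call. = FALSE)
    }
    fit <- stats::lm.fit(cbind(1, a), y[ok])
    data.frame(feature = f, intercept = fit$coefficients[1],
               slope = fit$coefficients[2], n_fit = sum(ok),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("age_correction_model", "data.frame"))
}

#' Apply an age-correction model
#'
#' Replaces each covered feature's non-missing values by the residual
#' `value - (intercept + slope * age)`. Uncovered features (binary ones,
#' age itself) and missing cells are untouched.
#'
#' @param model an [fit_age_correction()] model.
#' @param cohort a [cohort_table()] or data.frame of features.
#' @param age per-subject age when `cohort` is a plain data.frame.
#' @return an object of the same type as `cohort` with corrected features.
#' @export
apply_age_correction <- function(model, cohort, age = NULL) {
  stopifnot(inherits(model, "age_correction_model"))
  is_cohort <- inherits(cohort, "cohort_table")
  x <- if (is_cohort) cohort$features else as.data.frame(cohort)
  if (is.null(age)) {
    if (!is_cohort) stop("`age` is required with plain feature data", call. = FALSE)
    age <- cohort$age
  }
  unknown <- setdiff(model$feature, names(x))
  if (length(unknown)) {
    stop("model covers features absent from the data: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(model))) {
    f <- model$feature[i]
    x[[f]] <- x[[f]] - (model$intercept[i] + model$slope[i] * age)
  }
  if (is_cohort) {
    cohort$features <- x
    cohort
  } else {
    x
  }
}

#' Relevance-threshold selection of MRI features
#'
#' Computes each MRI feature's univariate relevance on the entire dataset
#' (before any train/test split — the protocol's stated, optimistic choice:
#' the labels of future test subjects inform the selection, so any AUC gain
#' is an upper bound) and retains those with relevance at or above the
#' threshold `t`. If no MRI feature survives, the MRI branch simply drops
#' out of the hierarchy with a warning; the index tolerates absent branches.
#'
#' @param cohort a [cohort_table()] or data.frame of features.
#' @param labels outcome labels ([label_cohort()] result or logical vector).
#' @param mri_features feature names eligible for selection; defaults to
#'   `features_in_category(cohort, "mri")`.
#' @param t relevance threshold in \[0, 1\]. The protocol's default grid is
#'   `seq(0, 0.1, by = 0.01)`.
#' @return object of class `selection_report`: data.frame with `feature`,
#'   `relevance`, `retained`, plus attributes `threshold`, `retained` and
#'   `dropped` name vectors.
#' @export
select_mri_features <- function(cohort, labels, mri_features = NULL, t = 0) {
  if (!(is.numeric(t) && length(t) == 1L && t >= 0 && t <= 1)) {
    stop("threshold `t` must be a single value in [0, 1]", call. = FALSE)
  }
  x <- if (inherits(cohort, "cohort_table")) cohort$features else as.data.frame(cohort)
  if (is.null(mri_features)) {
    if (!inherits(cohort, "cohort_table")) {
      stop("`mri_features` is required with plain feature data", call. = FALSE)
    }
    mri_features <- features_in_category(cohort, "mri")
  }
  unknown <- setdiff(mri_features, names(x))
  if (length(unknown)) {
    stop("unknown MRI features: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (inherits(labels, "outcome_labels")) labels <- labels$labels
  labels <- as_binary_labels(labels)

  rel <- vapply(mri_features, function(f) {
    v <- x[[f]]
    fit_feature(v[labels %in% TRUE], v[labels %in% FALSE], feature = f)$relevance
  }, numeric(1))
  retained <- rel >= t
  if (!any(retained)) {
    warning("no MRI feature reaches relevance ", t,
            "; the MRI branch drops out of the hierarchy", call. = FALSE)
  }
  out <- data.frame(feature = mri_features, relevance = as.numeric(rel),
                    retained = retained, stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(out, class = c("selection_report", "data.frame"),
            threshold = t,
            retained = mri_features[retained],
            dropped = mri_features[!retained])
}
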