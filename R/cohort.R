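#' Construct a cohort table
#'
#' The central data container: one row per subject, with per-subject
#' covariates (age, sex, follow-up interval), cognitive test scores at two
#' visits, and a subject-by-feature matrix with explicit missingness (`NA`)
#' plus per-feature metadata (hierarchy category path, binary flag).
#'
#' @param subject_id character vector of unique subject identifiers.
#' @param age,sex,followup_years numeric per-subject covariates; `sex` is
#'   coded female = 1, male = 0.
#' @param baseline_tests,followup_tests numeric matrices (subjects x tests)
#'   with identical column names, the cognitive battery at each visit.
#' @param features data.frame of numeric feature values, `NA` = missing.
#'   Typically includes `age` and `sex` as feature columns as well, since
#'   both enter the classifier hierarchy.
#' @param feature_meta data.frame with columns `feature`, `category_path`
#'   (slash-separated path from the hierarchy root, e.g. `"mri/diffusion"`)
#'   and `is_binary` (logical). Every feature column must appear exactly once.
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(subject_id, age, sex, followup_years,
                         baseline_tests, followup_tests,
                         features, feature_meta) {
  subject_id <- as.character(subject_id)
  n <- length(subject_id)
  features <- as.data.frame(features)
  baseline_tests <- as.matrix(baseline_tests)
  followup_tests <- as.matrix(followup_tests)

  if (anyDuplicated(subject_id)) {
    dup <- unique(subject_id[duplicated(subject_id)])
    stop("duplicated subject_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  for (nm in c("age", "sex", "followup_years")) {
    v <- get(nm)
    if (length(v) != n) stop("`", nm, "` must have length n_subjects", call. = FALSE)
  }
  if (any(!is.na(followup_years) & followup_years <= 0)) {
    stop("followup_years must be > 0", call. = FALSE)
  }
  if (nrow(features) != n || nrow(baseline_tests) != n || nrow(followup_tests) != n) {
    stop("all components must have one row per subject", call. = FALSE)
  }
  if (!identical(colnames(baseline_tests), colnames(followup_tests))) {
    stop("baseline and follow-up test matrices must share column names", call. = FALSE)
  }
  req <- c("feature", "category_path", "is_binary")
  if (!all(req %in% names(feature_meta))) {
    stop("feature_meta needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  feature_meta <- as.data.frame(feature_meta)[, req]
  feature_meta$feature <- as.character(feature_meta$feature)
  if (anyDuplicated(feature_meta$feature)) {
    stop("every feature must appear exactly once in feature_meta", call. = FALSE)
  }
  missing_meta <- setdiff(names(features), feature_meta$feature)
  if (length(missing_meta)) {
    stop("features absent from feature_meta: ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  missing_col <- setdiff(feature_meta$feature, names(features))
  if (length(missing_col)) {
    stop("feature_meta rows without a feature column: ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  }
  # align metadata row order with column order
  feature_meta <- feature_meta[match(names(features), feature_meta$feature), ]
  rownames(feature_meta) <- NULL

  structure(
    list(subject_id = subject_id,
         age = as.numeric(age),
         sex = as.numeric(sex),
         followup_years = as.numeric(followup_years),
         baseline_tests = baseline_tests,
         followup_tests = followup_tests,
         features = features,
         feature_meta = feature_meta),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort table:", length(x$subject_id), "subjects,",
      ncol(x$features), "features,",
      ncol(x$baseline_tests), "cognitive tests at 2 visits\n")
  cat(sprintf("  age %.1f +/- %.1f y; %.1f%% female; follow-up %.1f +/- %.1f y\n",
              mean(x$age), stats::sd(x$age), 100 * mean(x$sex),
              mean(x$followup_years), stats::sd(x$followup_years)))
  miss <- mean(is.na(as.matrix(x$features)))
  cat(sprintf("  feature cells missing: %.1f%%\n", 100 * miss))
  cat("  top-level categories:",
      paste(unique(top_level_category(x$feature_meta$category_path)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort a [cohort_table()].
#' @return integer count.
#' @export
n_subjects <- function(cohort) length(cohort$subject_id)

# First component of a slash-separated category path.
top_level_category <- function(path) sub("/.*$", "", path)

#' Features under a hierarchy category
#'
#' @param cohort a [cohort_table()].
#' @param category a category name; matches any feature whose category path
#'   equals it or starts under it (e.g. `"mri"` matches `"mri/diffusion"`).
#' @return character vector of feature names.
#' @export
features_in_category <- function(cohort, category) {
  path <- cohort$feature_meta$category_path
  hit <- path == category | startsWith(path, paste0(category, "/"))
  cohort$feature_meta$feature[hit]
}

#' Top-level feature categories of a cohort
#' @param cohort a [cohort_table()].
#' @return character vector in feature order, deduplicated.
#' @export
feature_categories <- function(cohort) {
  unique(top_level_category(cohort$feature_meta$category_path))
}

#' Names of non-binary features
#' @param cohort a [cohort_table()].
#' @param exclude features never to return (default `"age"`, which is not
#'   age-corrected).
#' @return character vector of feature names flagged non-binary.
#' @export
nonbinary_features <- function(cohort, exclude = "age") {
  setdiff(cohort$feature_meta$feature[!cohort$feature_meta$is_binary], exclude)
}
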