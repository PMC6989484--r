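#' Mann-Whitney AUC of a score against binary labels
#'
#' Computes the area under the ROC curve as the Mann-Whitney probability
#' that a randomly chosen positive outranks a randomly chosen negative,
#' with ties counted as 1/2. Subjects with a missing score are excluded
#' pairwise; the number excluded is attached as an attribute.
#'
#' @param scores numeric vector of scores (higher = more positive).
#' @param labels logical or 0/1 vector, `TRUE`/1 = positive class.
#' @param na_action `"exclude"` (default) drops missing scores before
#'   computing; the count of dropped subjects is returned in the
#'   `"n_excluded"` attribute.
#' @return AUC in \[0, 1\], or `NA` (with a warning) if either class is
#'   absent after exclusions.
#' @examples
#' auc_mw(c(0.9, 0.4, 0.5, 0.1), c(TRUE, TRUE, FALSE, FALSE))
#' @export
auc_mw <- function(scores, labels, na_action = "exclude") {
  labels <- as_binary_labels(labels)
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have the same length", call. = FALSE)
  }
  keep <- !is.na(scores) & !is.na(labels)
  n_excluded <- sum(!keep)
  scores <- scores[keep]
  labels <- labels[keep]
  n_pos <- as.numeric(sum(labels))
  n_neg <- as.numeric(sum(!labels))
  if (n_pos == 0L || n_neg == 0L) {
    warning("AUC undefined: one class absent after exclusions", call. = FALSE)
    out <- NA_real_
  } else {
    r <- rank(scores) # midranks handle ties as 1/2
    out <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  attr(out, "n_excluded") <- n_excluded
  out
}

# Coerce labels given as logical, 0/1 numeric, or a two-level factor to logical.
as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.numeric(labels)) {
    bad <- !is.na(labels) & !(labels %in% c(0, 1))
    if (any(bad)) stop("labels must be logical or 0/1", call. = FALSE)
    return(labels == 1)
  }
  stop("labels must be logical, 0/1, or a two-level factor", call. = FALSE)
}

# Seeded RNG scope: pins the generator kind so results are reproducible
# across machines, and restores the caller's RNG state on exit.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
  }
  force(code)
}

# Moments of a normal truncated to [lower, upper].
truncnorm_moments <- function(mu, sigma, lower, upper) {
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  ada <- if (is.finite(a)) a * da else 0
  bdb <- if (is.finite(b)) b * db else 0
  m <- mu + sigma * (da - db) / z
  v <- sigma^2 * (1 + (ada - bdb) / z - ((da - db) / z)^2)
  c(mean = m, sd = sqrt(v))
}

# Underlying (mu, sigma) such that the truncated distribution has the target
# mean and sd: truncation otherwise shifts and shrinks the realized moments.
truncnorm_params <- function(mean, sd, lower, upper) {
  obj <- function(p) {
    mom <- truncnorm_moments(p[1], exp(p[2]), lower, upper)
    (mom["mean"] - mean)^2 + (mom["sd"] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "BFGS")
  if (fit$value > 1e-8) {
    stop("no truncated normal on [", lower, ", ", upper,
         "] attains mean ", mean, " and sd ", sd, call. = FALSE)
  }
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Truncated-normal sampler by rejection, moment-matched so the realized
# distribution has the requested mean and sd. Bounds are wide relative to
# the sd in all uses here, so rejection is cheap.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (is.finite(lower) || is.finite(upper)) {
    p <- truncnorm_params(mean, sd,
                          if (is.finite(lower)) lower else -Inf,
                          if (is.finite(upper)) upper else Inf)
    mean <- p[["mu"]]
    sd <- p[["sigma"]]
  }
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lower & x <= upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
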