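test_that("orientation follows the class ordering with a +1 tie rule", {
  expect_identical(fit_feature(c(3, 5), c(1, 2))$orientation, 1)
  expect_identical(fit_feature(c(1, 2), c(3, 5))$orientation, -1)
  tie <- fit_feature(c(1, 2, 3), c(1, 2, 3))
  expect_identical(tie$orientation, 1)
  expect_identical(tie$relevance, 0)
})

test_that("fitness reproduces the counting formula at worked points", {
  m <- fit_feature(c(3, 5), c(1, 2))
  expect_equal(fitness(m, 0), 0)   # below all training values
  expect_equal(fitness(m, 10), 1)  # above all training values
  expect_equal(fitness(m, 2.5), 0.5) # gap between supports: 0/0 -> 0.5

  # class imbalance: P/N = 0.5 rescales the false positives
  m2 <- fit_feature(c(3, 5), c(1, 2, 4, 6))
  expect_equal(fitness(m2, 4), 1 / (1 + 0.5))

  expect_true(is.na(fitness(m, NA))) # missing propagates, never 0.5
})

test_that("relevance is the clamped Youden index of the fitness classifier", {
  expect_equal(fit_feature(c(3, 5), c(1, 2))$relevance, 1) # separated
  expect_equal(fit_feature(c(1, 2, 3), c(1, 2, 3))$relevance, 0) # identical
  expect_equal(fit_feature(c(4, 5, 6), c(1, 2, 5))$relevance, 1 / 3)
})

test_that("unusable features score 0.5 and vanish from weighted sums", {
  m <- fit_feature(numeric(0), c(1, 2))
  expect_false(m$usable)
  expect_identical(m$relevance, 0)
  expect_equal(fitness(m, 3), 0.5)
})

test_that("fitness and relevance match the brute-force counting oracle", {
  set.seed(42)
  for (i in 1:40) {
    pos <- sample(0:8, sample(1:10, 1), replace = TRUE)
    neg <- sample(0:8, sample(1:10, 1), replace = TRUE)
    m <- fit_feature(pos, neg)
    xs <- seq(-1, 9, by = 0.5)
    expect_identical(fitness(m, xs), brute_fitness(pos, neg, xs))
    expect_identical(m$relevance, brute_relevance(pos, neg))
  }
})

test_that("orientation symmetry: negating both classes mirrors fitness", {
  set.seed(7)
  pos <- rnorm(15, 1)
  neg <- rnorm(20)
  m <- fit_feature(pos, neg)
  mneg <- fit_feature(-pos, -neg)
  expect_equal(mneg$relevance, m$relevance)
  xs <- seq(-3, 4, by = 0.25)
  expect_equal(fitness(mneg, -xs), fitness(m, xs))
})

test_that("the composite index is the relevance-weighted mean of fitnesses", {
  set.seed(5)
  n <- 120
  y <- rep(c(TRUE, FALSE), c(30, 90))
  x <- data.frame(a = rnorm(n) + y, b = rnorm(n) + 0.3 * y, c = rnorm(n))
  model <- dsi_fit(x, y)
  sc <- dsi_score(model, x)

  leaf <- lapply(names(x), function(f) fit_feature(x[[f]][y], x[[f]][!y]))
  w <- vapply(leaf, `[[`, numeric(1), "relevance")
  f <- sapply(seq_along(leaf), function(j) fitness(leaf[[j]], x[[names(x)[j]]]))
  expect_equal(sc$dsi, as.numeric(f %*% w / sum(w)))

  # all relevances equal -> unweighted mean (check via a mirrored pair)
  x2 <- data.frame(a = x$a, a_neg = -x$a)
  m2 <- dsi_fit(x2, y)
  rel <- dsi_relevances(m2)
  expect_equal(rel$relevance[rel$node == "a"], rel$relevance[rel$node == "a_neg"])
  s2 <- dsi_score(m2, x2)
  fa <- fitness(fit_feature(x$a[y], x$a[!y]), x$a)
  fb <- fitness(fit_feature(-x$a[y], -x$a[!y]), -x$a)
  expect_equal(s2$dsi, (fa + fb) / 2)
})

test_that("a single-feature hierarchy reduces to that feature's fitness", {
  set.seed(6)
  y <- rep(c(TRUE, FALSE), c(20, 60))
  x <- data.frame(age = rnorm(80) + y)
  model <- dsi_fit(x, y)
  expect_equal(dsi_score(model, x)$dsi,
               fitness(fit_feature(x$age[y], x$age[!y]), x$age))
})

test_that("hierarchy recursion aggregates node composites, not raw leaves", {
  set.seed(8)
  n <- 200
  y <- rep(c(TRUE, FALSE), c(50, 150))
  x <- data.frame(u = rnorm(n) + y, v = rnorm(n) + 0.5 * y, w = rnorm(n) - y)
  meta <- data.frame(feature = c("u", "v", "w"),
                     category_path = c("grp", "grp", "solo"),
                     is_binary = FALSE)
  h <- build_hierarchy(meta)
  model <- dsi_fit(x, y, hierarchy = h)
  sc <- dsi_score(model, x)

  leaf <- lapply(names(x), function(f) fit_feature(x[[f]][y], x[[f]][!y]))
  names(leaf) <- names(x)
  fv <- sapply(names(x), function(f) fitness(leaf[[f]], x[[f]]))
  wg <- c(leaf$u$relevance, leaf$v$relevance)
  grp <- as.numeric(fv[, c("u", "v")] %*% wg / sum(wg))
  r_grp <- max(mean(grp[y] > 0.5) + mean(grp[!y] <= 0.5) - 1, 0)
  r_w <- leaf$w$relevance
  expected <- (r_grp * grp + r_w * fv[, "w"]) / (r_grp + r_w)
  expect_equal(sc$dsi, expected)

  rel <- dsi_relevances(model)
  expect_equal(rel$relevance[rel$node == "grp"], r_grp)
})

test_that("DSI stays in [0,1] and classifies strictly above 0.5 as positive", {
  co <- tiny_cohort(n = 300, seed = 13)
  lab <- label_cohort(co)
  model <- dsi_fit(co, lab)
  sc <- dsi_score(model, co)
  expect_true(all(sc$dsi >= 0 & sc$dsi <= 1, na.rm = TRUE))
  expect_identical(sc$classification[!is.na(sc$dsi) & sc$dsi > 0.5][1], "positive")
  expect_true(all(ifelse(is.na(sc$dsi), sc$classification == "undefined",
                         sc$classification == ifelse(sc$dsi > 0.5,
                                                     "positive", "negative"))))
  # a hand-built boundary case: dsi exactly 0.5 is negative
  y <- c(TRUE, TRUE, FALSE, FALSE)
  x <- data.frame(f = c(4, 5, 1, 2))
  m <- dsi_fit(x, y)
  s <- dsi_score(m, data.frame(f = 3)) # in the gap between supports
  expect_equal(s$dsi, 0.5)
  expect_identical(s$classification, "negative")
})

test_that("zero-relevance features leave every score unchanged", {
  set.seed(9)
  n <- 100
  y <- rep(c(TRUE, FALSE), each = n / 2)
  x <- data.frame(a = rnorm(n) + y, b = rnorm(n) - 0.5 * y)
  base <- dsi_score(dsi_fit(x, y), x)
  # a feature whose classes are identical has relevance exactly 0
  x$null <- rep(c(1, 2, 3, 4, 5), n / 5)
  x$null[y] <- x$null[!y]
  aug <- dsi_fit(x, y)
  rel <- dsi_relevances(aug)
  expect_true(all(rel$relevance[rel$node == "null"] == 0))
  expect_equal(dsi_score(aug, x)$dsi, base$dsi)
})

test_that("a missing feature is equivalent to an absent feature", {
  co <- tiny_cohort(n = 250, seed = 14)
  lab <- label_cohort(co)
  # remove the feature from the hierarchy entirely...
  feats <- setdiff(co$feature_meta$feature, "global_md")
  h_removed <- build_hierarchy(co$feature_meta, features = feats)
  m_removed <- dsi_fit(co$features, lab$labels, hierarchy = h_removed)
  s_removed <- dsi_score(m_removed, co$features)
  # ... versus masking it everywhere under the full hierarchy
  masked <- mask_subset_features(co, "global_md", n_subjects(co))
  m_masked <- dsi_fit(masked, lab)
  s_masked <- dsi_score(m_masked, masked)
  expect_equal(s_masked$dsi, s_removed$dsi)

  # per-subject renormalization: one observed child only
  y <- rep(c(TRUE, FALSE), each = 10)
  x <- data.frame(a = c(rnorm(10, 2), rnorm(10)), b = c(rnorm(10, 1), rnorm(10)))
  m <- dsi_fit(x, y)
  s <- dsi_score(m, data.frame(a = 1.4, b = NA))
  expect_equal(s$dsi, fitness(fit_feature(x$a[y], x$a[!y]), 1.4))
  s_none <- dsi_score(m, data.frame(a = NA, b = NA))
  expect_true(is.na(s_none$dsi))
  expect_identical(s_none$classification, "undefined")
})

test_that("hierarchy configurations survive a YAML/JSON round trip", {
  co <- tiny_cohort(n = 50, seed = 15)
  h <- build_hierarchy(co$feature_meta)
  for (ext in c("yaml", "json")) {
    path <- file.path(withr::local_tempdir(), paste0("h.", ext))
    write_hierarchy(h, path)
    h2 <- read_hierarchy(path)
    expect_identical(unclass(h2), unclass(h))
  }
  expect_error(dsi_fit(data.frame(x = 1:4), c(TRUE, TRUE, FALSE, FALSE),
                       hierarchy = build_hierarchy(
                         data.frame(feature = "zz", category_path = "zz",
                                    is_binary = FALSE))),
               "unknown features")
  expect_error(dsi_fit(data.frame(x = 1:4), c(TRUE, TRUE, TRUE, TRUE)),
               "both classes")
})
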