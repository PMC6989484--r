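# Independent brute-force implementation of the per-feature fitness and
# relevance definitions, written as explicit pair/count enumeration so it
# shares no code path with the package implementation.

brute_orientation <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  if (s / (length(pos) * length(neg)) >= 0.5) 1 else -1
}

brute_fitness <- function(pos, neg, x) {
  o <- brute_orientation(pos, neg)
  pos <- o * pos
  neg <- o * neg
  x <- o * x
  P <- length(pos)
  N <- length(neg)
  vapply(x, function(xi) {
    fn <- 0
    for (p in pos) if (p <= xi) fn <- fn + 1
    fp <- 0
    for (n in neg) if (n > xi) fp <- fp + 1
    if (fn == 0 && fp == 0) return(0.5)
    fn / (fn + (P / N) * fp)
  }, numeric(1))
}

brute_relevance <- function(pos, neg) {
  f_pos <- brute_fitness(pos, neg, pos)
  f_neg <- brute_fitness(pos, neg, neg)
  sens <- mean(f_pos > 0.5)
  spec <- mean(f_neg <= 0.5)
  max(sens + spec - 1, 0)
}

# Small cohort for pipeline-level tests: defaults scaled down.
tiny_cohort <- function(n = 400, seed = 11, ...) {
  generate_cohort(generator_config(n_subjects = n, seed = seed, ...))
}
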