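# Independent oracles used across the suite. These are deliberately naive,
# literal implementations kept separate from the package's code paths.

# Brute-force ssGSEA running sum: walk the ranked list and accumulate the
# weighted in-set ECDF minus the uniform out-of-set ECDF, step by step.
ssgsea_brute <- function(values, set, expo) {
  ord <- order(-values, names(values))
  v <- values[ord]
  g <- names(v)
  den <- sum(abs(v[g %in% set])^expo)
  n_out <- sum(!g %in% set)
  run_in <- 0
  run_out <- 0
  score <- 0
  for (i in seq_along(v)) {
    if (g[i] %in% set) run_in <- run_in + abs(v[[i]])^expo / den
    else run_out <- run_out + 1 / n_out
    score <- score + (run_in - run_out)
  }
  unname(score)
}

# Exhaustive two-sided Fisher p by hypergeometric enumeration over every
# table with the observed margins (fisher.test's relative-error convention
# for "as extreme").
fisher_enum <- function(a, b, c, d) {
  m <- a + b          # first row margin (successes)
  n <- c + d          # second row margin
  k <- a + c          # first column margin
  lo <- max(0L, k - n)
  hi <- min(m, k)
  xs <- lo:hi
  probs <- dhyper(xs, m, n, k)
  sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

# Textbook k=2 log-rank: observed minus expected over event times.
logrank_hand <- function(t, e, grp) {
  g1 <- unique(grp)[1]
  evt <- sort(unique(t[e == 1]))
  O <- 0; E <- 0; V <- 0
  for (tt in evt) {
    atrisk <- t >= tt
    n <- sum(atrisk)
    n1 <- sum(atrisk & grp == g1)
    d <- sum(t == tt & e == 1)
    d1 <- sum(t == tt & e == 1 & grp == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Small default-structure cohorts are reused by several files; memoize them.
.cohort_cache <- new.env(parent = emptyenv())
small_cohort <- function(seed = 42, n = 150, probes = 300) {
  key <- sprintf("c_%d_%d_%d", seed, n, probes)
  if (is.null(.cohort_cache[[key]])) {
    cfg <- synthetic_config(n_samples = n, n_probes = probes,
                            n_noise_genes = 100, seed = seed)
    .cohort_cache[[key]] <- generate_cohort(cfg)
  }
  .cohort_cache[[key]]
}
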