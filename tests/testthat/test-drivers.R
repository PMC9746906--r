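# Driver-event detection: Fisher agreement with enumeration, the three
# driver cascades, and direction correctness.

test_that("Fisher exact p agrees with exhaustive enumeration", {
  set.seed(3)
  for (i in 1:200) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    c_ <- sample(0:12, 1); d <- sample(0:12, 1)
    if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0)
      next
    p_pkg <- fisher.test(matrix(c(a, c_, b, d), 2))$p.value
    expect_lt(abs(p_pkg - fisher_enum(a, b, c_, d)), 1e-10)
  }
})

test_that("strongly enriched mutations pass and flat ones do not", {
  samples <- sprintf("s%03d", 1:500)
  lab <- setNames(rep(1:5, each = 100), samples)
  status <- matrix(0L, 3, 500, dimnames = list(c("g1", "g2", "g3"), samples))
  # g1: 60/100 mutated inside subtype 1, 20/400 outside
  status["g1", c(1:60, 101:120)] <- 1L
  # g2: identical 10% frequency everywhere
  status["g2", seq(1, 500, by = 10)] <- 1L
  # g3: never mutated (zero margin)
  ev <- mutation_driver_test(status, lab, c("g1", "g2", "g3", "g4"))
  e1 <- ev[ev$feature == "g1" & ev$subtype == 1, ]
  expect_lt(e1$enrichment_p, 0.001)
  expect_identical(e1$effect_direction, "enriched")
  expect_true(e1$passes)
  e2 <- ev[ev$feature == "g2" & ev$subtype == 1, ]
  expect_equal(e2$enrichment_p, 1)
  expect_false(e2$passes)
  expect_setequal(attr(ev, "untested"), c("g3", "g4"))
})

test_that("SCNA drivers need one-subtype enrichment plus concordance", {
  set.seed(11)
  samples <- sprintf("s%03d", 1:500)
  lab <- setNames(rep(1:5, each = 100), samples)
  tri <- matrix(0L, 3, 500, dimnames = list(c("f1", "f2", "f3"), samples))
  # f1 deleted in 70% of subtype 2, 5% elsewhere; expression coupled -1.5
  del1 <- c(100 + sample(100, 70), setdiff(1:500, 101:200)[
    runif(400) < 0.05])
  tri["f1", del1] <- -1L
  # f2 deleted with the same enrichment but expression independent
  del2 <- c(100 + sample(100, 70), setdiff(1:500, 101:200)[
    runif(400) < 0.05])
  tri["f2", del2] <- -1L
  expr <- matrix(rnorm(2 * 500, 8, 1), 2, 500,
                 dimnames = list(c("GA", "GB"), samples))
  expr["GA", tri["f1", ] == -1] <- expr["GA", tri["f1", ] == -1] - 1.5
  ev <- scna_driver_test(tri, lab, expr, list(f1 = "GA", f2 = "GB"))
  e1 <- ev[ev$feature == "f1", ]
  expect_identical(e1$event_type, "deletion")
  expect_equal(e1$subtype, 2)
  expect_true(e1$passes)
  e2 <- ev[ev$feature == "f2", ]
  expect_lt(e2$enrichment_p, 0.001)
  expect_false(e2$passes)      # concordance failed
  expect_gt(e2$concordance_p, 0.05)
  # f3 altered nowhere: no event emitted
  expect_false("f3" %in% ev$feature)
})

test_that("hypermethylation drivers need pairwise contrast and negative
           regulation", {
  set.seed(13)
  n <- 500
  samples <- sprintf("s%03d", seq_len(n))
  lab <- setNames(rep(1:5, each = 100), samples)
  mk_beta <- function(p_by_subtype) {
    on <- runif(n) < p_by_subtype[lab]
    ifelse(on, rbeta(n, 10, 2), rbeta(n, 2, 10))
  }
  beta <- rbind(
    p1 = mk_beta(c(0.05, 0.05, 0.8, 0.05, 0.05)),  # driver pattern
    p2 = mk_beta(rep(0.3, 5)),                      # flat
    p3 = mk_beta(c(0.05, 0.05, 0.8, 0.05, 0.05)))   # positive coupling
  colnames(beta) <- samples
  expr <- rbind(G1 = 8 - 2 * beta["p1", ] + rnorm(n, 0, 1),
                G2 = rnorm(n, 8, 1),
                G3 = 8 + 2 * beta["p3", ] + rnorm(n, 0, 1))
  colnames(expr) <- samples
  map <- c(p1 = "G1", p2 = "G2", p3 = "G3")
  ev <- methylation_driver_test(beta, lab, expr, map,
                                top_sites = c("p1", "p2", "p3"))
  e1 <- ev[ev$feature == "p1", ]
  expect_equal(e1$subtype, 3)
  expect_true(e1$passes)
  expect_lt(e1$concordance_stat, 0)
  if ("p2" %in% ev$feature)
    expect_false(ev[ev$feature == "p2", ]$passes)
  e3 <- ev[ev$feature == "p3", ]
  expect_lt(e3$enrichment_p, 0.001)   # step (a) passes
  expect_false(e3$passes)             # step (b) fails: positive correlation
})

test_that("passing events point in the planted direction", {
  coh <- small_cohort()
  cfg <- coh$config
  st <- coh$truth$subtype
  tri <- trinarize_gistic(coh$cnv)
  fmap <- setNames(as.list(cfg$driver_fragments$gene),
                   cfg$driver_fragments$fragment)
  scna <- scna_driver_test(tri, st, coh$expression, fmap)
  amp <- scna[scna$passes & scna$event_type == "amplification", ]
  for (i in seq_len(nrow(amp))) {
    altered <- tri[amp$feature[i], ] == 1
    expect_gt(mean(coh$expression[amp$gene[i], altered]),
              mean(coh$expression[amp$gene[i], !altered]))
  }
  pmap <- setNames(coh$probe_annotation$gene, coh$probe_annotation$probe)
  meth <- methylation_driver_test(coh$methylation, st, coh$expression, pmap,
                                  top_sites = cfg$driver_cpgs$probe)
  hyp <- meth[meth$passes, ]
  expect_gt(nrow(hyp), 0)
  for (i in seq_len(nrow(hyp)))
    expect_lt(cor(coh$methylation[hyp$feature[i], ],
                  coh$expression[hyp$gene[i], ]), 0)
})

test_that("a null cohort produces almost no mutation drivers", {
  set.seed(29)
  samples <- sprintf("s%03d", 1:500)
  lab <- setNames(rep(1:5, each = 100), samples)
  genes <- sprintf("G%03d", 1:127)
  false_counts <- vapply(1:10, function(i) {
    status <- matrix(rbinom(127 * 500, 1, 0.08), 127, 500,
                     dimnames = list(genes, samples))
    ev <- mutation_driver_test(status, lab, genes)
    sum(ev$passes)
  }, numeric(1))
  expect_lte(mean(false_counts), 1.5)
})
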