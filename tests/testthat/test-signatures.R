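# NMF signature extraction: exact low-rank recovery, the cophenetic rank
# rule, reference matching and exposure clustering.

test_that("an exact rank-1 matrix is reconstructed essentially exactly", {
  set.seed(1)
  w <- runif(25, 1, 3)
  h <- rgamma(96, 0.2); h <- h / sum(h) * 150
  v <- outer(w, h)
  rownames(v) <- sprintf("s%02d", 1:25)
  m <- extract_signatures(v, rank_range = 1:3, n_restarts = 5, seed = 2,
                          max_iter = 5000, tol = 1e-9)
  expect_lt(m$reconstruction_error_by_rank[["1"]], 1e-6)
})

test_that("reconstruction error is non-increasing in rank", {
  set.seed(4)
  v <- matrix(rpois(30 * 96, 4), 30, 96)
  rownames(v) <- sprintf("s%02d", 1:30)
  m <- extract_signatures(v, rank_range = 1:4, n_restarts = 30, seed = 5,
                          max_iter = 400)
  err <- m$reconstruction_error_by_rank
  expect_true(all(diff(err) <= 1e-3))  # up to restart noise
})

test_that("the cophenetic drop rule picks the last rank before the fall", {
  coph <- c(`2` = 0.99, `3` = 0.99, `4` = 0.98, `5` = 0.80, `6` = 0.75)
  expect_equal(select_rank_by_cophenetic(coph, tolerance = 0.05), 4)
  # no cliff: the peak is where the coefficient begins to (gently) fall
  expect_equal(select_rank_by_cophenetic(
    c(`2` = 0.97, `3` = 0.99, `4` = 0.975, `5` = 0.96), 0.05), 3)
  # exact ties break toward the smaller rank
  expect_equal(select_rank_by_cophenetic(c(`2` = 0.9, `3` = 0.9), 0.05), 2)
  expect_equal(select_rank_by_cophenetic(c(`2` = 0.99, `3` = 0.90), 0.05), 2)
})

test_that("cophenetic coefficient is 1 when restarts agree exactly", {
  # two well-separated duplicated motif patterns: every restart produces the
  # same connectivity, so the consensus is binary and the tree fits it
  base1 <- c(rep(40, 8), rep(0, 88))
  base2 <- c(rep(0, 88), rep(40, 8))
  v <- rbind(matrix(rep(base1, 10), 10, byrow = TRUE),
             matrix(rep(base2, 10), 10, byrow = TRUE))
  rownames(v) <- sprintf("s%02d", 1:20)
  m <- extract_signatures(v, rank_range = 2, n_restarts = 10, seed = 3,
                          max_iter = 300)
  expect_equal(unname(m$cophenetic_by_rank[["2"]]), 1)
})

test_that("planted signatures are recovered with high cosine similarity", {
  cfg <- synthetic_config(n_samples = 120, n_signatures = 3, n_probes = 60,
                          meth_program_size = 5,
                          n_noise_genes = 20, mutations_per_sample = 150,
                          seed = 17)
  coh <- generate_cohort(cfg)
  motif <- build_motif_matrix(coh$mutation_records, coh$sample_ids)
  m <- extract_signatures(motif, rank_range = 2:4, n_restarts = 15,
                          seed = 23)
  expect_equal(m$selected_rank, 3)
  cosim <- sapply(seq_len(3), function(i)
    max(sapply(seq_len(3), function(j)
      sum(cfg$signature_profiles[i, ] * m$signatures[j, ]) /
        sqrt(sum(cfg$signature_profiles[i, ]^2) *
               sum(m$signatures[j, ]^2)))))
  expect_true(all(cosim >= 0.9))
  # signature rows on the simplex, everything nonnegative
  expect_true(all(m$signatures >= 0))
  expect_true(all(abs(rowSums(m$signatures) - 1) < 1e-6))
  expect_true(all(m$exposures >= 0))
})

test_that("degenerate inputs are rejected", {
  v <- matrix(0, 10, 96)
  rownames(v) <- letters[1:10]
  expect_error(extract_signatures(v, rank_range = 2:3), "all-zero")
  v2 <- matrix(rpois(5 * 96, 3), 5, 96)
  expect_error(extract_signatures(v2, rank_range = 2:6), "rank")
})

test_that("reference matching reports correlations and flags flat profiles", {
  cfg <- synthetic_config(n_samples = 80, n_signatures = 3, n_probes = 60,
                          meth_program_size = 5,
                          n_noise_genes = 20, mutations_per_sample = 120,
                          seed = 29)
  coh <- generate_cohort(cfg)
  motif <- build_motif_matrix(coh$mutation_records, coh$sample_ids)
  m <- extract_signatures(motif, rank_range = 3, n_restarts = 10, seed = 1)
  # the model's own signatures as reference: diagonal r = 1
  self <- match_reference_signatures(m, m$signatures)
  expect_true(all(abs(diag(self$correlations) - 1) < 1e-12))
  # perturbed reference: best match still nearly perfect
  set.seed(9)
  noisy <- m$signatures + matrix(rnorm(3 * 96, 0, 0.001), 3)
  pert <- match_reference_signatures(m, noisy)
  expect_true(all(pert$best_match$r > 0.99))
  # a flat profile is excluded from best-match reporting
  ref <- rbind(m$signatures, flat = rep(1 / 96, 96))
  fl <- match_reference_signatures(m, ref)
  expect_identical(fl$flat_references, "flat")
  expect_false(any(fl$best_match$reference == "flat"))
  # column-order mismatch is an error, not a silent reorder
  scrambled <- m$signatures[, rev(seq_len(96))]
  expect_error(match_reference_signatures(m, scrambled), "column-order")
})

test_that("exposure clustering splits point masses and is order-invariant", {
  ex <- rbind(matrix(rep(c(10, 0, 0), 30), 30, byrow = TRUE),
              matrix(rep(c(0, 10, 0), 30), 30, byrow = TRUE))
  rownames(ex) <- sprintf("s%02d", 1:60)
  ca <- cluster_exposures(ex, k = 2)
  expect_equal(ca$k, 2)
  expect_equal(length(unique(ca$labels[1:30])), 1)
  expect_equal(length(unique(ca$labels[31:60])), 1)
  expect_false(ca$labels[1] == ca$labels[31])
  # permuting samples permutes the partition identically
  set.seed(2)
  perm <- sample(60)
  ca2 <- cluster_exposures(ex[perm, ], k = 2)
  expect_equal(adjusted_rand_index(ca2$labels[rownames(ex)], ca$labels), 1)
  expect_error(cluster_exposures(ex, k = 100), "exceeds")
})

test_that("auto-k exposure clustering recovers planted subtype structure", {
  set.seed(31)
  centers <- diag(6) * 30
  ex <- centers[rep(1:6, each = 25), ] + matrix(rnorm(150 * 6, 0, 1.5), 150)
  ex <- pmax(ex, 0)
  rownames(ex) <- sprintf("s%03d", 1:150)
  ca <- cluster_exposures(ex, k = "auto", k_range = 2:8)
  expect_equal(ca$k, 6)
  expect_gte(adjusted_rand_index(ca$labels, rep(1:6, each = 25)), 0.9)
})
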