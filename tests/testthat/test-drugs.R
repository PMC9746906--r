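# Drug screen: missingness filtering before imputation, KNN imputation,
# ridge AUC prediction and two-panel candidate ranking.

test_that("drugs beyond the missingness cap are removed, never imputed", {
  auc <- matrix(rnorm(4 * 20, 10), 4, 20,
                dimnames = list(paste0("d", 1:4), paste0("c", 1:20)))
  auc["d2", 1:5] <- NA   # 25% missing: above the 20% cap
  auc["d3", 1:6] <- NA   # 30% missing
  prep <- prepare_drug_matrix(auc, max_missing = 0.2)
  expect_setequal(prep$removed, c("d2", "d3"))
  expect_false(any(c("d2", "d3") %in% rownames(prep$auc)))
  expect_false(anyNA(prep$auc))
  # complete matrix passes through untouched
  full <- matrix(rnorm(3 * 8, 10), 3, 8,
                 dimnames = list(paste0("d", 1:3), paste0("c", 1:8)))
  prep2 <- prepare_drug_matrix(full)
  expect_identical(prep2$auc, full)
  expect_equal(prep2$n_imputed, 0L)
})

test_that("an identical twin drug donates its value under k = 1", {
  base <- rnorm(10, 10)
  auc <- rbind(d1 = base, d2 = base, d3 = rnorm(10, 20))
  colnames(auc) <- paste0("c", 1:10)
  auc["d1", 4] <- NA
  prep <- prepare_drug_matrix(auc, max_missing = 0.2, k_neighbors = 1)
  expect_equal(unname(prep$auc["d1", 4]), base[4])
  expect_equal(prep$n_imputed, 1L)
})

test_that("ridge prediction interpolates exact linear responses", {
  set.seed(17)
  genes <- sprintf("G%02d", 1:10)
  xc <- matrix(rnorm(10 * 40, 6, 1.5), 10, 40,
               dimnames = list(genes, sprintf("c%02d", 1:40)))
  w <- rnorm(10)
  harm0 <- harmonize_cohorts(xc, xc)
  y <- setNames(drop(t(harm0$reference) %*% w) + 10, colnames(xc))
  pred <- predict_patient_auc(xc, y, xc, ridge_penalty = 1e-8)
  expect_lt(max(abs(pred - y)), 1e-6)
  # constant AUC: everyone predicted the constant
  const <- setNames(rep(7, 40), colnames(xc))
  predc <- predict_patient_auc(xc, const, xc, ridge_penalty = "auto")
  expect_equal(as.numeric(predc), rep(7, 40), tolerance = 1e-9)
})

test_that("a constant gene in both cohorts never changes predictions", {
  set.seed(18)
  genes <- sprintf("G%02d", 1:12)
  xc <- matrix(rnorm(12 * 30, 5), 12, 30,
               dimnames = list(genes, sprintf("c%02d", 1:30)))
  xp <- matrix(rnorm(12 * 12, 5), 12, 12,
               dimnames = list(genes, sprintf("p%02d", 1:12)))
  y <- setNames(rnorm(30, 10), colnames(xc))
  p1 <- predict_patient_auc(xc, y, xp, ridge_penalty = 1)
  p2 <- predict_patient_auc(rbind(xc, CONST = 3), y,
                            rbind(xp, CONST = 3), ridge_penalty = 1)
  expect_equal(as.numeric(p1), as.numeric(p2), tolerance = 1e-10)
})

test_that("held-out accuracy of the generative ridge model is high", {
  set.seed(19)
  p <- 30; n <- 200
  genes <- sprintf("G%02d", 1:p)
  xc <- matrix(rnorm(p * n), p, n, dimnames = list(genes,
                                                   sprintf("c%03d", 1:n)))
  xh <- matrix(rnorm(p * 100), p, 100,
               dimnames = list(genes, sprintf("h%03d", 1:100)))
  w <- rnorm(p, 0, 0.4)
  y <- setNames(drop(t(xc) %*% w) + rnorm(n, 0, 0.1) + 10, colnames(xc))
  yh <- drop(t(xh) %*% w) + 10
  pred <- predict_patient_auc(xc, y, xh, ridge_penalty = "auto")
  r2 <- 1 - sum((pred - yh)^2) / sum((yh - mean(yh))^2)
  expect_gte(r2, 0.8)
})

test_that("panel-level prediction matches the per-drug path", {
  set.seed(20)
  genes <- sprintf("G%02d", 1:12)
  xc <- matrix(rnorm(12 * 30, 5), 12, 30,
               dimnames = list(genes, sprintf("c%02d", 1:30)))
  xp <- matrix(rnorm(12 * 10, 5), 12, 10,
               dimnames = list(genes, sprintf("p%02d", 1:10)))
  auc <- matrix(rnorm(3 * 30, 10), 3, 30,
                dimnames = list(paste0("d", 1:3), colnames(xc)))
  panel <- predict_panel_auc(xc, auc, xp, ridge_penalty = 2)
  for (d in rownames(auc))
    expect_equal(panel[d, ],
                 unclass(predict_patient_auc(xc, auc[d, ], xp,
                                             ridge_penalty = 2)),
                 tolerance = 1e-10, ignore_attr = TRUE)
})

sim_predictions <- function(seed, n_pat = 200, n_null = 20,
                            effect = -1.0) {
  set.seed(seed)
  pats <- sprintf("p%03d", seq_len(n_pat))
  lab <- setNames(rep(1:5, length.out = n_pat), pats)
  drugs <- c("HIT", sprintf("N%02d", seq_len(n_null)))
  m <- matrix(rnorm(length(drugs) * n_pat, 10, 0.5), length(drugs),
              dimnames = list(drugs, pats))
  m["HIT", lab == 3] <- m["HIT", lab == 3] + effect
  list(m = m, lab = lab)
}

test_that("the two-panel intersection keeps the planted drug only", {
  a <- sim_predictions(1)
  b <- sim_predictions(2)
  res <- rank_candidate_drugs(list(p1 = a$m, p2 = b$m), a$lab, 3)
  expect_true("HIT" %in% res$candidates)
  expect_identical(res$candidates[1], "HIT")
  # a drug present in one panel only is excluded from the intersection
  a2 <- a$m; b2 <- b$m[-2, ]
  only <- rownames(a2)[2]
  res2 <- rank_candidate_drugs(list(p1 = a2, p2 = b2), a$lab, 3)
  expect_false(only %in% res2$candidates)
  # candidate list is a subset of each panel's significant-lower list
  for (d in res$candidates) {
    pd <- res$per_drug[res$per_drug$drug == d, ]
    expect_true(all(pd$p < 0.05 & pd$direction == "lower"))
  }
})

test_that("null panels give an (almost always) empty candidate list", {
  empties <- vapply(1:10, function(s) {
    a <- sim_predictions(100 + s, effect = 0)
    b <- sim_predictions(200 + s, effect = 0)
    length(rank_candidate_drugs(list(p1 = a$m, p2 = b$m), a$lab, 3)$candidates)
  }, numeric(1))
  expect_lte(mean(empties > 0), 0.2)
})
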