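# Trinarization, driver-CpG filtering, variable-site selection and the
# shared hierarchical-clustering core.

test_that("trinarization maps the five GISTIC levels correctly", {
  m <- matrix(c(-2L, -1L, 0L, 1L, 2L, 0L), 2, 3,
              dimnames = list(c("f1", "f2"), c("a", "b", "c")))
  tr <- trinarize_gistic(m)
  expect_identical(as.vector(tr), c(-1L, -1L, 0L, 1L, 1L, 0L))
  # idempotent and value-set closed
  expect_identical(trinarize_gistic(tr), tr)
  z <- matrix(0L, 3, 3)
  expect_identical(trinarize_gistic(z), z)
  bad <- m; bad[1, 1] <- 3L
  expect_error(trinarize_gistic(bad), "f1")
})

make_filter_fixture <- function() {
  # 4 probes x 100 tumors, 20 normals
  tumors <- sprintf("t%03d", 1:100)
  normals <- sprintf("n%02d", 1:20)
  bt <- matrix(0.05, 4, 100, dimnames = list(paste0("p", 1:4), tumors))
  bn <- matrix(0.05, 4, 20, dimnames = list(paste0("p", 1:4), normals))
  # p1: methylated in 12/100 tumors, clean normals, autosomal -> retained
  bt["p1", 1:12] <- 0.8
  # p2: like p1 but on chrX -> removed under (c)
  bt["p2", 1:12] <- 0.8
  # p3: methylated in exactly 10/100 tumors (10% not strictly more) -> fails (b)
  bt["p3", 1:10] <- 0.8
  # p4: methylated normals -> fails (a)
  bt["p4", 1:50] <- 0.8
  bn["p4", ] <- 0.6
  ann <- data.frame(probe = paste0("p", 1:4),
                    chromosome = c("chr2", "chrX", "chr3", "chr4"),
                    snp_overlap = FALSE, gene = NA)
  list(bt = bt, bn = bn, ann = ann)
}

test_that("the three-criterion CpG filter retains exactly the right probes", {
  fx <- make_filter_fixture()
  rep <- filter_driver_cpgs(fx$bt, fx$bn, fx$ann)
  expect_identical(rep$retained, "p1")
  expect_equal(rep$n_input, 4)
  expect_equal(rep$n_retained, 1)
  expect_equal(unname(rep$first_failure["p2"]), "c_sex_or_snp")
  expect_equal(unname(rep$first_failure["p3"]), "b_tumor")
  expect_equal(unname(rep$first_failure["p4"]), "a_normal")
  # order independence: permuting probe rows leaves the retained set equal
  perm <- c(3, 1, 4, 2)
  rep2 <- filter_driver_cpgs(fx$bt[perm, ], fx$bn[perm, ], fx$ann)
  expect_setequal(rep2$retained, rep$retained)
  # missing annotation is an error
  expect_error(filter_driver_cpgs(fx$bt, fx$bn, fx$ann[-1, ]), "p1")
})

test_that("normal-criterion boundaries are honored", {
  # mean normal beta 0.1, zero normals above 0.3, 12% of tumors above 0.3:
  # retained under the quoted thresholds
  bt <- matrix(0.05, 1, 100, dimnames = list("p1", sprintf("t%03d", 1:100)))
  bt[1, 1:12] <- 0.9
  bn <- matrix(0.1, 1, 20, dimnames = list("p1", sprintf("n%02d", 1:20)))
  ann <- data.frame(probe = "p1", chromosome = "chr1", snp_overlap = FALSE)
  expect_identical(filter_driver_cpgs(bt, bn, ann)$retained, "p1")
  # exactly 6 normals above the 0.3 cut breaks the "no more than 5" clause
  bn6 <- bn; bn6[1, 1:6] <- 0.35
  expect_length(filter_driver_cpgs(bt, bn6, ann)$retained, 0)
  bn5 <- bn; bn5[1, 1:5] <- 0.35
  expect_identical(filter_driver_cpgs(bt, bn5, ann)$retained, "p1")
})

test_that("variable-site selection ranks by variance with id tie-break", {
  bt <- rbind(a = c(0.1, 0.7, 0.1, 0.7), b = c(0.4, 0.42, 0.4, 0.42),
              c = rep(0.3, 4), d = rep(0.3, 4))
  colnames(bt) <- paste0("t", 1:4)
  expect_identical(select_top_variable_sites(bt, rownames(bt), 2),
                   c("a", "b"))
  # identity selection at n = retained count
  expect_setequal(select_top_variable_sites(bt, rownames(bt), 4),
                  rownames(bt))
  # constant probes: returned in id order with a zero-variance flag
  sel <- select_top_variable_sites(bt, c("c", "d"), 2)
  expect_identical(as.vector(sel), c("c", "d"))
  expect_setequal(attr(sel, "zero_variance"), c("c", "d"))
  expect_error(select_top_variable_sites(bt, rownames(bt), 10), "exceeds")
})

test_that("hierarchical clustering separates planted structure exactly", {
  set.seed(6)
  centers <- matrix(c(0, 0, 0, 0, 0,
                      8, 8, 0, 0, 0,
                      0, 0, 8, 8, 8), 3, byrow = TRUE)
  lab_true <- rep(1:3, each = 20)
  x <- t(centers[lab_true, ] + matrix(rnorm(60 * 5, 0, 0.5), 60))
  colnames(x) <- sprintf("s%02d", 1:60)
  ca <- hierarchical_cluster(x, k = 3, linkage = "ward")
  expect_equal(adjusted_rand_index(ca$labels, lab_true), 1)
  # duplicated samples co-cluster
  dup <- cbind(x, x)
  colnames(dup) <- sprintf("s%03d", 1:120)
  cd <- hierarchical_cluster(dup, k = 3, linkage = "ward")
  expect_identical(unname(cd$labels[1:60]), unname(cd$labels[61:120]))
  # k = n gives singletons
  small <- x[, 1:5]
  expect_equal(hierarchical_cluster(small, k = 5)$k, 5)
  # missing values are a hard error
  xna <- x; xna[1, 1] <- NA
  expect_error(hierarchical_cluster(xna, k = 2), "missing")
  expect_error(hierarchical_cluster(x, k = 1), "k must")
})

test_that("labels are numbered by first occurrence", {
  x <- rbind(c(0, 0, 5, 5, 0), c(0, 0, 5, 5, 0))
  colnames(x) <- paste0("s", 1:5)
  ca <- hierarchical_cluster(x, k = 2)
  expect_equal(unname(ca$labels), c(1L, 1L, 2L, 2L, 1L))
})

test_that("silhouette-based k selection finds planted blob counts", {
  set.seed(8)
  centers <- matrix(rnorm(4 * 6, 0, 8), 4, 6)
  lab_true <- rep(1:4, each = 15)
  x <- t(centers[lab_true, ] + matrix(rnorm(60 * 6, 0, 0.4), 60))
  colnames(x) <- sprintf("s%02d", 1:60)
  k <- choose_k(x, k_range = 2:8, linkage = "ward")
  expect_equal(as.integer(k), 4)
  # restricted range
  two <- x[, lab_true <= 2]
  expect_equal(as.integer(choose_k(two, k_range = 2)), 2)
  # permutation invariance of the silhouette profile
  perm <- sample(ncol(x))
  k2 <- choose_k(x[, perm], k_range = 2:8, linkage = "ward")
  expect_equal(attr(k2, "silhouette"), attr(k, "silhouette"))
  # degenerate identical samples
  const <- matrix(1, 4, 10, dimnames = list(NULL, paste0("s", 1:10)))
  expect_error(choose_k(const), "identical")
})
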