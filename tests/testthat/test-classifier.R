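# Classifier stage: stratified splitting, lasso selection hygiene,
# harmonization, training across algorithms and prediction.

test_that("stratified splits preserve proportions and determinism", {
  samples <- sprintf("s%03d", 1:100)
  labels <- rep(c("focal", "other"), c(30, 70))
  sp <- split_cohort(samples, labels, 0.8, seed = 4)
  expect_length(sp$train, 80)
  expect_length(sp$validation, 20)
  tr_lab <- labels[match(sp$train, samples)]
  expect_lte(abs(sum(tr_lab == "focal") - 24), 1)
  expect_identical(split_cohort(samples, labels, 0.8, seed = 4), sp)
  expect_false(identical(split_cohort(samples, labels, 0.8, seed = 5), sp))
  expect_error(split_cohort(samples[1:3], c("a", "a", "b"), 0.8), "2 samples")
})

sim_lasso_data <- function(n = 300, p_noise = 490, n_info = 10, seed = 31) {
  set.seed(seed)
  x <- matrix(rnorm((n_info + p_noise) * n), n_info + p_noise, n,
              dimnames = list(sprintf("G%03d", seq_len(n_info + p_noise)),
                              sprintf("s%03d", seq_len(n))))
  eta <- colSums(x[seq_len(n_info), , drop = FALSE] * 2.0)
  y <- rbinom(n, 1, plogis(eta))
  list(x = x, y = factor(ifelse(y == 1, "focal", "other")),
       informative = rownames(x)[seq_len(n_info)])
}

test_that("lasso finds informative genes under the auto penalty", {
  d <- sim_lasso_data()
  sel <- lasso_select_features(d$x, d$y, penalty = "auto", cv_repeats = 5,
                               seed = 7)
  expect_gte(sum(d$informative %in% sel), 9)
  expect_lte(sum(!sel %in% d$informative), 20)
})

test_that("a strong penalty on null labels selects almost nothing", {
  set.seed(9)
  x <- matrix(rnorm(100 * 120), 100, 120,
              dimnames = list(sprintf("G%03d", 1:100),
                              sprintf("s%03d", 1:120)))
  y <- factor(rep(c("focal", "other"), 60))
  sel <- lasso_select_features(x, y, penalty = 0.5)
  expect_lte(length(sel), 2)
  # constant genes are excluded before the fit, with a log
  x2 <- rbind(x, CONST = 1)
  sel2 <- lasso_select_features(x2, y, penalty = 0.5)
  expect_identical(attr(sel2, "excluded"), "CONST")
})

test_that("the default lasso penalty constant is 0.0015", {
  expect_equal(eval(formals(lasso_select_features)$penalty), 0.0015)
})

test_that("harmonization removes per-gene location shifts and is
           idempotent", {
  set.seed(10)
  ref <- matrix(rnorm(30 * 40, 6, 2), 30, 40,
                dimnames = list(sprintf("G%02d", 1:30),
                                sprintf("r%02d", 1:40)))
  shift <- rnorm(30, 0, 3)
  tgt <- ref + shift
  colnames(tgt) <- sprintf("t%02d", 1:40)
  h <- harmonize_cohorts(ref, tgt)
  expect_equal(unname(h$reference), unname(h$target), tolerance = 1e-12)
  # same cohort twice: identical outputs
  h2 <- harmonize_cohorts(ref, ref)
  expect_equal(h2$reference, h2$target)
  # idempotence
  h3 <- harmonize_cohorts(h$reference, h$target)
  expect_equal(h3$reference, h$reference, tolerance = 1e-12)
  expect_equal(h3$target, h$target, tolerance = 1e-12)
  # output genes are the intersection
  h4 <- harmonize_cohorts(ref, tgt[1:20, ])
  expect_identical(h4$genes, rownames(ref)[1:20])
  expect_error(harmonize_cohorts(ref, tgt[1:3, ]), "intersection")
})

sep_data <- function(n = 60, seed = 12) {
  set.seed(seed)
  x <- matrix(rnorm(5 * n), 5, n,
              dimnames = list(paste0("G", 1:5), sprintf("s%03d", 1:n)))
  y <- factor(rep(c("focal", "other"), each = n / 2))
  x[1, y == "focal"] <- x[1, y == "focal"] + 8   # separable coordinate
  list(x = x, y = setNames(y, colnames(x)))
}

test_that("linearly separable classes are fit perfectly by LR and LDA", {
  d <- sep_data()
  for (m in c("logistic", "lda")) {
    fit <- train_classifier(d$x, d$y, method = m)
    expect_equal(fit$training_accuracy, 1.0)
  }
  expect_error(train_classifier(d$x, d$y, method = "boosting"),
               "valid methods")
})

test_that("the neural-net hyperparameter record keeps the configured
           values", {
  ctrl <- nn_control()
  expect_equal(ctrl$batch_size, 200)
  expect_equal(ctrl$epochs, 50)
  expect_equal(ctrl$learning_rate, 0.001)
  expect_equal(ctrl$hidden, c(500, 1500, 1700))
  d <- sep_data()
  small <- nn_control(hidden = c(16, 8), epochs = 150, batch_size = 16,
                      learning_rate = 0.01)
  fit <- train_classifier(d$x, d$y, method = "neural_net",
                          hyperparams = list(nn = small), seed = 2)
  expect_identical(fit$hyperparams$hidden, c(16, 8))
  expect_gte(fit$training_accuracy, 0.9)
})

test_that("label-permuted training stays at the majority baseline", {
  set.seed(14)
  n <- 200
  x <- matrix(rnorm(20 * n), 20, n,
              dimnames = list(paste0("G", 1:20), sprintf("s%03d", 1:n)))
  y <- setNames(factor(rep(c("focal", "other"), each = n / 2)), colnames(x))
  sp <- split_cohort(colnames(x), as.character(y), 0.8, seed = 3)
  fit <- train_classifier(x[, sp$train], y[sp$train], method = "lda")
  pred <- predict_subtype(fit, x[, sp$validation])
  acc <- mean(pred$label == as.character(y[sp$validation]))
  baseline <- 0.5
  se <- sqrt(0.25 / length(sp$validation))
  expect_lt(abs(acc - baseline), 3 * se + 1e-9)
})

test_that("prediction is deterministic and checks its inputs", {
  d <- sep_data()
  fit <- train_classifier(d$x, d$y, method = "logistic")
  pred <- predict_subtype(fit, d$x)
  expect_equal(mean(pred$label == as.character(d$y)),
               fit$training_accuracy)
  # identical samples receive identical labels
  two <- d$x[, c(1, 1)]
  colnames(two) <- c("a", "b")
  p2 <- predict_subtype(fit, two)
  expect_identical(p2$label[1], p2$label[2])
  expect_error(predict_subtype(fit, d$x[-1, ]), "missing selected genes")
})

test_that("feature selection sees only the training partition", {
  d <- sim_lasso_data(n = 150, p_noise = 50, seed = 41)
  sp <- split_cohort(colnames(d$x), as.character(d$y), 0.8, seed = 5)
  sel1 <- lasso_select_features(d$x[, sp$train], d$y[match(sp$train,
                                                           colnames(d$x))],
                                penalty = 0.02, seed = 6)
  # replace the validation columns by pure noise: selection is unchanged
  x2 <- d$x
  x2[, sp$validation] <- rnorm(length(x2[, sp$validation]))
  sel2 <- lasso_select_features(x2[, sp$train], d$y[match(sp$train,
                                                          colnames(d$x))],
                                penalty = 0.02, seed = 6)
  expect_identical(sel1, sel2)
})

test_that("the comparison report ranks methods and picks the argmax", {
  d <- sep_data(n = 80, seed = 15)
  sp <- split_cohort(colnames(d$x), as.character(d$y), 0.75, seed = 8)
  cmp <- compare_classifiers(d$x, d$y, sp,
                             methods = c("logistic", "lda", "cart"))
  expect_equal(nrow(cmp$comparison), 3)
  expect_true(!is.unsorted(rev(cmp$comparison$validation_accuracy)))
  expect_identical(cmp$best_method, cmp$comparison$method[1])
  expect_s3_class(cmp$best_model, "coca_classifier")
})

test_that("held-out samples from the same process are classified well", {
  cfg <- synthetic_config(n_samples = 240, n_probes = 150,
                          meth_program_size = 5, n_noise_genes = 60,
                          seed = 33)
  coh <- generate_cohort(cfg)
  y <- setNames(factor(ifelse(coh$truth$subtype == 3, "focal", "other")),
                coh$sample_ids)
  sp <- split_cohort(coh$sample_ids, as.character(y), 0.8, seed = 9)
  genes <- lasso_select_features(coh$expression[, sp$train],
                                 y[sp$train], penalty = 0.0015, seed = 10)
  fit <- train_classifier(coh$expression[genes, sp$train], y[sp$train],
                          method = "lda")
  pred <- predict_subtype(fit, coh$expression[genes, sp$validation])
  expect_gte(mean(pred$label == as.character(y[sp$validation])), 0.95)
})
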