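# Expression classifier separating the focal subtype (COCA3 analog) from the
# merged remaining subtypes: stratified splitting, lasso feature selection,
# cohort harmonization, multi-algorithm training and prediction.

#' Stratified train/validation split
#'
#' Splits samples into training and validation sets preserving class
#' proportions within rounding (+-1 sample per class); deterministic per
#' seed.
#'
#' @param samples character sample ids.
#' @param labels class labels aligned with `samples`.
#' @param train_fraction fraction in (0,1) (default 0.8).
#' @param seed integer seed.
#' @return List with `train` and `validation` sample id vectors.
#' @export
split_cohort <- function(samples, labels, train_fraction = 0.8, seed = 1) {
  stopifnot(length(samples) == length(labels),
            train_fraction > 0, train_fraction < 1)
  if (any(table(labels) < 2))
    stop("every class needs at least 2 samples to split")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  train <- character(0)
  for (cl in unique(labels)) {
    ids <- samples[labels == cl]
    n_tr <- max(1L, min(length(ids) - 1L, round(train_fraction * length(ids))))
    train <- c(train, sample(ids, n_tr))
  }
  list(train = sort(train), validation = sort(setdiff(samples, train)))
}

#' Lasso feature selection for the binary subtype classifier
#'
#' Genes are standardized (per gene) and an L1-penalized logistic model is
#' fitted with \pkg{glmnet}; the selected features are the genes with
#' nonzero coefficients at the given penalty. With `penalty = "auto"` the
#' penalty is chosen by repeated k-fold cross-validated misclassification
#' error averaged over `cv_repeats` fold assignments, under the
#' one-standard-error rule (the sparsest penalty within one SE of the
#' minimum); near-separable cohorts make deviance-based selection collapse
#' to a vanishing penalty, which the error/1-SE combination avoids.
#' Constant-expression genes are excluded before fitting and listed in the
#' `excluded` attribute.
#'
#' @param expression gene x sample matrix (training samples only).
#' @param labels binary labels aligned with the columns.
#' @param penalty numeric lasso penalty (default 0.0015) or `"auto"`.
#' @param cv_folds,cv_repeats cross-validation controls for `"auto"`.
#' @param seed integer seed.
#' @return Character vector of selected genes ordered by decreasing absolute
#'   coefficient, with attributes `penalty` and `excluded`.
#' @export
lasso_select_features <- function(expression, labels, penalty = 0.0015,
                                  cv_folds = 5, cv_repeats = 100, seed = 1) {
  x <- as.matrix(expression)
  y <- factor(labels)
  stopifnot(nlevels(y) == 2, ncol(x) == length(y))
  sds <- apply(x, 1, stats::sd)
  excluded <- rownames(x)[sds == 0]
  x <- x[sds > 0, , drop = FALSE]
  xs <- t((x - rowMeans(x)) / apply(x, 1, stats::sd))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (identical(penalty, "auto")) {
    path_fit <- glmnet::glmnet(xs, y, family = "binomial", alpha = 1,
                               standardize = FALSE)
    lambda <- path_fit$lambda
    n <- nrow(xs)
    cvm <- cvsd <- matrix(NA_real_, cv_repeats, length(lambda))
    for (r in seq_len(cv_repeats)) {
      foldid <- sample(rep_len(seq_len(cv_folds), n))
      cv <- glmnet::cv.glmnet(xs, y, family = "binomial", alpha = 1,
                              standardize = FALSE, lambda = lambda,
                              foldid = foldid, type.measure = "class")
      at <- match(lambda, cv$lambda)
      cvm[r, ] <- cv$cvm[at]
      cvsd[r, ] <- cv$cvsd[at]
    }
    mean_cvm <- colMeans(cvm, na.rm = TRUE)
    mean_cvsd <- colMeans(cvsd, na.rm = TRUE)
    # one-standard-error rule on the repeat-averaged error curve: the
    # sparsest penalty whose error is within one SE of the minimum
    best <- which.min(mean_cvm)
    ok <- which(mean_cvm <= mean_cvm[best] + mean_cvsd[best])
    penalty <- max(lambda[ok], na.rm = TRUE)
  }
  stopifnot(is.numeric(penalty), penalty > 0)
  lam_path <- sort(unique(c(exp(seq(log(max(penalty * 100, 1)),
                                    log(penalty), length.out = 40)),
                            penalty)), decreasing = TRUE)
  fit <- glmnet::glmnet(xs, y, family = "binomial", alpha = 1,
                        standardize = FALSE, lambda = lam_path)
  cf <- as.matrix(fit$beta[, which.min(abs(fit$lambda - penalty))])[, 1]
  sel <- cf[cf != 0]
  out <- names(sel)[order(-abs(sel))]
  attr(out, "penalty") <- penalty
  attr(out, "excluded") <- excluded
  out
}

#' Harmonize two expression cohorts
#'
#' Restricts both cohorts to their gene intersection and standardizes each
#' gene to mean 0 and variance 1 within each cohort - a deterministic
#' location/scale batch alignment. Idempotent: harmonizing an already
#' harmonized cohort is the identity.
#'
#' @param reference_expression,target_expression gene x sample matrices.
#' @param min_genes smallest acceptable gene intersection (default 10).
#' @return List with `reference`, `target` (harmonized matrices) and
#'   `genes`.
#' @export
harmonize_cohorts <- function(reference_expression, target_expression,
                              min_genes = 10) {
  genes <- intersect(rownames(reference_expression),
                     rownames(target_expression))
  if (length(genes) < min_genes)
    stop(sprintf("gene intersection too small (%d < %d)", length(genes),
                 min_genes))
  zscore <- function(m) {
    m <- m[genes, , drop = FALSE]
    mu <- rowMeans(m)
    sd_ <- apply(m, 1, stats::sd)
    sd_[sd_ == 0] <- 1
    (m - mu) / sd_
  }
  list(reference = zscore(reference_expression),
       target = zscore(target_expression),
       genes = genes)
}

#' Neural-network training control
#'
#' Defaults follow the fully connected architecture used for the subtype
#' classifier: hidden widths 500, 1500 and 1700, two output categories,
#' batch size 200, 50 epochs, Adam with learning rate 0.001.
#'
#' @param hidden integer vector of hidden-layer widths.
#' @param batch_size,epochs,learning_rate training hyperparameters.
#' @return A list of class `nn_control`.
#' @export
nn_control <- function(hidden = c(500, 1500, 1700), batch_size = 200,
                       epochs = 50, learning_rate = 0.001) {
  structure(list(hidden = hidden, batch_size = batch_size, epochs = epochs,
                 learning_rate = learning_rate), class = "nn_control")
}

# Minimal fully connected network with ReLU hidden layers, softmax output
# and Adam updates; sufficient for the expression-classifier comparison.
mlp_fit <- function(x, y, control, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- nrow(x); p <- ncol(x)
  classes <- levels(y)
  t_onehot <- cbind(y == classes[1], y == classes[2]) * 1
  dims <- c(p, control$hidden, 2L)
  L <- length(dims) - 1L
  W <- lapply(seq_len(L), function(l)
    matrix(stats::rnorm(dims[l] * dims[l + 1], 0, sqrt(2 / dims[l])),
           dims[l], dims[l + 1]))
  b <- lapply(seq_len(L), function(l) rep(0, dims[l + 1]))
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(bb) bb * 0); vb <- mb
  lr <- control$learning_rate; beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  bs <- min(control$batch_size, n)
  for (epoch in seq_len(control$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      a <- list(x[idx, , drop = FALSE])
      for (l in seq_len(L)) {
        z <- a[[l]] %*% W[[l]] + matrix(b[[l]], length(idx), dims[l + 1],
                                        byrow = TRUE)
        a[[l + 1]] <- if (l < L) pmax(z, 0) else z
      }
      logits <- a[[L + 1]]
      m_ <- apply(logits, 1, max)
      ex <- exp(logits - m_)
      probs <- ex / rowSums(ex)
      delta <- (probs - t_onehot[idx, , drop = FALSE]) / length(idx)
      step <- step + 1L
      for (l in rev(seq_len(L))) {
        gW <- crossprod(a[[l]], delta)
        gb <- colSums(delta)
        if (l > 1) {
          delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
        }
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        mW_hat <- mW[[l]] / (1 - beta1^step)
        vW_hat <- vW[[l]] / (1 - beta2^step)
        mb_hat <- mb[[l]] / (1 - beta1^step)
        vb_hat <- vb[[l]] / (1 - beta2^step)
        W[[l]] <- W[[l]] - lr * mW_hat / (sqrt(vW_hat) + eps)
        b[[l]] <- b[[l]] - lr * mb_hat / (sqrt(vb_hat) + eps)
      }
    }
  }
  list(W = W, b = b, classes = classes, dims = dims)
}

mlp_predict_prob <- function(fit, x) {
  a <- x
  L <- length(fit$W)
  for (l in seq_len(L)) {
    z <- a %*% fit$W[[l]] + matrix(fit$b[[l]], nrow(a), ncol(fit$W[[l]]),
                                   byrow = TRUE)
    a <- if (l < L) pmax(z, 0) else z
  }
  ex <- exp(a - apply(a, 1, max))
  probs <- ex / rowSums(ex)
  colnames(probs) <- fit$classes
  probs
}

#' Train a binary subtype classifier
#'
#' Fits one of the supported algorithms on the selected genes:
#' `"neural_net"` (fully connected network, see [nn_control()]), `"svm"`
#' (radial kernel), `"logistic"`, `"knn"`, `"lda"`, `"naive_bayes"`, or
#' `"cart"`.
#'
#' @param expression gene x sample training matrix restricted to the
#'   selected genes.
#' @param labels binary class labels aligned with the columns.
#' @param method one of the method names above.
#' @param hyperparams method-specific controls: `nn` (an [nn_control()]),
#'   `knn_k` (default 5), `svm_cost` (default 1).
#' @param seed integer seed (neural net initialization and shuffling).
#' @return A `coca_classifier` with the fitted model, the gene order, the
#'   class levels and the training accuracy.
#' @export
train_classifier <- function(expression, labels,
                             method = c("neural_net", "svm", "logistic",
                                        "knn", "lda", "naive_bayes", "cart"),
                             hyperparams = list(), seed = 1) {
  if (!is.character(method) || !method[1] %in%
      c("neural_net", "svm", "logistic", "knn", "lda", "naive_bayes", "cart"))
    stop(paste("unknown method; valid methods:",
               "neural_net, svm, logistic, knn, lda, naive_bayes, cart"))
  method <- method[1]
  x <- t(as.matrix(expression))
  y <- factor(labels)
  stopifnot(nlevels(y) == 2, nrow(x) == length(y))
  ctrl <- hyperparams$nn %||% nn_control()
  fit <- switch(
    method,
    neural_net = mlp_fit(x, y, ctrl, seed = seed),
    svm = e1071::svm(x, y, kernel = "radial",
                     cost = hyperparams$svm_cost %||% 1,
                     probability = TRUE),
    logistic = suppressWarnings(stats::glm(y ~ ., family = stats::binomial(),
                                           data = data.frame(y = y, x))),
    knn = list(train = x, y = y, k = hyperparams$knn_k %||% 5),
    lda = MASS::lda(x, grouping = y),
    naive_bayes = e1071::naiveBayes(x, y),
    cart = rpart::rpart(y ~ ., data = data.frame(y = y, x),
                        method = "class"))
  model <- structure(list(method = method, fit = fit,
                          genes = rownames(expression),
                          levels = levels(y),
                          hyperparams = if (method == "neural_net") ctrl else
                            hyperparams,
                          seed = seed),
                     class = "coca_classifier")
  pred <- predict_subtype(model, expression)
  model$training_accuracy <- mean(pred$label == as.character(y))
  model
}

#' @export
print.coca_classifier <- function(x, ...) {
  cat(sprintf("<coca_classifier> method=%s, %d genes, training accuracy %.3f\n",
              x$method, length(x$genes), x$training_accuracy %||% NA))
  invisible(x)
}

#' Predict subtype membership for new samples
#'
#' @param model a `coca_classifier`.
#' @param expression gene x sample matrix containing all of the model's
#'   genes (harmonized against the training reference where applicable).
#' @return Data frame (sample, label, score); `score` is the probability of
#'   the second class level.
#' @export
predict_subtype <- function(model, expression) {
  stopifnot(inherits(model, "coca_classifier"))
  missing <- setdiff(model$genes, rownames(expression))
  if (length(missing))
    stop(sprintf("missing selected genes: %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  x <- t(as.matrix(expression[model$genes, , drop = FALSE]))
  lv <- model$levels
  score <- switch(
    model$method,
    neural_net = mlp_predict_prob(model$fit, x)[, lv[2]],
    svm = {
      pr <- attr(stats::predict(model$fit, x, probability = TRUE),
                 "probabilities")
      pr[, lv[2]]
    },
    logistic = stats::predict(model$fit, newdata = data.frame(x),
                              type = "response"),
    knn = {
      pr <- class::knn(model$fit$train, x, model$fit$y, k = model$fit$k,
                       prob = TRUE)
      p_win <- attr(pr, "prob")
      ifelse(pr == lv[2], p_win, 1 - p_win)
    },
    lda = stats::predict(model$fit, x)$posterior[, lv[2]],
    naive_bayes = stats::predict(model$fit, x, type = "raw")[, lv[2]],
    cart = stats::predict(model$fit, newdata = data.frame(x),
                          type = "prob")[, lv[2]])
  label <- ifelse(score > 0.5, lv[2], lv[1])
  data.frame(sample = colnames(expression), label = unname(label),
             score = unname(score), stringsAsFactors = FALSE)
}

#' Train and rank all classification algorithms
#'
#' Trains each method on the training partition, evaluates on the
#' validation partition, and selects the method with the highest validation
#' accuracy.
#'
#' @param expression gene x sample matrix (selected genes).
#' @param labels binary labels named by sample.
#' @param split list with `train` and `validation` ids (see
#'   [split_cohort()]).
#' @param methods methods to compare (default all seven).
#' @param hyperparams,seed passed to [train_classifier()].
#' @return List with `comparison` (data frame ranked by validation
#'   accuracy), `best_method` and `best_model`.
#' @export
compare_classifiers <- function(expression, labels, split,
                                methods = c("neural_net", "svm", "logistic",
                                            "knn", "lda", "naive_bayes",
                                            "cart"),
                                hyperparams = list(), seed = 1) {
  stopifnot(!is.null(names(labels)))
  xtr <- expression[, split$train, drop = FALSE]
  xva <- expression[, split$validation, drop = FALSE]
  ytr <- labels[split$train]
  yva <- labels[split$validation]
  fits <- list()
  rows <- lapply(methods, function(m) {
    fit <- train_classifier(xtr, ytr, method = m, hyperparams = hyperparams,
                            seed = seed)
    fits[[m]] <<- fit
    pred <- predict_subtype(fit, xva)
    data.frame(method = m,
               training_accuracy = fit$training_accuracy,
               validation_accuracy = mean(pred$label == as.character(yva)),
               stringsAsFactors = FALSE)
  })
  comparison <- do.call(rbind, rows)
  comparison <- comparison[order(-comparison$validation_accuracy), ]
  rownames(comparison) <- NULL
  best <- comparison$method[1]
  list(comparison = comparison, best_method = best,
       best_model = fits[[best]])
}
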