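# Two-panel drug-sensitivity screen: missingness filtering and KNN
# imputation of AUC matrices, ridge-based patient AUC prediction from
# cell-line panels, and candidate ranking in the focal subtype.

#' Filter and KNN-impute a drug x cell-line AUC matrix
#'
#' Drugs missing in strictly more than `max_missing` of the cell lines are
#' removed first (they never receive imputed values); the remaining missing
#' entries are imputed by the mean AUC of the `k_neighbors` nearest drugs,
#' with drug-drug distance the Euclidean distance over co-observed cell
#' lines (normalized per shared cell line).
#'
#' @param auc drug x cell-line matrix, `NA` for missing.
#' @param max_missing maximum tolerated missing fraction (default 0.2).
#' @param k_neighbors neighbors used for imputation (default 5).
#' @return List with `auc` (complete matrix), `removed` (drug ids),
#'   `n_imputed`, and `missing_fraction` of the input drugs.
#' @export
prepare_drug_matrix <- function(auc, max_missing = 0.2, k_neighbors = 5) {
  stopifnot(max_missing >= 0, max_missing < 1, k_neighbors >= 1)
  auc <- as.matrix(auc)
  miss <- rowMeans(is.na(auc))
  removed <- rownames(auc)[miss > max_missing]
  kept <- auc[miss <= max_missing, , drop = FALSE]
  if (any(rowSums(!is.na(kept)) == 0))
    stop("a drug has no observed entries after filtering; cannot impute")
  n_imputed <- 0L
  obs <- !is.na(kept)
  for (d in seq_len(nrow(kept))) {
    na_cols <- which(!obs[d, ])
    if (!length(na_cols)) next
    # mean squared difference over co-observed cell lines
    dists <- rep(NA_real_, nrow(kept))
    for (e in seq_len(nrow(kept))) {
      if (e == d) next
      shared <- obs[d, ] & obs[e, ]
      if (!any(shared)) next
      dists[e] <- sqrt(mean((kept[d, shared] - kept[e, shared])^2))
    }
    for (cc in na_cols) {
      cand <- which(!is.na(dists) & obs[, cc])
      if (!length(cand)) {
        kept[d, cc] <- mean(kept[d, ], na.rm = TRUE)
      } else {
        nb <- cand[order(dists[cand])][seq_len(min(k_neighbors,
                                                   length(cand)))]
        kept[d, cc] <- mean(kept[nb, cc])
      }
      n_imputed <- n_imputed + 1L
    }
  }
  list(auc = kept, removed = removed, n_imputed = n_imputed,
       missing_fraction = miss)
}

#' Predict patient AUC for one drug by ridge regression on expression
#'
#' Cell-line and patient expression are harmonized (gene intersection,
#' per-cohort per-gene standardization; see [harmonize_cohorts()]); a linear
#' ridge regression of the drug's AUC on the harmonized cell-line expression
#' is then applied to the harmonized patient expression. With
#' `ridge_penalty = "auto"` the penalty minimizes generalized
#' cross-validation (GCV) on the cell-line panel. When the harmonized gene
#' set exceeds `gene_cap`, the most variable cell-line genes are kept (the
#' reduction is recorded in the `genes_used` attribute).
#'
#' @param ccl_expression gene x cell-line matrix.
#' @param ccl_auc named numeric vector of one drug's AUC per cell line.
#' @param patient_expression gene x patient matrix.
#' @param ridge_penalty nonnegative penalty or `"auto"`.
#' @param gene_cap maximum number of genes entering the regression.
#' @return Named numeric vector of predicted AUC per patient, with
#'   attributes `penalty` and `genes_used`.
#' @export
predict_patient_auc <- function(ccl_expression, ccl_auc, patient_expression,
                                ridge_penalty = "auto", gene_cap = 1000) {
  stopifnot(!is.null(names(ccl_auc)))
  lines <- intersect(colnames(ccl_expression), names(ccl_auc))
  harm <- harmonize_cohorts(ccl_expression[, lines, drop = FALSE],
                            patient_expression)
  xr <- harm$reference; xt <- harm$target
  if (nrow(xr) > gene_cap) {
    v <- apply(xr, 1, stats::var)
    keep <- rownames(xr)[order(-v)][seq_len(gene_cap)]
    xr <- xr[keep, , drop = FALSE]
    xt <- xt[keep, , drop = FALSE]
  }
  X <- t(xr)
  y <- ccl_auc[lines]
  mu_y <- mean(y)
  yc <- y - mu_y
  sv <- svd(X)
  d <- sv$d
  uy <- crossprod(sv$u, yc)
  if (identical(ridge_penalty, "auto")) {
    grid <- 10^seq(-4, 6, length.out = 80)
    n <- nrow(X)
    gcv <- vapply(grid, function(l) {
      shrink <- d^2 / (d^2 + l)
      fitted <- sv$u %*% (shrink * uy)
      rss <- sum((yc - fitted)^2)
      df <- sum(shrink)
      n * rss / (n - df)^2
    }, numeric(1))
    ridge_penalty <- grid[which.min(gcv)]
  }
  stopifnot(is.numeric(ridge_penalty), ridge_penalty >= 0)
  beta <- sv$v %*% ((d / (d^2 + ridge_penalty)) * uy)
  pred <- drop(mu_y + t(xt) %*% beta)
  names(pred) <- colnames(patient_expression)
  attr(pred, "penalty") <- ridge_penalty
  attr(pred, "genes_used") <- rownames(xr)
  pred
}

#' Predict patient AUC for a whole drug panel
#'
#' Same model as [predict_patient_auc()], but the harmonization and the
#' singular value decomposition of the cell-line design are shared across
#' drugs, which is what makes screening hundreds of drugs cheap. The
#' per-drug GCV penalty search is unchanged.
#'
#' @inheritParams predict_patient_auc
#' @param auc drug x cell-line matrix (complete; see
#'   [prepare_drug_matrix()]).
#' @return Drug x patient matrix of predicted AUC.
#' @export
predict_panel_auc <- function(ccl_expression, auc, patient_expression,
                              ridge_penalty = "auto", gene_cap = 1000) {
  lines <- intersect(colnames(ccl_expression), colnames(auc))
  harm <- harmonize_cohorts(ccl_expression[, lines, drop = FALSE],
                            patient_expression)
  xr <- harm$reference; xt <- harm$target
  if (nrow(xr) > gene_cap) {
    v <- apply(xr, 1, stats::var)
    keep <- rownames(xr)[order(-v)][seq_len(gene_cap)]
    xr <- xr[keep, , drop = FALSE]
    xt <- xt[keep, , drop = FALSE]
  }
  X <- t(xr)
  sv <- svd(X)
  d <- sv$d
  n <- nrow(X)
  grid <- 10^seq(-4, 6, length.out = 80)
  out <- matrix(NA_real_, nrow(auc), ncol(patient_expression),
                dimnames = list(rownames(auc), colnames(patient_expression)))
  for (drug in rownames(auc)) {
    y <- auc[drug, lines]
    mu_y <- mean(y)
    yc <- y - mu_y
    uy <- crossprod(sv$u, yc)
    lam <- ridge_penalty
    if (identical(ridge_penalty, "auto")) {
      gcv <- vapply(grid, function(l) {
        shrink <- d^2 / (d^2 + l)
        rss <- sum((yc - sv$u %*% (shrink * uy))^2)
        n * rss / (n - sum(shrink))^2
      }, numeric(1))
      lam <- grid[which.min(gcv)]
    }
    beta <- sv$v %*% ((d / (d^2 + lam)) * uy)
    out[drug, ] <- drop(mu_y + t(xt) %*% beta)
  }
  out
}

#' Rank candidate drugs preferentially effective in the focal subtype
#'
#' Per panel and per drug, a two-sided rank-sum test compares predicted AUC
#' in the focal subtype against the rest; a drug is significant-lower in a
#' panel when `p < alpha` and its median AUC is lower in the focal subtype.
#' Candidates are the drugs significant-lower in every panel, sorted by the
#' maximum of their per-panel p-values; drugs present in only one panel are
#' evaluated there but excluded from the intersection.
#'
#' @param predicted_auc named list of drug x patient matrices, one per panel.
#' @param labels subtype labels named by patient.
#' @param focal_subtype the focal subtype.
#' @param alpha significance level (default 0.05).
#' @return A `drug_screen_result`: `per_drug` (drug, panel, p, direction),
#'   `candidates` (intersected, sorted), `single_panel_hits`, `panel_info`.
#' @export
rank_candidate_drugs <- function(predicted_auc, labels, focal_subtype,
                                 alpha = 0.05) {
  stopifnot(is.list(predicted_auc), length(predicted_auc) >= 1)
  panels <- names(predicted_auc) %||%
    paste0("panel", seq_along(predicted_auc))
  lab <- as_labels(labels)
  rows <- list()
  sig_lower <- stats::setNames(vector("list", length(panels)), panels)
  for (pi in seq_along(panels)) {
    m <- predicted_auc[[pi]]
    pats <- intersect(colnames(m), names(lab))
    focal <- lab[pats] == focal_subtype
    for (drug in rownames(m)) {
      a <- m[drug, pats][focal]
      b <- m[drug, pats][!focal]
      wt <- stats::wilcox.test(a, b, exact = FALSE)
      lower <- stats::median(a) < stats::median(b)
      rows[[length(rows) + 1L]] <- data.frame(
        drug = drug, panel = panels[pi], p = wt$p.value,
        statistic = unname(wt$statistic),
        direction = if (lower) "lower" else "higher",
        stringsAsFactors = FALSE)
      if (wt$p.value < alpha && lower)
        sig_lower[[pi]] <- c(sig_lower[[pi]], drug)
    }
  }
  per_drug <- do.call(rbind, rows)
  shared <- Reduce(intersect, lapply(predicted_auc, rownames))
  inter <- Reduce(intersect, lapply(sig_lower, function(s)
    intersect(s %||% character(0), shared)))
  if (length(inter)) {
    maxp <- vapply(inter, function(drug)
      max(per_drug$p[per_drug$drug == drug]), numeric(1))
    inter <- inter[order(maxp)]
  }
  singles <- setdiff(unlist(sig_lower), c(inter, shared))
  structure(list(per_drug = per_drug,
                 candidates = inter,
                 single_panel_hits = singles,
                 alpha = alpha,
                 focal_subtype = focal_subtype,
                 panel_info = data.frame(
                   panel = panels,
                   n_drugs = vapply(predicted_auc, nrow, integer(1)))),
            class = "drug_screen_result")
}

#' @export
print.drug_screen_result <- function(x, ...) {
  cat(sprintf("<drug_screen_result> focal subtype %s, alpha = %g\n",
              x$focal_subtype, x$alpha))
  cat(sprintf("candidates (lower AUC in focal subtype in all panels): %s\n",
              if (length(x$candidates)) paste(x$candidates, collapse = ", ")
              else "(none)"))
  invisible(x)
}
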