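# Mutational-signature extraction by KL-divergence NMF with consensus-based
# cophenetic rank selection, and clustering of per-sample exposures.

#' Select the NMF rank from a cophenetic-coefficient profile
#'
#' Operationalizes the rule "the rank where the cophenetic correlation
#' coefficient begins to fall". When the profile shows a cliff - a
#' rank-to-rank drop larger than `tolerance` - the selected rank is the one
#' immediately before the first cliff (small dips inside the leading
#' plateau are absorbed). When no drop exceeds the tolerance the
#' coefficient only drifts, and the selected rank is the one attaining the
#' maximum, with ties broken toward the smaller rank.
#'
#' @param cophenetic named numeric vector (names = evaluated ranks).
#' @param tolerance consecutive drop below which the coefficient is not
#'   considered to have fallen (default 0.05).
#' @return The selected rank (integer).
#' @export
select_rank_by_cophenetic <- function(cophenetic, tolerance = 0.05) {
  stopifnot(length(cophenetic) >= 1, !is.null(names(cophenetic)))
  ranks <- as.integer(names(cophenetic))
  if (length(ranks) == 1) return(ranks)
  drops <- -diff(cophenetic)
  cliff <- which(drops > tolerance)
  if (length(cliff)) ranks[min(cliff)] else ranks[which.max(cophenetic)]
}

nmf_random_init <- function(v, rank) {
  scale <- sqrt(mean(v) / rank)
  list(w = matrix(stats::runif(nrow(v) * rank, 0, 2 * scale), nrow(v), rank),
       h = matrix(stats::runif(rank * ncol(v), 0, 2 * scale), rank, ncol(v)))
}

# Cophenetic correlation of a consensus matrix: agreement between the
# average-linkage tree's cophenetic distances and 1 - consensus.
consensus_cophenetic <- function(consensus) {
  d <- stats::as.dist(1 - consensus)
  if (stats::sd(d) == 0) return(1)
  h <- stats::hclust(d, method = "average")
  stats::cor(d, stats::cophenetic(h))
}

#' Extract mutational signatures by nonnegative matrix factorization
#'
#' Factorizes the motif matrix `V (samples x 96)` as `W H` under the
#' generalized Kullback-Leibler objective with multiplicative updates (the
#' Brunet variant), at every rank in `rank_range` with `n_restarts` random
#' restarts per rank. Restarts are consensus-combined: each restart assigns
#' every sample to its dominant signature, the restart-averaged connectivity
#' matrix gives the per-rank cophenetic coefficient, and the rank is selected
#' by [select_rank_by_cophenetic()]. The best-objective factorization of the
#' selected rank is returned with signatures row-normalized to the simplex
#' and exposures rescaled so the product is preserved.
#'
#' @param motif sample x 96 nonnegative matrix (see [build_motif_matrix()]).
#' @param rank_range integer ranks to evaluate; all ranks must be >= 2 except
#'   an optional rank-1 baseline.
#' @param n_restarts random restarts per rank (>= 10; default 50).
#' @param seed master seed; restart seeds are derived at fixed offsets.
#' @param max_iter,tol multiplicative-update convergence controls.
#' @param cophenetic_tolerance tolerance of the rank-selection drop rule.
#' @return A `signature_model`: `rank`, `signatures` (rank x 96, rows sum to
#'   1), `exposures` (sample x rank), `cophenetic_by_rank`,
#'   `reconstruction_error_by_rank` (relative Frobenius, best restart),
#'   `selected_rank`, and `divergence`.
#' @export
extract_signatures <- function(motif, rank_range = 2:6, n_restarts = 50,
                               seed = 1, max_iter = 2000, tol = 1e-6,
                               cophenetic_tolerance = 0.05) {
  v <- as.matrix(motif)
  if (all(v == 0)) stop("degenerate input: all-zero motif matrix")
  if (any(v < 0)) stop("motif matrix must be nonnegative")
  if (any(rank_range >= min(nrow(v), ncol(v))))
    stop("configuration error: rank must be < min(n_samples, 96)")
  if (any(rank_range < 1) || sum(rank_range == 1) > 1 ||
      any(rank_range[rank_range != 1] < 2))
    stop("configuration error: ranks must be >= 2 (plus optional rank-1 baseline)")
  # samples with zero substitutions carry no signal; factorize the rest and
  # report zero exposures for them
  nz <- rowSums(v) > 0
  vz <- v[nz, , drop = FALSE]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  ranks <- sort(unique(as.integer(rank_range)))
  coph <- stats::setNames(numeric(length(ranks)), ranks)
  relerr <- stats::setNames(numeric(length(ranks)), ranks)
  best_fit <- vector("list", length(ranks))
  fnorm <- sqrt(sum(vz^2))
  for (ri in seq_along(ranks)) {
    r <- ranks[ri]
    consensus <- matrix(0, nrow(vz), nrow(vz))
    best <- NULL
    for (rs in seq_len(n_restarts)) {
      set.seed(derive_seed(seed, sprintf("nmf_r%d_restart%d", r, rs)))
      init <- nmf_random_init(vz, r)
      fit <- nmf_kl_cpp(vz, init$w, init$h, max_iter, tol)
      if (is.null(best) || fit$divergence < best$divergence) best <- fit
      lab <- if (r == 1) rep(1L, nrow(vz)) else
        max.col(fit$W, ties.method = "first")
      consensus <- consensus + outer(lab, lab, "==")
    }
    consensus <- consensus / n_restarts
    coph[ri] <- if (r == 1) 1 else consensus_cophenetic(consensus)
    relerr[ri] <- sqrt(sum((vz - best$W %*% best$H)^2)) / fnorm
    best_fit[[ri]] <- best
  }
  selected <- select_rank_by_cophenetic(coph, cophenetic_tolerance)
  fit <- best_fit[[match(selected, ranks)]]
  h <- fit$H
  w <- fit$W
  rs <- rowSums(h)
  rs[rs == 0] <- 1
  signatures <- sweep(h, 1, rs, "/")
  exposures_nz <- sweep(w, 2, rs, "*")
  exposures <- matrix(0, nrow(v), selected,
                      dimnames = list(rownames(v),
                                      paste0("S", seq_len(selected))))
  exposures[nz, ] <- exposures_nz
  rownames(signatures) <- paste0("S", seq_len(selected))
  colnames(signatures) <- colnames(v) %||% sbs_contexts()
  structure(list(rank = selected,
                 signatures = signatures,
                 exposures = exposures,
                 cophenetic_by_rank = coph,
                 reconstruction_error_by_rank = relerr,
                 selected_rank = selected,
                 divergence = fit$divergence,
                 rank_range = ranks,
                 n_restarts = n_restarts,
                 seed = seed),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model> selected rank %d (evaluated %s)\n",
              x$selected_rank, paste(x$rank_range, collapse = ",")))
  cat("cophenetic by rank:\n")
  print(round(x$cophenetic_by_rank, 3))
  invisible(x)
}

#' Correlate extracted signatures with a reference signature set
#'
#' Pearson correlation between each extracted signature and each reference
#' profile over the shared, identically ordered 96 contexts. Zero-variance
#' (flat) reference profiles are flagged and excluded from best-match
#' reporting rather than silently returning NA.
#'
#' @param model a `signature_model`.
#' @param reference named matrix (reference signatures x 96) with the same
#'   column order as the model's signatures.
#' @return List with `correlations` (extracted x reference Pearson r),
#'   `best_match` data frame (signature, reference, r) and `flat_references`.
#' @export
match_reference_signatures <- function(model, reference) {
  stopifnot(inherits(model, "signature_model"))
  reference <- as.matrix(reference)
  if (ncol(reference) != 96)
    stop("reference profiles must have 96 columns")
  if (!is.null(colnames(reference)) && !is.null(colnames(model$signatures)) &&
      !identical(colnames(reference), colnames(model$signatures)))
    stop("column-order mismatch between reference and extracted signatures")
  flat <- apply(reference, 1, stats::sd) == 0
  r <- matrix(NA_real_, nrow(model$signatures), nrow(reference),
              dimnames = list(rownames(model$signatures), rownames(reference)))
  for (i in seq_len(nrow(model$signatures)))
    for (j in seq_len(nrow(reference)))
      if (!flat[j])
        r[i, j] <- stats::cor(model$signatures[i, ], reference[j, ])
  usable <- which(!flat)
  best <- data.frame(
    signature = rownames(r),
    reference = rownames(reference)[usable[apply(r[, usable, drop = FALSE],
                                                 1, which.max)]],
    r = apply(r[, usable, drop = FALSE], 1, max),
    row.names = NULL)
  list(correlations = r, best_match = best,
       flat_references = rownames(reference)[flat])
}

#' Cluster samples on their signature exposures
#'
#' Agglomerative clustering with Ward.D2 linkage on Euclidean distances over
#' per-sample exposure vectors. `k = "auto"` selects the cluster number by
#' mean silhouette width over `k_range`.
#'
#' @param model a `signature_model` (or a plain sample x signature matrix).
#' @param k integer number of clusters, or `"auto"`.
#' @param k_range candidate k values for `"auto"`.
#' @param normalize if TRUE, exposures are converted to per-sample
#'   proportions before clustering (default FALSE: raw exposures).
#' @return A [cluster_assignment()] with platform `"mutation"`.
#' @export
cluster_exposures <- function(model, k = "auto", k_range = 2:8,
                              normalize = FALSE) {
  x <- if (inherits(model, "signature_model")) model$exposures else
    as.matrix(model)
  if (normalize) {
    rs <- rowSums(x)
    rs[rs == 0] <- 1
    x <- sweep(x, 1, rs, "/")
  }
  if (identical(k, "auto")) {
    k <- choose_k(t(x), k_range = k_range, linkage = "ward")
  }
  if (k > nrow(x)) stop("k exceeds the number of samples")
  hierarchical_cluster(t(x), k = k, linkage = "ward",
                       platform = "mutation")
}
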