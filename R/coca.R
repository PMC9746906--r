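# Cluster-of-clusters integration: binary membership encoding, resampled
# consensus clustering (Monti procedure) and CDF delta-area selection of K.

#' Encode platform cluster memberships as binary vectors
#'
#' One indicator column per (platform, cluster); a sample's row carries a 1
#' in exactly one column per platform, so every row sums to the number of
#' platforms. All platforms must cover the same sample set (samples need an
#' intact profile on every platform; there is no imputation).
#'
#' @param assignments named list of [cluster_assignment()]s (or named label
#'   vectors), one per platform.
#' @return Binary sample x (total clusters) matrix with columns named
#'   `platform:cluster`.
#' @export
encode_binary_membership <- function(assignments) {
  stopifnot(is.list(assignments), length(assignments) >= 1)
  platforms <- names(assignments) %||%
    paste0("platform", seq_along(assignments))
  labs <- lapply(assignments, as_labels)
  samples <- names(labs[[1]])
  for (i in seq_along(labs)) {
    miss <- union(setdiff(samples, names(labs[[i]])),
                  setdiff(names(labs[[i]]), samples))
    if (length(miss))
      stop(sprintf("samples missing from some platform: %s",
                   paste(utils::head(miss, 5), collapse = ", ")))
  }
  blocks <- lapply(seq_along(labs), function(i) {
    l <- labs[[i]][samples]
    lev <- sort(unique(l))
    b <- outer(l, lev, "==") * 1
    colnames(b) <- paste0(platforms[i], ":", lev)
    b
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- samples
  out
}

#' Resampled consensus clustering of the binary membership matrix
#'
#' The Monti consensus procedure: in each repetition a fraction of samples is
#' drawn without replacement and clustered by average-linkage hierarchical
#' clustering on Euclidean distances; co-assignment counts are accumulated
#' over repetitions, and `consensus(i,j)` is the co-clustered count divided
#' by the co-sampled count (0/0 treated as 0 and flagged). Final labels at
#' each K come from average-linkage clustering of `1 - consensus`. The
#' integrated cluster number is chosen by [select_k_by_cdf()].
#'
#' @param binary sample x feature matrix (see [encode_binary_membership()];
#'   any numeric matrix is accepted).
#' @param k_range candidate cluster numbers (within `[2, n-1]`).
#' @param item_fraction subsampling fraction in `(0, 1]` (default 0.8).
#' @param repetitions number of resampling repetitions (>= 50; default 1000).
#' @param seed integer seed.
#' @param delta_threshold,rule passed to [select_k_by_cdf()].
#' @return A `coca_result`: `consensus` (list of per-K matrices), `cdf_area`,
#'   `delta_area`, `selected_k`, `labels` (at the selected K, named by
#'   sample), `labels_by_k`, and the resampling settings.
#' @export
consensus_cluster <- function(binary, k_range = 2:8, item_fraction = 0.8,
                              repetitions = 1000, seed = 1,
                              delta_threshold = 0.05,
                              rule = c("largest", "elbow")) {
  rule <- match.arg(rule)
  x <- as.matrix(binary)
  n <- nrow(x)
  if (item_fraction <= 0 || item_fraction > 1)
    stop("configuration error: item_fraction must lie in (0, 1]")
  if (repetitions < 50)
    stop("configuration error: repetitions must be >= 50")
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > n - 1))
    stop("k_range must lie within [2, n-1]")
  ids <- rownames(x) %||% sprintf("sample%d", seq_len(n))
  if (anyDuplicated(ids)) stop("sample ids must be unique")
  # canonical sample order: the resampling stream attaches to sorted ids,
  # so permuting the input rows cannot change the consensus estimates
  ord <- order(ids)
  x <- x[ord, , drop = FALSE]
  ids_c <- ids[ord]
  m <- ceiling(item_fraction * n)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  count <- matrix(0, n, n)
  conn <- lapply(k_range, function(k) matrix(0, n, n))
  names(conn) <- k_range
  for (rep_i in seq_len(repetitions)) {
    idx <- sample.int(n, m)
    d <- stats::dist(x[idx, , drop = FALSE])
    h <- stats::hclust(d, method = "average")
    cuts <- stats::cutree(h, k = k_range)
    if (is.null(dim(cuts))) cuts <- matrix(cuts, ncol = 1)
    # count co-sampling once per repetition (alongside the first K)
    for (ki in seq_along(k_range)) {
      accumulate_consensus_cpp(conn[[ki]], count, idx - 1L,
                               as.integer(cuts[, ki]),
                               update_count = (ki == 1L))
    }
  }
  never <- sum(count[upper.tri(count)] == 0)
  if (never > 0)
    warning(sprintf("%d sample pair(s) never co-sampled; consensus set to 0",
                    never))
  consensus <- lapply(conn, function(cm) {
    out <- cm / pmax(count, 1)
    out[count == 0] <- 0
    diag(out) <- 1
    dimnames(out) <- list(ids_c, ids_c)
    out
  })
  area <- vapply(consensus, consensus_cdf_area, numeric(1))
  names(area) <- k_range
  labels_by_k <- lapply(seq_along(k_range), function(ki) {
    h <- stats::hclust(stats::as.dist(1 - consensus[[ki]]),
                       method = "average")
    lab <- stats::cutree(h, k = k_range[ki])
    names(lab) <- ids_c
    # report in input order, renumbered by first occurrence there
    lab <- lab[ids]
    lab <- stats::setNames(relabel_first_occurrence(lab), ids)
    lab
  })
  names(labels_by_k) <- k_range
  consensus <- lapply(consensus, function(cm) cm[ids, ids])
  res <- structure(list(consensus = consensus,
                        cdf_area = area,
                        delta_area = NULL,
                        selected_k = NULL,
                        labels = NULL,
                        labels_by_k = labels_by_k,
                        k_range = k_range,
                        item_fraction = item_fraction,
                        repetitions = repetitions,
                        seed = seed,
                        never_cosampled_pairs = never),
                   class = "coca_result")
  sel <- select_k_by_cdf(res, threshold = delta_threshold, rule = rule)
  res$selected_k <- as.integer(sel)
  res$delta_area <- attr(sel, "delta")
  res$labels <- labels_by_k[[as.character(sel)]]
  res
}

# Area under the empirical CDF of the off-diagonal consensus entries
# (trapezoid-free form: sum over sorted unique values of step widths times
# the CDF, the standard consensus-clustering area).
consensus_cdf_area <- function(cm) {
  v <- sort(cm[upper.tri(cm)])
  if (!length(v)) return(0)
  xs <- sort(unique(c(0, v, 1)))
  cdf <- findInterval(xs, v) / length(v)  # counts of v <= x (v is sorted)
  sum(diff(xs) * cdf[-length(xs)])
}

#' Select the integrated cluster number from consensus CDF areas
#'
#' The relative change in the area under the consensus CDF,
#' `delta(K) = (A(K) - A(K-1)) / A(K-1)` for K above the smallest evaluated
#' value. Under the default `"largest"` rule the selected K is the largest K
#' whose delta is at least `threshold`; if no K passes, the smallest
#' evaluated K is returned. The `"elbow"` alternative returns the K
#' maximizing delta.
#'
#' @param result a `coca_result` (or a named numeric vector of areas).
#' @param threshold relative-increase threshold (default 0.05).
#' @param rule `"largest"` or `"elbow"`.
#' @return Selected K with attribute `delta` (the delta profile).
#' @export
select_k_by_cdf <- function(result, threshold = 0.05,
                            rule = c("largest", "elbow")) {
  rule <- match.arg(rule)
  area <- if (inherits(result, "coca_result")) result$cdf_area else result
  ks <- as.integer(names(area))
  if (length(ks) == 1) {
    message(sprintf("single K in range; returning K = %d", ks))
    out <- ks
    attr(out, "delta") <- stats::setNames(numeric(0), character(0))
    return(out)
  }
  prev <- area[-length(area)]
  delta <- (area[-1] - prev) / ifelse(prev > 0, prev, NA_real_)
  delta[is.na(delta)] <- ifelse(area[-1][is.na(delta)] > 0, Inf, 0)
  names(delta) <- ks[-1]
  out <- if (rule == "elbow") {
    ks[-1][which.max(delta)]
  } else if (any(delta >= threshold)) {
    max(ks[-1][delta >= threshold])
  } else {
    ks[1]
  }
  attr(out, "delta") <- delta
  out
}

#' @export
print.coca_result <- function(x, ...) {
  cat(sprintf(paste0("<coca_result> %d samples, K range %s, selected K = %d ",
                     "(%d reps, item fraction %.2f)\n"),
              length(x$labels), paste(range(x$k_range), collapse = "-"),
              x$selected_k, x$repetitions, x$item_fraction))
  cat("CDF areas:\n"); print(round(x$cdf_area, 4))
  cat("cluster sizes at selected K:\n"); print(table(x$labels))
  invisible(x)
}

#' Consensus-matrix heatmap at the selected K
#'
#' @param x a `coca_result`.
#' @param k which K to draw (default the selected K).
#' @param ... passed to [graphics::image()].
#' @export
plot.coca_result <- function(x, k = x$selected_k, ...) {
  cm <- x$consensus[[as.character(k)]]
  ord <- order(x$labels_by_k[[as.character(k)]])
  graphics::image(cm[ord, ord], col = grDevices::gray.colors(64, 1, 0),
                  axes = FALSE,
                  main = sprintf("consensus matrix, K = %d", k), ...)
  invisible(x)
}
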