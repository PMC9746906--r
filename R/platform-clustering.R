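# Copy-number trinarization, methylation driver-CpG filtering and the shared
# hierarchical-clustering core used by all three single-platform stages.

#' Collapse GISTIC 5-level copy-number calls to trinary values
#'
#' Maps thresholded calls to the three-level alphabet used for clustering:
#' amplification values 1 and 2 become 1, deletion values -1 and -2 become
#' -1, neutral 0 stays 0.
#'
#' @param cnv fragment x sample matrix with entries in `{-2,-1,0,1,2}`.
#' @return Integer matrix of the same shape with entries in `{-1,0,1}`.
#' @export
trinarize_gistic <- function(cnv) {
  cnv <- as.matrix(cnv)
  bad <- matrix(!(cnv %in% c(-2L, -1L, 0L, 1L, 2L)), nrow(cnv))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid copy-number value %s at fragment '%s', sample '%s'",
                 cnv[idx[1], idx[2]],
                 rownames(cnv)[idx[1]] %||% idx[1],
                 colnames(cnv)[idx[2]] %||% idx[2]))
  }
  out <- sign(cnv)
  storage.mode(out) <- "integer"
  out
}

#' Filter methylation probes to candidate driver CpG sites
#'
#' Retains probes satisfying all of: (a) mean beta < 0.2 in the normal panel
#' and beta > 0.3 in at most 5 normal samples; (b) beta > 0.3 in strictly
#' more than 10% of tumors; (c) not on a sex chromosome and not overlapping a
#' SNP. Each excluded probe is attributed to its first failing criterion in
#' the order a, b, c; the retained set itself is order-independent (the
#' criteria are conjunctive).
#'
#' @param beta_tumor,beta_normal probe x sample beta matrices sharing probe
#'   ids.
#' @param probe_annotation data frame (probe, chromosome, snp_overlap, ...)
#'   covering all probes.
#' @param normal_mean_max,normal_beta_cut,normal_max_exceed,tumor_beta_cut,tumor_frac_min
#'   the filter thresholds (defaults 0.2, 0.3, 5, 0.3, 0.10).
#' @return A `cpg_filter_report` list: `retained` probe ids, per-criterion
#'   counts, `first_failure` per excluded probe, and `tumor_variance` of the
#'   retained probes.
#' @export
filter_driver_cpgs <- function(beta_tumor, beta_normal, probe_annotation,
                               normal_mean_max = 0.2, normal_beta_cut = 0.3,
                               normal_max_exceed = 5, tumor_beta_cut = 0.3,
                               tumor_frac_min = 0.10) {
  probes <- rownames(beta_tumor)
  stopifnot(!is.null(probes))
  if (!identical(sort(probes), sort(rownames(beta_normal))))
    stop("tumor and normal matrices must share probe ids")
  beta_normal <- beta_normal[probes, , drop = FALSE]
  missing <- setdiff(probes, probe_annotation$probe)
  if (length(missing))
    stop(sprintf("probes missing from annotation: %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  ann <- probe_annotation[match(probes, probe_annotation$probe), ]

  pass_a <- rowMeans(beta_normal) < normal_mean_max &
    rowSums(beta_normal > normal_beta_cut) <= normal_max_exceed
  pass_b <- rowMeans(beta_tumor > tumor_beta_cut) > tumor_frac_min
  pass_c <- !(ann$chromosome %in% c("chrX", "chrY", "X", "Y")) &
    !ann$snp_overlap
  retained <- probes[pass_a & pass_b & pass_c]
  first_failure <- rep(NA_character_, length(probes))
  first_failure[!pass_c] <- "c_sex_or_snp"
  first_failure[!pass_b] <- "b_tumor"
  first_failure[!pass_a] <- "a_normal"
  names(first_failure) <- probes
  structure(list(
    n_input = length(probes),
    n_pass_normal_criterion = sum(pass_a),
    n_pass_tumor_criterion = sum(pass_b),
    n_removed_sex_or_snp = sum(!pass_c),
    n_retained = length(retained),
    retained = retained,
    first_failure = first_failure[!is.na(first_failure)],
    tumor_variance = apply(beta_tumor[retained, , drop = FALSE], 1,
                           stats::var)),
    class = "cpg_filter_report")
}

#' @export
print.cpg_filter_report <- function(x, ...) {
  cat(sprintf(paste0("<cpg_filter_report> %d probes in, %d retained ",
                     "(normal-pass %d, tumor-pass %d, sex/SNP removed %d)\n"),
              x$n_input, x$n_retained, x$n_pass_normal_criterion,
              x$n_pass_tumor_criterion, x$n_removed_sex_or_snp))
  invisible(x)
}

#' Select the most variable methylation sites
#'
#' The `n` retained probes with the largest beta variance across tumors;
#' deterministic tie-break by probe id. Zero-variance selections are flagged.
#'
#' @param beta_tumor probe x sample beta matrix.
#' @param retained probe ids to choose among (e.g. from
#'   [filter_driver_cpgs()]).
#' @param n number of sites (default 1000); must not exceed
#'   `length(retained)`.
#' @return Character vector of `n` probe ids, attribute `zero_variance`
#'   flagging selected probes with zero variance.
#' @export
select_top_variable_sites <- function(beta_tumor, retained, n = 1000) {
  if (n > length(retained))
    stop(sprintf("n (%d) exceeds the number of retained probes (%d)",
                 n, length(retained)))
  v <- apply(beta_tumor[retained, , drop = FALSE], 1, stats::var)
  ord <- order(-v, retained)
  sel <- retained[ord][seq_len(n)]
  zv <- sel[v[match(sel, retained)] == 0]
  if (length(zv)) attr(sel, "zero_variance") <- zv
  sel
}

#' Hierarchical clustering of samples on a feature matrix
#'
#' Agglomerative clustering of the columns (samples) of a feature x sample
#' matrix, with Euclidean distance and Ward.D2 or average linkage. Labels are
#' renumbered 1..k in order of first occurrence, so the partition is
#' invariant to sample permutation up to relabeling.
#'
#' @param x feature x sample numeric matrix, no missing values.
#' @param k number of clusters (2..n samples).
#' @param linkage `"ward"` (Ward.D2 convention: raw Euclidean distances) or
#'   `"average"`.
#' @param distance only `"euclidean"`.
#' @param platform platform tag stored in the result.
#' @return A [cluster_assignment()].
#' @export
hierarchical_cluster <- function(x, k, linkage = c("ward", "average"),
                                 distance = "euclidean",
                                 platform = "unknown") {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance, "euclidean")
  x <- as.matrix(x)
  if (anyNA(x))
    stop("missing values in clustering input; impute explicitly first")
  n <- ncol(x)
  if (k < 2 || k > n) stop("k must lie in [2, n_samples]")
  ids <- colnames(x) %||% sprintf("sample%d", seq_len(n))
  d <- stats::dist(t(x), method = "euclidean")
  h <- stats::hclust(d, method = if (linkage == "ward") "ward.D2" else
    "average")
  lab <- relabel_first_occurrence(stats::cutree(h, k = k))
  names(lab) <- ids
  cluster_assignment(lab, platform = platform)
}

#' Choose the number of clusters by mean silhouette width
#'
#' Cuts the hierarchical tree at every k in `k_range` and returns the k with
#' the largest mean silhouette width.
#'
#' @inheritParams hierarchical_cluster
#' @param k_range candidate cluster numbers within `[2, n_samples - 1]`.
#' @return The chosen k, with attribute `silhouette` (the full profile).
#' @export
choose_k <- function(x, k_range = 2:8, linkage = c("ward", "average"),
                     distance = "euclidean") {
  linkage <- match.arg(linkage)
  x <- as.matrix(x)
  n <- ncol(x)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("empty k_range after bounding to [2, n-1]")
  d <- stats::dist(t(x), method = "euclidean")
  if (all(d == 0))
    stop("degenerate input: all samples identical")
  h <- stats::hclust(d, method = if (linkage == "ward") "ward.D2" else
    "average")
  sil <- vapply(k_range, function(k) {
    lab <- stats::cutree(h, k = k)
    mean(cluster::silhouette(lab, d)[, "sil_width"])
  }, numeric(1))
  names(sil) <- k_range
  out <- k_range[which.max(sil)]
  attr(out, "silhouette") <- sil
  out
}
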