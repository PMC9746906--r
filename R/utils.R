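#' Derive a reproducible stage seed from a master seed
#'
#' Decouples the RNG streams of pipeline stages: each stage draws its own seed
#' as a deterministic hash of the master seed and the stage name, so changing
#' one stage's internals never perturbs another stage's randomness.
#'
#' @param master_seed integer master seed.
#' @param stage character stage name.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  h <- as.numeric(master_seed) %% 2147483647
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples.
#' Thin wrapper around [mclust::adjustedRandIndex()].
#'
#' @param a,b label vectors of equal length.
#' @return The adjusted Rand index (1 = identical partitions up to renaming).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

#' Cluster assignment container
#'
#' @param labels integer cluster labels, named by sample id.
#' @param platform character platform tag (e.g. "mutation").
#' @return An object of class `cluster_assignment` with elements `labels`,
#'   `k` (number of distinct clusters) and `platform`.
#' @export
cluster_assignment <- function(labels, platform = "unknown") {
  stopifnot(!is.null(names(labels)))
  ids <- names(labels)
  labels <- as.integer(labels)
  names(labels) <- ids
  structure(list(labels = labels,
                 k = length(unique(labels)),
                 platform = platform),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> platform=%s, %d samples, k=%d\n",
              x$platform, length(x$labels), x$k))
  print(table(x$labels))
  invisible(x)
}

# Accept either a cluster_assignment or a named label vector.
as_labels <- function(x) {
  if (inherits(x, "cluster_assignment")) return(x$labels)
  stopifnot(!is.null(names(x)))
  x
}

# Relabel cluster ids as 1..k in order of first occurrence.
relabel_first_occurrence <- function(x) {
  match(x, unique(x))
}

# Two-sided Fisher exact p for a 2x2 table given as counts; wraps
# stats::fisher.test but tolerates degenerate margins by returning NA.
fisher_p <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), nrow = 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NA_real_)
  stats::fisher.test(tab)$p.value
}

# chi-square test of a 2x2 table without continuity correction, with the
# Fisher exact fallback used across the package when any expected count < 5.
chisq_or_fisher <- function(tab) {
  tab <- as.matrix(tab)
  if (any(dim(tab) != c(2L, 2L)) || any(rowSums(tab) == 0) ||
      any(colSums(tab) == 0)) {
    p <- fisher_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    return(list(statistic = NA_real_, p = if (is.na(p)) 1 else p,
                method = "fisher"))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    list(statistic = NA_real_,
         p = stats::fisher.test(tab)$p.value,
         method = "fisher")
  } else {
    ct <- stats::chisq.test(tab, correct = FALSE)
    list(statistic = unname(ct$statistic), p = ct$p.value, method = "chisq")
  }
}

# Cosine similarity between two vectors.
cosine_similarity <- function(x, y) {
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
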