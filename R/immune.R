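# Single-sample gene-set enrichment scoring of stimulatory and inhibitory
# immune checkpoints, patient categorization, and subtype enrichment testing.

#' Single-sample gene-set enrichment score (running-sum form)
#'
#' Genes are ranked by expression (descending, deterministic tie-break by
#' gene id). The score is the sum over the ranked list of the difference
#' between the weighted in-set ECDF (weights `|value|^exponent`) and the
#' uniform out-of-set ECDF - the running-sum integral form of ssGSEA. With
#' `exponent = 0` the score depends on ranks only and is invariant under any
#' strictly increasing transform of the values.
#'
#' @param values named numeric vector of one sample's expression.
#' @param gene_set character vector; at least one member must be present in
#'   `values`, and the set must be a strict subset of all genes.
#' @param exponent rank weighting exponent (default 0.25).
#' @return The enrichment score (a single real number).
#' @export
ssgsea_score <- function(values, gene_set, exponent = 0.25) {
  stopifnot(!is.null(names(values)), length(gene_set) > 0)
  genes <- names(values)
  in_set <- genes %in% gene_set
  if (!any(in_set)) stop("no gene of the set is present in the expression index")
  if (all(in_set)) stop("degenerate set: the gene set covers all genes")
  ord <- order(-values, genes)
  v <- values[ord]
  inside <- in_set[ord]
  w <- abs(v)^exponent
  w[!inside] <- 0
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!inside) / sum(!inside)
  sum(p_in - p_out)
}

#' Stimulatory and inhibitory checkpoint scores per sample
#'
#' Scores every sample of an expression matrix against the two checkpoint
#' gene sets and assigns the category by strict comparison; exact ties go to
#' `"stimulatory"` (fixed, documented tie rule) and are counted in the
#' `ties` attribute.
#'
#' @param expression gene x sample matrix.
#' @param checkpoint_sets list with character elements `stimulatory` and
#'   `inhibitory` (disjoint gene sets).
#' @param exponent passed to [ssgsea_score()].
#' @return Data frame (sample, stimulatory_score, inhibitory_score,
#'   category).
#' @export
checkpoint_scores <- function(expression, checkpoint_sets, exponent = 0.25) {
  stopifnot(all(c("stimulatory", "inhibitory") %in% names(checkpoint_sets)))
  if (length(intersect(checkpoint_sets$stimulatory,
                       checkpoint_sets$inhibitory)))
    stop("stimulatory and inhibitory sets must be disjoint")
  stim <- apply(expression, 2, ssgsea_score,
                gene_set = checkpoint_sets$stimulatory, exponent = exponent)
  inhib <- apply(expression, 2, ssgsea_score,
                 gene_set = checkpoint_sets$inhibitory, exponent = exponent)
  out <- data.frame(sample = colnames(expression),
                    stimulatory_score = unname(stim),
                    inhibitory_score = unname(inhib),
                    category = checkpoint_categorize(stim, inhib),
                    stringsAsFactors = FALSE)
  attr(out, "ties") <- sum(stim == inhib)
  out
}

#' Categorize samples as stimulatory or inhibitory
#'
#' @param stimulatory_score,inhibitory_score numeric vectors.
#' @return Character vector `"stimulatory"`/`"inhibitory"`; exact ties are
#'   `"stimulatory"`.
#' @export
checkpoint_categorize <- function(stimulatory_score, inhibitory_score) {
  ifelse(stimulatory_score >= inhibitory_score, "stimulatory", "inhibitory")
}

#' Enrichment of a checkpoint category in a focal subtype
#'
#' Chi-square test (no continuity correction) of category x (focal subtype
#' vs rest), with the package-wide Fisher exact fallback for small expected
#' counts or degenerate tables.
#'
#' @param categories character vector of per-sample categories (named by
#'   sample, or aligned with `subtype_labels`).
#' @param subtype_labels cluster labels.
#' @param focal_subtype the subtype tested for enrichment.
#' @return List with `statistic`, `p`, `method`, `table`, and
#'   `inhibitory_fraction` in the focal subtype and the rest.
#' @export
category_enrichment_test <- function(categories, subtype_labels,
                                     focal_subtype) {
  lab <- as_labels(subtype_labels)
  if (!is.null(names(categories))) categories <- categories[names(lab)]
  stopifnot(length(categories) == length(lab))
  if (length(unique(lab)) < 2) stop("need at least two subtypes")
  focal <- factor(lab == focal_subtype, levels = c(TRUE, FALSE),
                  labels = c("focal", "rest"))
  cat_f <- factor(categories, levels = c("inhibitory", "stimulatory"))
  tab <- table(cat_f, focal)
  res <- chisq_or_fisher(tab)
  res$table <- tab
  res$inhibitory_fraction <- c(
    focal = unname(tab["inhibitory", "focal"] / sum(tab[, "focal"])),
    rest = unname(tab["inhibitory", "rest"] / sum(tab[, "rest"])))
  res
}

#' Read gene sets from a GMT file
#'
#' Plain-text GMT: one set per line, tab-separated `name`, `description`,
#' then member genes.
#'
#' @param path file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  out
}
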