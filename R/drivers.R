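# Subtype driver-event detection: differentially mutated genes, SCNA drivers
# with expression concordance, and hypermethylation drivers that negatively
# regulate expression.

driver_event_row <- function(feature, event_type, subtype, enrichment_p,
                             direction, concordance_stat = NA_real_,
                             concordance_p = NA_real_, gene = NA_character_,
                             passes = NA) {
  data.frame(feature = feature, event_type = event_type, subtype = subtype,
             enrichment_p = enrichment_p, effect_direction = direction,
             concordance_stat = concordance_stat,
             concordance_p = concordance_p, gene = gene, passes = passes,
             stringsAsFactors = FALSE)
}

#' Build a gene x sample mutation-status matrix from mutation records
#'
#' @param mutation_records data frame with `sample` and `gene` columns.
#' @param sample_ids samples to report.
#' @param genes genes to report (rows).
#' @return 0/1 integer matrix genes x samples.
#' @export
mutation_status_matrix <- function(mutation_records, sample_ids, genes) {
  m <- matrix(0L, length(genes), length(sample_ids),
              dimnames = list(genes, sample_ids))
  rec <- mutation_records[mutation_records$gene %in% genes &
                            mutation_records$sample %in% sample_ids, ]
  if (nrow(rec))
    m[cbind(match(rec$gene, genes), match(rec$sample, sample_ids))] <- 1L
  m
}

#' Differentially mutated genes per subtype (Fisher exact test)
#'
#' For every gene in `gene_list` and every subtype, a two-sided Fisher exact
#' test of mutated/unmutated against in-subtype/rest. Genes absent from the
#' mutation table, or with a zero margin (never or always mutated), are
#' reported untested.
#'
#' @param mutation_status gene x sample 0/1 matrix (see
#'   [mutation_status_matrix()]).
#' @param labels a [cluster_assignment()] or named label vector covering all
#'   samples.
#' @param gene_list genes to test (e.g. a significantly-mutated-gene list).
#' @param p_threshold enrichment threshold defining `passes`
#'   (default 0.001).
#' @return A data frame of driver events (one row per tested gene x subtype)
#'   with attribute `untested` listing skipped genes.
#' @export
mutation_driver_test <- function(mutation_status, labels, gene_list,
                                 p_threshold = 0.001) {
  stopifnot(length(gene_list) > 0)
  lab <- as_labels(labels)
  samples <- intersect(colnames(mutation_status), names(lab))
  m <- mutation_status[, samples, drop = FALSE]
  lab <- lab[samples]
  subtypes <- sort(unique(lab))
  untested <- character(0)
  rows <- list()
  for (g in gene_list) {
    if (!g %in% rownames(m)) { untested <- c(untested, g); next }
    mut <- m[g, ] == 1
    if (all(mut) || !any(mut)) { untested <- c(untested, g); next }
    for (s in subtypes) {
      inside <- lab == s
      a <- sum(mut & inside); b <- sum(mut & !inside)
      c_ <- sum(!mut & inside); d <- sum(!mut & !inside)
      p <- fisher_p(a, c_, b, d)
      dir <- if (a / sum(inside) > b / sum(!inside)) "enriched" else
        "depleted"
      rows[[length(rows) + 1L]] <- driver_event_row(
        g, "mutation", s, p, dir, gene = g,
        passes = !is.na(p) && p < p_threshold)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    driver_event_row(character(0), character(0), integer(0), numeric(0),
                     character(0))[0, ]
  attr(out, "untested") <- untested
  out
}

#' Copy-number driver fragments with expression concordance
#'
#' Amplification (value 1) and deletion (value -1) indicators of the trinary
#' matrix are tested per subtype by two-sided Fisher exact tests.
#' "Consistently enriched" means: significant (`enrichment_p <
#' p_enrichment`) with higher in-subtype frequency in exactly one subtype,
#' which also carries the maximum frequency across subtypes. Candidate
#' fragments are then screened by expression concordance of their annotated
#' oncogenes / tumor suppressors: a one-sided rank-sum test requiring higher
#' expression in amplified samples, or lower in deleted samples
#' (`concordance_p < p_concordance`). Fragments with no mapped gene keep
#' their enrichment result but cannot pass.
#'
#' @param trinary fragment x sample matrix over `{-1,0,1}` (see
#'   [trinarize_gistic()]).
#' @param labels cluster labels covering the samples.
#' @param expression gene x sample matrix (log2 scale).
#' @param fragment_to_genes named list: fragment id -> character vector of
#'   annotated genes.
#' @param p_enrichment,p_concordance thresholds (defaults 0.001 and 0.05).
#' @return Data frame of driver events (one row per candidate fragment and
#'   mapped gene; `feature` is the fragment).
#' @export
scna_driver_test <- function(trinary, labels, expression, fragment_to_genes,
                             p_enrichment = 0.001, p_concordance = 0.05) {
  lab <- as_labels(labels)
  samples <- intersect(colnames(trinary), names(lab))
  tri <- trinary[, samples, drop = FALSE]
  lab <- lab[samples]
  subtypes <- sort(unique(lab))
  rows <- list()
  for (frag in rownames(tri)) {
    for (ev in c("amplification", "deletion")) {
      altered <- if (ev == "amplification") tri[frag, ] == 1 else
        tri[frag, ] == -1
      if (!any(altered)) next
      ps <- freqs <- numeric(length(subtypes))
      for (si in seq_along(subtypes)) {
        inside <- lab == subtypes[si]
        a <- sum(altered & inside); b <- sum(altered & !inside)
        ps[si] <- fisher_p(a, sum(inside) - a, b, sum(!inside) - b)
        freqs[si] <- a / sum(inside)
      }
      out_freq <- vapply(seq_along(subtypes), function(si)
        sum(altered & lab != subtypes[si]) / sum(lab != subtypes[si]),
        numeric(1))
      sig_enriched <- !is.na(ps) & ps < p_enrichment & freqs > out_freq
      if (sum(sig_enriched) != 1) next
      si <- which(sig_enriched)
      if (freqs[si] < max(freqs)) next
      s <- subtypes[si]
      genes <- fragment_to_genes[[frag]]
      if (is.null(genes) || !length(genes)) {
        rows[[length(rows) + 1L]] <- driver_event_row(
          frag, ev, s, ps[si], "enriched", passes = FALSE)
        next
      }
      for (g in genes) {
        if (!g %in% rownames(expression)) {
          rows[[length(rows) + 1L]] <- driver_event_row(
            frag, ev, s, ps[si], "enriched", gene = g, passes = FALSE)
          next
        }
        alt_expr <- expression[g, samples][altered]
        ref_expr <- expression[g, samples][!altered]
        wt <- stats::wilcox.test(
          alt_expr, ref_expr,
          alternative = if (ev == "amplification") "greater" else "less",
          exact = FALSE)
        rows[[length(rows) + 1L]] <- driver_event_row(
          frag, ev, s, ps[si], "enriched",
          concordance_stat = unname(wt$statistic),
          concordance_p = wt$p.value, gene = g,
          passes = ps[si] < p_enrichment && wt$p.value < p_concordance)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    driver_event_row(character(0), character(0), integer(0), numeric(0),
                     character(0))[0, ]
}

#' Hypermethylation drivers negatively regulating expression
#'
#' Beta values are dichotomized at `beta >= 0.3` (positive methylation). For
#' each evaluated probe, the most-methylated subtype is the candidate; step
#' (a) requires every pairwise test of the methylation indicator between the
#' candidate subtype and each other subtype to reach `p < p_enrichment`
#' (chi-square without continuity correction, with an automatic Fisher exact
#' fallback when any expected cell count is below 5); step (b) requires the
#' Pearson correlation between beta and the mapped gene's expression to be
#' negative with one-sided `p < p_concordance`.
#'
#' @param beta probe x sample matrix.
#' @param labels cluster labels.
#' @param expression gene x sample matrix.
#' @param probe_to_gene named character vector probe -> gene.
#' @param top_sites probes to evaluate (the most variable filtered sites).
#' @param beta_cut dichotomization threshold (default 0.3).
#' @param p_enrichment,p_concordance thresholds (defaults 0.001 and 0.05).
#' @param pairwise `"focal"` (default: only pairs involving the candidate
#'   subtype must be significant) or `"all"` (every pair).
#' @return Data frame of driver events (`feature` is the probe;
#'   `enrichment_p` the largest required pairwise p).
#' @export
methylation_driver_test <- function(beta, labels, expression, probe_to_gene,
                                    top_sites, beta_cut = 0.3,
                                    p_enrichment = 0.001,
                                    p_concordance = 0.05,
                                    pairwise = c("focal", "all")) {
  pairwise <- match.arg(pairwise)
  lab <- as_labels(labels)
  samples <- intersect(colnames(beta), names(lab))
  lab <- lab[samples]
  subtypes <- sort(unique(lab))
  rows <- list()
  for (probe in intersect(top_sites, rownames(beta))) {
    mth <- beta[probe, samples] >= beta_cut
    frac <- vapply(subtypes, function(s) mean(mth[lab == s]), numeric(1))
    if (max(frac) == 0 || length(unique(frac)) == 1) next
    cand <- subtypes[which.max(frac)]
    pairs <- if (pairwise == "focal") {
      lapply(setdiff(subtypes, cand), function(s) c(cand, s))
    } else {
      prs <- utils::combn(subtypes, 2, simplify = FALSE)
      prs
    }
    pvals <- vapply(pairs, function(pr) {
      sel <- lab %in% pr
      tab <- table(factor(mth[sel], levels = c(TRUE, FALSE)),
                   factor(lab[sel], levels = pr))
      chisq_or_fisher(tab)$p
    }, numeric(1))
    step_a <- all(pvals < p_enrichment)
    gene <- unname(probe_to_gene[probe])
    if (is.na(gene) || !gene %in% rownames(expression)) {
      rows[[length(rows) + 1L]] <- driver_event_row(
        probe, "hypermethylation", cand, max(pvals), "enriched",
        gene = gene, passes = FALSE)
      next
    }
    ct <- stats::cor.test(beta[probe, samples], expression[gene, samples],
                          alternative = "less")
    rows[[length(rows) + 1L]] <- driver_event_row(
      probe, "hypermethylation", cand, max(pvals), "enriched",
      concordance_stat = unname(ct$estimate), concordance_p = ct$p.value,
      gene = gene,
      passes = step_a && ct$estimate < 0 && ct$p.value < p_concordance)
  }
  if (length(rows)) do.call(rbind, rows) else
    driver_event_row(character(0), character(0), integer(0), numeric(0),
                     character(0))[0, ]
}

#' Precision and recall of driver recovery against planted truth
#'
#' Compares passing, subtype-enriched driver events with a planted driver
#' table. A detection matches when feature, event type and subtype all agree
#' (subtypes are matched through a label mapping when cluster labels are a
#' permutation of planted subtypes).
#'
#' @param events data frame of driver events (rbind of the three tests).
#' @param truth data frame (feature, event_type, subtype).
#' @param subtype_map optional named vector mapping cluster labels to planted
#'   subtype ids (defaults to identity).
#' @return List with `precision`, `recall`, `n_detected`, `n_planted`.
#' @export
score_driver_recovery <- function(events, truth, subtype_map = NULL) {
  det <- events[!is.na(events$passes) & events$passes &
                  events$effect_direction == "enriched", , drop = FALSE]
  sub <- det$subtype
  if (!is.null(subtype_map)) sub <- unname(subtype_map[as.character(sub)])
  det_key <- unique(paste(det$feature, det$event_type, sub))
  truth_key <- unique(paste(truth$feature, truth$event_type, truth$subtype))
  tp <- sum(det_key %in% truth_key)
  list(precision = if (length(det_key)) tp / length(det_key) else NA_real_,
       recall = if (length(truth_key)) tp / length(truth_key) else NA_real_,
       n_detected = length(det_key), n_planted = length(truth_key))
}

#' Map cluster labels to planted subtypes by majority vote
#'
#' @param labels cluster labels (named by sample).
#' @param truth planted subtype vector (named by sample).
#' @return Named vector: cluster label -> majority planted subtype.
#' @export
majority_subtype_map <- function(labels, truth) {
  lab <- as_labels(labels)
  truth <- truth[names(lab)]
  vapply(split(truth, lab), function(tt)
    as.integer(names(which.max(table(tt)))), integer(1))
}
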