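# Orchestration: cohort inclusion filtering and the end-to-end run across
# all stages, with per-stage seeds derived from the master seed.

#' Cancer-type inclusion filter
#'
#' Keeps cancer types whose TP53-mutation frequency is strictly above
#' `min_frequency` (default 10%) and whose count of TP53-mutant samples with
#' complete four-platform profiles is strictly above `min_complete`
#' (default 50); optionally subsets a sample table to the complete-profile
#' samples of the included types.
#'
#' @param frequencies named numeric vector: TP53mut frequency per cancer
#'   type, in `[0, 1]`.
#' @param complete_counts named numeric vector: complete-profile TP53mut
#'   sample count per type.
#' @param min_frequency,min_complete inclusion thresholds.
#' @param samples optional data frame (sample, cancer_type, complete).
#' @return List with `included_types` and (when `samples` is given)
#'   `included_samples`.
#' @export
filter_cohort <- function(frequencies, complete_counts,
                          min_frequency = 0.10, min_complete = 50,
                          samples = NULL) {
  stopifnot(all(frequencies >= 0 & frequencies <= 1))
  types <- intersect(names(frequencies), names(complete_counts))
  keep <- types[frequencies[types] > min_frequency &
                  complete_counts[types] > min_complete]
  out <- list(included_types = keep)
  if (!is.null(samples)) {
    ok <- samples$cancer_type %in% keep
    if ("complete" %in% names(samples)) ok <- ok & samples$complete
    out$included_samples <- samples$sample[ok]
  }
  out
}

#' Pipeline stage parameters
#'
#' Collects the tunable parameters of every stage with the package defaults:
#' NMF rank range and restarts, per-platform cluster search ranges, COCA
#' resampling settings, driver and screening thresholds, and classifier
#' controls. The documented analysis thresholds (10% inclusion frequency,
#' >50 complete profiles, P<0.001 enrichment, P<0.05 concordance, beta 0.3
#' dichotomization, 1000 variable sites, 20% drug missingness, 80/20 split)
#' are all configurable here.
#'
#' @param nmf_rank_range,nmf_restarts,nmf_max_iter signature extraction
#'   controls (the pipeline default of 20 restarts trades a little rank-
#'   selection stability for speed; [extract_signatures()] alone defaults
#'   to 50).
#' @param platform_k_range cluster-number search range per platform.
#' @param n_variable_sites methylation sites kept for clustering.
#' @param coca_k_range,coca_item_fraction,coca_repetitions,coca_delta_threshold
#'   consensus-clustering controls.
#' @param driver_p_enrichment,driver_p_concordance driver thresholds.
#' @param ssgsea_exponent checkpoint scoring exponent.
#' @param train_fraction,lasso_penalty,classifier_methods classifier stage.
#' @param drug_max_missing,drug_k_neighbors,drug_alpha drug screen stage.
#' @param nn neural-network control ([nn_control()]).
#' @return A list of class `pipeline_control`.
#' @export
pipeline_control <- function(nmf_rank_range = 2:6,
                             nmf_restarts = 20,
                             nmf_max_iter = 2000,
                             platform_k_range = 2:8,
                             n_variable_sites = 1000,
                             coca_k_range = 2:8,
                             coca_item_fraction = 0.8,
                             coca_repetitions = 500,
                             coca_delta_threshold = 0.05,
                             driver_p_enrichment = 0.001,
                             driver_p_concordance = 0.05,
                             ssgsea_exponent = 0.25,
                             train_fraction = 0.8,
                             lasso_penalty = 0.0015,
                             classifier_methods = c("neural_net", "svm",
                                                    "logistic", "knn", "lda",
                                                    "naive_bayes", "cart"),
                             drug_max_missing = 0.2,
                             drug_k_neighbors = 5,
                             drug_alpha = 0.05,
                             nn = nn_control()) {
  structure(as.list(environment()), class = "pipeline_control")
}

#' Run the integrated subtyping pipeline end to end
#'
#' Sequences the stages on a multiomics cohort: per-platform clustering
#' (mutational signatures, copy number, methylation), COCA integration,
#' driver detection, immune checkpoint scoring, focal-subtype
#' classification, the optional two-panel drug screen, and survival
#' analysis. Fully deterministic for a fixed seed (stage seeds are derived
#' with [derive_seed()]). The focal subtype is the COCA cluster with the
#' largest inhibitory-category fraction (the immunosuppressive subtype).
#'
#' @param cohort a `multiomics_cohort` (see [generate_cohort()]); any list
#'   with the same element shapes works.
#' @param ccl_panels optional named list of `ccl_panel`s for the drug stage.
#' @param checkpoint_sets list with `stimulatory`/`inhibitory` gene sets;
#'   defaults to the cohort's planted sets when present.
#' @param smg_genes gene list for mutation driver testing; defaults to the
#'   cohort's planted SMG list.
#' @param stages stages to run (subset of the default vector); upstream
#'   requirements are checked.
#' @param seed master seed.
#' @param control a [pipeline_control()].
#' @return A `tp53coca_report` with per-stage results, the COCA labels, and
#'   (when planted truth is available) the ARI against the planted subtypes
#'   and driver precision/recall.
#' @export
run_pipeline <- function(cohort, ccl_panels = NULL, checkpoint_sets = NULL,
                         smg_genes = NULL,
                         stages = c("mutation", "cnv", "methylation", "coca",
                                    "drivers", "immune", "classifier",
                                    "drugs", "survival"),
                         seed = 1, control = pipeline_control()) {
  stages <- match.arg(stages, several.ok = TRUE)
  report <- list(seed = seed, stages = stages, control = control)
  samples <- cohort$sample_ids
  assignments <- list()

  if ("mutation" %in% stages) {
    motif <- build_motif_matrix(cohort$mutation_records, samples)
    model <- extract_signatures(motif, rank_range = control$nmf_rank_range,
                                n_restarts = control$nmf_restarts,
                                max_iter = control$nmf_max_iter,
                                seed = derive_seed(seed, "nmf"))
    assignments$mutation <- cluster_exposures(model, k = "auto",
                                              k_range = control$platform_k_range)
    report$signature_model <- model
  }
  if ("cnv" %in% stages) {
    tri <- trinarize_gistic(cohort$cnv)
    k <- choose_k(tri, k_range = control$platform_k_range, linkage = "ward")
    assignments$cnv <- hierarchical_cluster(tri, k = k, linkage = "ward",
                                            platform = "cnv")
    report$trinary_cnv <- tri
  }
  if ("methylation" %in% stages) {
    filt <- filter_driver_cpgs(cohort$methylation, cohort$methylation_normal,
                               cohort$probe_annotation)
    n_sites <- min(control$n_variable_sites, length(filt$retained))
    sites <- select_top_variable_sites(cohort$methylation, filt$retained,
                                       n = n_sites)
    sub <- cohort$methylation[sites, , drop = FALSE]
    k <- choose_k(sub, k_range = control$platform_k_range, linkage = "ward")
    assignments$methylation <- hierarchical_cluster(sub, k = k,
                                                    linkage = "ward",
                                                    platform = "methylation")
    report$cpg_filter <- filt
    report$top_sites <- sites
  }
  report$platform_assignments <- assignments

  if ("coca" %in% stages) {
    if (length(assignments) < 2)
      stop("COCA requires at least two platform assignments")
    binary <- encode_binary_membership(assignments)
    coca <- consensus_cluster(binary, k_range = control$coca_k_range,
                              item_fraction = control$coca_item_fraction,
                              repetitions = control$coca_repetitions,
                              seed = derive_seed(seed, "coca"),
                              delta_threshold = control$coca_delta_threshold)
    report$binary_membership <- binary
    report$coca <- coca
    report$labels <- coca$labels
    if (!is.null(cohort$truth$subtype))
      report$ari <- adjusted_rand_index(coca$labels[samples],
                                        cohort$truth$subtype[samples])
  }

  labels <- report$labels
  if (is.null(labels) && !is.null(cohort$truth$subtype))
    labels <- cohort$truth$subtype  # downstream stages without COCA

  if ("drivers" %in% stages && !is.null(labels)) {
    smg <- smg_genes %||% cohort$truth$smg_genes
    status <- mutation_status_matrix(cohort$mutation_records, samples, smg)
    mut_ev <- mutation_driver_test(status, labels, smg,
                                   p_threshold = control$driver_p_enrichment)
    tri <- report$trinary_cnv %||% trinarize_gistic(cohort$cnv)
    frag_map <- fragment_gene_map(cohort)
    scna_ev <- scna_driver_test(tri, labels, cohort$expression, frag_map,
                                p_enrichment = control$driver_p_enrichment,
                                p_concordance = control$driver_p_concordance)
    probe_map <- stats::setNames(cohort$probe_annotation$gene,
                                 cohort$probe_annotation$probe)
    sites <- report$top_sites %||% rownames(cohort$methylation)
    meth_ev <- methylation_driver_test(cohort$methylation, labels,
                                       cohort$expression, probe_map, sites,
                                       p_enrichment = control$driver_p_enrichment,
                                       p_concordance = control$driver_p_concordance)
    report$drivers <- rbind(mut_ev, scna_ev, meth_ev)
    if (!is.null(cohort$truth$drivers)) {
      map <- majority_subtype_map(labels, cohort$truth$subtype)
      rec <- score_driver_recovery(report$drivers, cohort$truth$drivers,
                                   subtype_map = map)
      report$driver_recovery <- rec
    }
  }

  if ("immune" %in% stages && !is.null(labels)) {
    sets <- checkpoint_sets %||% cohort$truth$checkpoint_sets
    if (is.null(sets))
      stop("immune stage needs checkpoint_sets (no planted sets available)")
    scores <- checkpoint_scores(cohort$expression, sets,
                                exponent = control$ssgsea_exponent)
    report$checkpoint_scores <- scores
    inhib_frac <- vapply(split(scores$category, labels[scores$sample]),
                         function(cc) mean(cc == "inhibitory"), numeric(1))
    focal <- as.integer(names(which.max(inhib_frac)))
    cats <- stats::setNames(scores$category, scores$sample)
    report$focal_subtype <- focal
    report$category_enrichment <-
      category_enrichment_test(cats, labels, focal)
  }
  focal <- report$focal_subtype %||%
    (if (!is.null(cohort$truth$checkpoint_subtype) &&
         !is.null(cohort$truth$subtype) &&
         identical(labels, cohort$truth$subtype))
      cohort$truth$checkpoint_subtype else NULL)

  if ("classifier" %in% stages && !is.null(labels) && !is.null(focal)) {
    y <- stats::setNames(ifelse(labels == focal, "focal", "other"),
                         names(labels))
    split <- split_cohort(names(y), y,
                          train_fraction = control$train_fraction,
                          seed = derive_seed(seed, "split"))
    genes <- lasso_select_features(
      cohort$expression[, split$train, drop = FALSE], y[split$train],
      penalty = control$lasso_penalty,
      seed = derive_seed(seed, "lasso"))
    if (length(genes) < 2) genes <- rownames(cohort$expression)
    cmp <- compare_classifiers(
      cohort$expression[genes, , drop = FALSE], y, split,
      methods = control$classifier_methods,
      hyperparams = list(nn = control$nn),
      seed = derive_seed(seed, "classifier"))
    report$classifier <- list(selected_genes = genes, split = split,
                              comparison = cmp$comparison,
                              best_method = cmp$best_method,
                              best_model = cmp$best_model)
  }

  if ("drugs" %in% stages && !is.null(labels) && !is.null(focal) &&
      !is.null(ccl_panels)) {
    preds <- lapply(ccl_panels, function(panel) {
      prep <- prepare_drug_matrix(panel$auc,
                                  max_missing = control$drug_max_missing,
                                  k_neighbors = control$drug_k_neighbors)
      predict_panel_auc(panel$expression, prep$auc, cohort$expression)
    })
    report$drug_screen <- rank_candidate_drugs(preds, labels, focal,
                                               alpha = control$drug_alpha)
  }

  if ("survival" %in% stages && !is.null(labels)) {
    cl <- cohort$clinical
    lab <- labels[cl$sample]
    report$survival <- list(
      os = km_logrank(cl$os_time, cl$os_event, lab),
      dss = km_logrank(cl$dss_time, cl$dss_event, lab))
    if (!is.null(focal)) {
      report$survival$cox_focal <- cox_fit(
        cl$os_time, cl$os_event,
        covariates = data.frame(focal = as.integer(lab == focal)))
    }
  }
  structure(report, class = "tp53coca_report")
}

# Fragment -> coupled-gene map; prefers the generator's planted coupling,
# otherwise an empty map (user cohorts supply their own).
fragment_gene_map <- function(cohort) {
  if (!is.null(cohort$config$driver_fragments)) {
    df <- cohort$config$driver_fragments
    return(stats::setNames(as.list(df$gene), df$fragment))
  }
  if (!is.null(cohort$fragment_to_genes)) return(cohort$fragment_to_genes)
  stats::setNames(list(), character(0))
}

#' @export
print.tp53coca_report <- function(x, ...) {
  cat("<tp53coca_report>\n")
  cat(sprintf("  stages: %s (seed %d)\n", paste(x$stages, collapse = ", "),
              x$seed))
  if (!is.null(x$platform_assignments))
    for (p in names(x$platform_assignments))
      cat(sprintf("  %s clusters: %d\n", p, x$platform_assignments[[p]]$k))
  if (!is.null(x$coca))
    cat(sprintf("  COCA: selected K = %d%s\n", x$coca$selected_k,
                if (!is.null(x$ari)) sprintf(" (ARI vs truth %.3f)", x$ari)
                else ""))
  if (!is.null(x$driver_recovery))
    cat(sprintf("  drivers: %d detected, precision %.2f recall %.2f\n",
                x$driver_recovery$n_detected, x$driver_recovery$precision,
                x$driver_recovery$recall))
  if (!is.null(x$focal_subtype))
    cat(sprintf("  focal (inhibitory-enriched) subtype: %d (enrichment p = %.3g)\n",
                x$focal_subtype, x$category_enrichment$p))
  if (!is.null(x$classifier))
    cat(sprintf("  classifier: best %s, validation accuracy %.3f\n",
                x$classifier$best_method,
                x$classifier$comparison$validation_accuracy[1]))
  if (!is.null(x$drug_screen))
    cat(sprintf("  drug candidates: %s\n",
                if (length(x$drug_screen$candidates))
                  paste(x$drug_screen$candidates, collapse = ", ")
                else "(none)"))
  if (!is.null(x$survival))
    cat(sprintf("  OS log-rank p = %.3g\n", x$survival$os$p))
  invisible(x)
}
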