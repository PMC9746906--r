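# tp53coca

Integrated molecular subtyping of TP53-mutant (TP53mut) tumor cohorts by
cluster-of-clusters analysis (COCA), with the downstream characterization
stages that make the subtypes actionable.

Tumors that lose *TP53* acquire different "second hit" alterations, and
those differences drive prognosis, immune state and drug response. Given a
cohort with matched somatic mutations, GISTIC-thresholded copy number,
DNA-methylation beta values, expression and clinical follow-up, the
package:

1. clusters each platform separately —
   * mutations: 96-context motif matrix, KL-divergence NMF
     (multiplicative updates, random-restart consensus), rank chosen where
     the cophenetic correlation begins to fall, Ward.D2 clustering of
     signature exposures;
   * copy number: trinarized GISTIC calls (2,1 → 1; −1,−2 → −1), Ward.D2;
   * methylation: three-criterion driver-CpG filter (normal beta, tumor
     beta fraction, sex-chromosome/SNP removal), top variable sites,
     Ward.D2;
2. integrates the partitions by COCA: binary platform-membership vectors,
   resampled consensus clustering (Monti), K from the relative change of
   the area under the consensus CDF, Δ(K) = (A(K) − A(K−1))/A(K−1);
3. detects subtype drivers: differentially mutated genes (Fisher exact,
   P < 0.001), copy-number drivers with expression concordance (one-sided
   rank-sum, P < 0.05), hypermethylation drivers negatively regulating
   their gene (beta ≥ 0.3 dichotomization, pairwise chi-square, negative
   correlation);
4. scores stimulatory and inhibitory immune checkpoints per sample by the
   ssGSEA running sum and finds the inhibitory-enriched (focal) subtype;
5. trains a focal-vs-rest expression classifier (lasso feature selection
   at penalty 0.0015 or cross-validated; neural network / SVM / logistic /
   KNN / LDA / naive Bayes / CART compared on an 80/20 stratified split);
6. screens two cell-line panels for drugs with lower predicted AUC in the
   focal subtype (KNN-imputed AUC matrices, harmonize-then-ridge patient
   prediction, two-panel intersection);
7. reports Kaplan-Meier / log-rank and Cox proportional-hazards summaries.

A synthetic-data module generates matched multiomics cohorts and cell-line
panels with planted subtype structure, so every stage is testable end to
end with known ground truth.

## Worked example

```r
library(tp53coca)

cfg    <- synthetic_config(n_samples = 500, seed = derive_seed(1, "cohort"))
cohort <- generate_cohort(cfg)
sens   <- data.frame(drug = "DRUG001", subtype = cfg$checkpoint_subtype,
                     effect = -1.0)
panels <- list(
  ctrp = generate_ccl_panel(cfg, 120, 50, 0.1, sens,
                            seed = derive_seed(1, "panel_ctrp")),
  gdsc = generate_ccl_panel(cfg, 120, 50, 0.1, sens,
                            seed = derive_seed(1, "panel_gdsc")))

report <- run_pipeline(cohort, ccl_panels = panels,
                       seed = derive_seed(1, "pipeline"))
print(report)
```

```
<tp53coca_report>
  stages: mutation, cnv, methylation, coca, drivers, immune, classifier, drugs, survival (seed 2115444983)
  mutation clusters: 5
  cnv clusters: 5
  methylation clusters: 5
  COCA: selected K = 5 (ARI vs truth 1.000)
  drivers: 30 detected, precision 1.00 recall 1.00
  focal (inhibitory-enriched) subtype: 3 (enrichment p = 1.11e-20)
  classifier: best svm, validation accuracy 1.000
  drug candidates: DRUG001, DRUG016, DRUG006, DRUG036
  OS log-rank p = 3.37e-07
```

Reading the output: all three platforms recover five clusters and COCA
selects K = 5 with perfect agreement (adjusted Rand index 1.0) against the
planted subtypes; all 30 planted driver events (10 mutation genes, 10
copy-number fragments, 10 CpGs) are detected with no false calls; subtype
3 — the one generated with the inhibitory-checkpoint shift and threefold
hazard — is flagged as the inhibitory-enriched focal subtype, the
expression classifier separates it perfectly on held-out samples, the
planted drug DRUG001 tops the two-panel candidate list (the extra
candidates are the screen's known optimism for prediction-based AUCs; the
planted drug ranks first by combined evidence), and overall survival
differs strongly across subtypes.

Individual stages are ordinary functions (`build_motif_matrix()`,
`extract_signatures()`, `trinarize_gistic()`, `filter_driver_cpgs()`,
`consensus_cluster()`, `mutation_driver_test()`, `ssgsea_score()`,
`lasso_select_features()`, `predict_panel_auc()`, `km_logrank()`, ...) and
can be used on real data in the documented plain-text shapes (MAF-like
TSV, feature × sample TSV, GMT, gene lists).

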