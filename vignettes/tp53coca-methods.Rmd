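---
title: "Methods: integrated cluster-of-clusters subtyping of TP53-mutant cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated cluster-of-clusters subtyping of TP53-mutant cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Tumors carrying somatic *TP53* mutations (TP53mut) are molecularly
heterogeneous: the "second hit" that follows *TP53* loss differs between
patients and shapes prognosis, immune microenvironment and drug response.
`tp53coca` implements an integrated subtyping workflow for such cohorts:
each molecular platform (somatic mutations, copy number, DNA methylation)
is clustered on its own, the three partitions are fused by
cluster-of-clusters analysis (COCA), and the resulting subtypes are
characterized by driver events, immune checkpoint state, a transferable
expression classifier, a cell-line drug screen, and survival analysis.

Every stage is exercisable on synthetic cohorts with planted ground truth,
so the pipeline's operating characteristics (subtype recovery, driver
precision/recall, classifier accuracy, screen specificity) are measured,
not assumed.

# Stage models and assumptions

## Mutational signatures (stage 1a)

Substitution records are tabulated into the 96 pyrimidine-normalized
trinucleotide classes (`build_motif_matrix()`; purine-reference records are
reverse-complemented; non-SNV records are ignored and malformed contexts
skipped with a count). The motif matrix $V$ (samples x 96) is factorized as
$V \approx WH$ by nonnegative matrix factorization under the generalized
Kullback-Leibler objective with multiplicative updates (the Brunet
variant), the standard model for mutational-signature extraction.
Convergence is declared when the per-iteration relative change of the
objective falls below `tol` (default `1e-6`) or after `max_iter` (2000)
iterations; the update loop is compiled code.

For each rank in `rank_range`, `n_restarts` random restarts (default 50;
seeds derived from the master seed at fixed offsets) are consensus-combined:
each restart assigns every sample to its dominant signature, and the
restart-averaged connectivity matrix yields a cophenetic correlation
coefficient (agreement between the average-linkage tree on
$1 - \text{consensus}$ and the consensus distances themselves).

**Rank rule.** "The rank where the cophenetic coefficient begins to fall"
is implemented as a two-tier rule (`select_rank_by_cophenetic()`): if some
rank-to-rank drop exceeds `tolerance` (default 0.05) — a cliff — the rank
just before the first cliff is selected, absorbing small dips inside the
leading plateau; if the coefficient only drifts downward, the rank
attaining the maximum is selected, ties toward the smaller rank. The
two tiers are both needed: on clean cohorts the restart consensus is very
stable and the coefficient falls gently past the true rank (drops of
0.005–0.04 per rank in our simulations), so a rule keyed only to
band-membership around the maximum would always return the largest
evaluated rank, while a rule keyed only to the peak would ignore genuine
plateaus before a collapse.

Samples are clustered on their exposure vectors (raw by default; a
proportion-normalization flag exists) with Ward.D2 linkage on Euclidean
distances; `k = "auto"` maximizes the mean silhouette width over
`k_range`. Extracted signatures can be matched against any reference
profile set by Pearson correlation over the identically ordered 96
classes; zero-variance (flat) references are flagged and excluded from
best-match reporting rather than silently yielding `NA`.

## Copy number (stage 1b)

GISTIC-thresholded values are collapsed to trinary calls
(2, 1 → 1; −1, −2 → −1; `trinarize_gistic()`, idempotent by construction),
treated as numeric under Euclidean distance, and clustered with Ward.D2.
The curated focal-fragment list is an input; no peak calling is performed.

## DNA methylation (stage 1c)

Candidate driver CpGs satisfy three conjunctive criteria
(`filter_driver_cpgs()`): (a) mean beta < 0.2 in the normal panel *and*
beta > 0.3 in at most 5 normal samples; (b) beta > 0.3 in strictly more
than 10% of tumors; (c) autosomal and not SNP-overlapping. Exclusions are
attributed to the first failing criterion in the order a, b, c; the
retained set is order-independent because the criteria are conjunctive.
The "no more than 5 samples" clause is read as *normal* samples (it sits
inside the normal-tissue criterion); the threshold arguments make the
reading switchable. The `n` most variable retained sites (default 1000,
deterministic tie-break by probe id) feed Ward.D2 clustering.

## COCA integration (stage 2)

Platform memberships are one-hot encoded (one column per platform
cluster; each sample's row sums to the number of platforms; samples
missing from any platform are an error — the design requires intact
three-platform profiles). The binary matrix is consensus-clustered by the
Monti procedure: in each of `repetitions` (default 1000; the pipeline
wrapper uses 500) repetitions, `item_fraction` (default 0.8) of the
samples is drawn without replacement and clustered by average linkage on
Euclidean distance; `consensus(i,j)` is the co-clustered count over the
co-sampled count (0/0 → 0, flagged). Final labels at each K cut the
average-linkage tree of $1 - \text{consensus}$. K is selected from the
relative change of the area under the consensus CDF,
$\Delta(K) = (A(K) - A(K-1))/A(K-1)$: the largest K with
$\Delta(K) \ge$ `delta_threshold` (default 0.05), an elbow alternative
being config-selectable. Internally samples are processed in sorted-id
order so that the procedure is exactly invariant to input permutation.

## Driver events (stage 3)

* **Mutations** — per gene and subtype, a two-sided Fisher exact test of
  mutated × (in-subtype vs rest); events pass at $P < 0.001$ (raw; the
  analysis uses no multiplicity correction by design, matching the fixed
  thresholds of the workflow). Genes with a zero margin are reported
  untested.
* **Copy number** — amplification (value 1) and deletion (value −1)
  indicators tested the same way; a fragment is "consistently enriched"
  when it is significant with higher in-subtype frequency in exactly one
  subtype which also carries the maximal frequency. Candidates are then
  screened by expression concordance of their annotated oncogene/tumor
  suppressor: one-sided rank-sum (higher expression in amplified samples,
  lower in deleted ones), $P < 0.05$. The rank-sum is used because the
  alteration indicator is binary.
* **Hypermethylation** — beta dichotomized at $\ge 0.3$; the candidate
  subtype is the most-methylated one; every pairwise chi-square test
  (no continuity correction; automatic Fisher fallback when an expected
  count is < 5) between the candidate and each other subtype must reach
  $P < 0.001$ (an all-pairs variant is switchable); the probe's gene must
  show negative beta–expression correlation (one-sided $P < 0.05$).

Recovery against planted truth is scored by `score_driver_recovery()`
on passing, subtype-enriched events, with cluster labels mapped to planted
subtypes by majority vote. Depletion shadows (a driver enriched in one
subtype is mechanically depleted elsewhere) are excluded from scoring.

## Immune checkpoints (stage 4)

Single-sample gene-set scores use the rank-weighted running-sum form:
genes sorted by expression (descending, tie-break by id), in-set steps
weighted by $|x|^\alpha$ (default $\alpha = 0.25$), out-of-set steps
uniform; the score is the summed difference of the two running CDFs. With
$\alpha = 0$ the score is rank-only and invariant to monotone transforms.
Patients are categorized by strict comparison of their stimulatory and
inhibitory scores (exact ties → stimulatory, fixed and logged), and
category enrichment in a focal subtype uses the same chi-square/Fisher
logic as stage 3. The checkpoint annotation is an input GMT with two
disjoint sets; the repository ships a synthetic placeholder fixture, not a
curated list (the literature itself reports slightly different counts for
this list, so it is an input, not a constant).

## Focal-subtype classifier (stage 5)

The pipeline defines the focal subtype as the COCA cluster with the
largest inhibitory-category fraction (the immunosuppressive subtype).
Samples are split 80/20 stratified; features are selected on the training
partition only, by L1-penalized logistic regression on per-gene
standardized expression. The default penalty constant is 0.0015; with
`penalty = "auto"` the penalty is chosen by repeated k-fold
cross-validation. The "auto" objective is *misclassification error* with
the one-standard-error rule rather than deviance: on near-separable
cohorts the deviance curve keeps improving as noise genes enter, so
deviance minimization collapses to a vanishing penalty and a noise-flooded
selection, while the error/1-SE combination recovers the informative set
with few false selections.

Seven algorithms are compared on identical splits: a fully connected
neural network (hidden widths 500/1500/1700, batch size 200, 50 epochs,
Adam at learning rate 0.001 — implemented natively with He initialization,
ReLU and softmax cross-entropy), radial SVM, logistic regression, KNN,
LDA, naive Bayes, and CART. The comparison report ranks methods by
validation accuracy and the pipeline keeps the argmax. Cross-cohort
transfer (cell lines, external cohorts) goes through
`harmonize_cohorts()`: gene intersection plus per-gene within-cohort
standardization — a deterministic, idempotent location/scale alignment
(an empirical-Bayes batch model would be a drop-in replacement but is out
of scope).

## Drug screen (stage 6)

Drugs missing in more than `max_missing` (default 20%) of cell lines are
removed before anything else — a removed drug never receives imputed
values; remaining gaps are imputed by the mean of the `k` (default 5)
nearest drugs, with drug-drug distance the RMS difference over co-observed
cell lines. Patient AUC for each drug is predicted by linear ridge
regression of the drug's AUC on harmonized cell-line expression, applied
to harmonized patient expression; the penalty defaults to generalized
cross-validation on the panel, and the SVD of the design is shared across
drugs (`predict_panel_auc()`). A variance-ranked gene pre-filter caps the
design (default 1000 genes). No power transform is applied: the synthetic
AUCs are generated on a linear scale; a transform option would target the
skew of real IC50-derived values.

Candidates are drugs whose predicted AUC is significantly lower (two-sided
rank-sum $P <$ `alpha`, plus a lower focal median) in the focal subtype in
*every* panel, sorted by the maximum of the per-panel p-values. A known
limitation, documented deliberately: predictions for null drugs are
deterministic projections of expression, and projections differ between
subtypes whenever expression does, so the rank-sum null is optimistic and
the single-panel false-positive rate is inflated; the two-panel
intersection (independent panels, independent projection directions) is
what restores specificity, and the null-simulation tests quantify exactly
that.

## Survival (utilities)

Kaplan-Meier estimates, k-group log-rank tests and Cox
proportional-hazards summaries wrap the `survival` package with Efron tie
handling (Breslow selectable) and an explicit complete-case filter.
OS and DSS are separate endpoint columns of one clinical table.

# The synthetic-data generator

The generator is first-class, tested code; its defaults define the
conditions under which all operating characteristics are measured.

* **Cohort**: 500 samples, 5 equiprobable subtypes, nominal cancer-type
  labels independent of subtype.
* **Mutations**: passenger burden Poisson(120) per sample — a typical
  exome SNV count; trinucleotide contexts drawn from the sample's
  signature mixture (Dirichlet over the subtype's concentration row; each
  subtype concentrates on one of 5 sparse random signatures); no reference
  genome is consulted because downstream stages only need context counts.
  A 127-gene SMG layer carries two planted driver genes per subtype
  (60% in-subtype frequency vs 5% background) over an 8% background
  mutation rate.
* **Copy number**: 84 abstract focal fragments; per subtype a program of 8
  fragments altered at 65% (fixed direction) plus one amplification and
  one deletion driver at 70% with ±1.5 log2 expression coupling; 5%
  background alteration.
* **Methylation**: bimodal beta (low mode Beta(2,10), high mode
  Beta(10,2)) matching the bimodality the 0.3 dichotomization assumes; per
  subtype 20 program probes plus 2 driver CpGs (80% in-subtype
  hypermethylation, −1.5 expression coupling); normal-tissue panel with a
  tight low mode (Beta(2,18)) so that unmethylated probes rarely exceed
  0.3 in normals — with a heavier tail the "≤ 5 normals above 0.3" clause
  would randomly discard true driver probes, which is a property of the
  panel, not of the filter; high-baseline noise probes are methylated in
  normals and are exactly the probes the normal criterion is meant to
  remove; a slice of noise probes is placed on sex chromosomes or flagged
  as SNP-overlapping to exercise criterion (c).
* **Expression**: log2-scale Gaussian noise (sd 1) around per-gene
  baselines; additive driver couplings; 30 program genes per subtype at
  +1.0 (subtypes have transcriptional programs — without them an
  expression classifier would have nothing to learn); 15 stimulatory and
  15 inhibitory checkpoint genes sharing one baseline (so the
  stimulatory-vs-inhibitory score comparison is calibrated at null), the
  inhibitory set shifted +1.2 in subtype 3.
* **Survival**: exponential event times (hazard 0.1; 0.3 in subtype 3,
  i.e. a planted hazard ratio of 3), independent uniform censoring with
  the horizon solved numerically for a 30% marginal censoring rate.
* **Cell-line panels**: subtype labels and expression programs as in the
  cohort (extra noise), per-drug AUC baselines Uniform(8, 14) with sd-0.5
  noise, planted (drug, subtype) sensitivities as additive AUC shifts,
  missingness completely at random.

What the generator does *not* emulate: correlated passenger structure,
cancer-type-specific effects, copy-number segmentation, probe-level
spatial correlation, batch effects, or the joint dependence structure of
real TCGA layers. Passing tests therefore demonstrate that the
implementation recovers what it is designed to recover under a faithful
but idealized data model — not that real cohorts will behave as cleanly.

# Numerical choices and degenerate inputs

* NMF restarts use seeds derived from the master seed by a fixed string
  hash; all-zero motif matrices are a hard error, all-zero *rows*
  (mutation-free samples) are carried with zero exposures.
* Hierarchical clustering refuses missing values (imputation is always an
  explicit step) and renumbers labels 1..k by first occurrence, making
  partitions permutation-stable.
* Consensus entries with a zero co-sampling count are set to 0 and
  flagged; repetition counts below 50 are rejected.
* Chi-square tests run without continuity correction and fall back to
  Fisher's exact test when an expected cell count is below 5 or a margin
  is degenerate, everywhere the same.
* Ridge regression is computed through one SVD; the GCV grid spans
  10^-4..10^6.
* Exact score ties in checkpoint categorization go to "stimulatory";
  variable-site selection breaks variance ties by probe id; zero-variance
  selections are flagged.

# Problem sizes used in the validation suite

The packaged tests measure: five-subtype recovery on 20 cohorts of 500
samples (pipeline through COCA; 20 NMF restarts per rank, 500 consensus
repetitions); signature-rank recovery on 10 cohorts of 200 samples with 3
planted signatures; the Fisher oracle on every 2x2 table with margins up
to 30; driver precision/recall on 20 default cohorts plus 200 null
cohorts; classifier comparison on one default cohort with the full
method set; drug-screen specificity on 20 simulated two-panel screens;
and log-rank power (100 runs) and Cox coverage (200 runs) at the planted
hazard ratio. These sizes were chosen so the whole suite runs on a
laptop-class single core in minutes while keeping the Monte-Carlo error
of each asserted proportion well below its margin.

# Known limitations

* COCA consensus entries are estimates; very small cohorts (< ~40
  samples) make the CDF delta-area rule unstable.
* The cophenetic rank rule discriminates weakly when restart consensus is
  near-perfect at every rank (clean, high-burden cohorts); the peak tier
  of the rule handles this, but on real noisy data the cliff tier is the
  one expected to act.
* The drug screen's single-panel p-values are optimistic for prediction-
  based AUCs (see above); interpret candidates through the intersection
  only.
* The classifier is binary (focal vs rest) by design; a 5-way extension
  is out of scope.
* Survival utilities assume right-censoring independent of covariates.
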