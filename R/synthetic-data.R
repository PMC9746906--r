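# Synthetic multiomics cohort generator with planted subtype structure.
#
# The generator emulates the shapes of a pan-cancer TP53mut cohort: MAF-like
# somatic mutation records with trinucleotide contexts, a GISTIC-thresholded
# copy-number matrix over abstract focal fragments, an Illumina-450K-like
# methylation beta matrix with probe annotation, log2(TPM + 0.001) expression,
# and clinical survival endpoints. Subtype identity drives all layers so the
# integrated pipeline has recoverable ground truth.

#' Dirichlet sampler (internal)
#' @noRd
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Random sparse 96-context signature profiles
#'
#' Draws `n` mutational-signature profiles over the 96 pyrimidine-normalized
#' trinucleotide substitution classes from a sparse Dirichlet, giving
#' near-orthogonal signatures such as those dominated by a few contexts.
#'
#' @param n number of signatures.
#' @param concentration Dirichlet concentration per context (small = sparse).
#' @param seed integer seed.
#' @return An `n x 96` matrix with rows summing to 1, columns named by the
#'   substitution classes of [sbs_contexts()].
#' @export
random_signature_profiles <- function(n, concentration = 0.05, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  p <- t(vapply(seq_len(n), function(i) rdirichlet1(rep(concentration, 96)),
                numeric(96)))
  rownames(p) <- paste0("S", seq_len(n))
  colnames(p) <- sbs_contexts()
  p
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Configuration for the synthetic multiomics generator
#'
#' Defines the planted structure of a synthetic TP53mut cohort: subtype
#' proportions, subtype-specific mutational-signature mixtures, driver genes /
#' copy-number fragments / CpG probes with coupled expression effects,
#' subtype transcriptional programs, an inhibitory-checkpoint shift in one
#' subtype, and subtype-specific survival hazards.
#'
#' @param n_samples number of tumor samples.
#' @param n_subtypes number of planted subtypes (default 5).
#' @param subtype_proportions simplex vector of length `n_subtypes`.
#' @param n_signatures number of planted mutational signatures.
#' @param signature_profiles `n_signatures x 96` matrix, rows on the simplex;
#'   defaults to [random_signature_profiles()] drawn from `seed`.
#' @param exposures_by_subtype `n_subtypes x n_signatures` Dirichlet
#'   concentration matrix; default concentrates each subtype on one signature.
#' @param mutations_per_sample Poisson mean of passenger substitutions.
#' @param driver_genes data frame (gene, subtype, freq_in, freq_bg): mutation
#'   probability inside the driver's subtype and elsewhere.
#' @param smg_background data frame (gene, freq) of non-driver significantly
#'   mutated genes carried along for null driver testing.
#' @param driver_fragments data frame (fragment, subtype, direction
#'   ("amp"/"del"), frequency, gene, expr_effect): copy-number drivers with the
#'   additive log2-expression effect of carrying the alteration.
#' @param driver_cpgs data frame (probe, gene, subtype, frequency,
#'   expr_effect): hypermethylation drivers; `expr_effect` is the (negative)
#'   additive expression effect of the methylated state.
#' @param n_fragments total number of copy-number fragments (default 84).
#' @param cnv_program_size non-driver fragments per subtype carrying a
#'   subtype-linked alteration (clustering signal).
#' @param cnv_program_freq alteration frequency of program fragments in their
#'   subtype.
#' @param n_probes total number of methylation probes.
#' @param meth_program_size non-driver probes per subtype hypermethylated in
#'   that subtype.
#' @param meth_program_freq hypermethylation frequency of program probes in
#'   their subtype.
#' @param background_alteration_rate per-cell background CNV alteration rate.
#' @param background_hyper_rate background hypermethylation rate.
#' @param expression_program_size genes per subtype forming its
#'   transcriptional program.
#' @param expression_program_effect additive log2 shift of program genes in
#'   their subtype.
#' @param n_noise_genes unstructured expression genes.
#' @param n_checkpoint_genes genes per checkpoint category (stimulatory /
#'   inhibitory).
#' @param checkpoint_effect additive shift of inhibitory-checkpoint expression
#'   in `checkpoint_subtype`.
#' @param checkpoint_subtype subtype carrying the inhibitory shift (the
#'   immunosuppressive, poor-prognosis subtype; default 3).
#' @param expression_noise_sd Gaussian noise SD on the log2 scale.
#' @param survival_hazard_by_subtype exponential event hazards per subtype;
#'   default gives the checkpoint subtype a threefold hazard.
#' @param censoring_rate target fraction of censored subjects (independent
#'   uniform censoring).
#' @param n_normals normal-tissue methylation samples (for driver-CpG
#'   filtering).
#' @param n_cancer_types nominal cancer-type labels assigned independently of
#'   subtype.
#' @param seed master seed for the generator.
#' @return A `synthetic_config` list, validated against the generator's
#'   invariants.
#' @export
synthetic_config <- function(n_samples = 500,
                             n_subtypes = 5,
                             subtype_proportions = rep(1 / n_subtypes, n_subtypes),
                             n_signatures = 5,
                             signature_profiles = NULL,
                             exposures_by_subtype = NULL,
                             mutations_per_sample = 120,
                             driver_genes = NULL,
                             smg_background = NULL,
                             driver_fragments = NULL,
                             driver_cpgs = NULL,
                             n_fragments = 84,
                             cnv_program_size = 8,
                             cnv_program_freq = 0.65,
                             n_probes = 1000,
                             meth_program_size = 20,
                             meth_program_freq = 0.75,
                             background_alteration_rate = 0.05,
                             background_hyper_rate = 0.05,
                             expression_program_size = 30,
                             expression_program_effect = 1.0,
                             n_noise_genes = 300,
                             n_checkpoint_genes = 15,
                             checkpoint_effect = 1.2,
                             checkpoint_subtype = min(3L, n_subtypes),
                             expression_noise_sd = 1.0,
                             survival_hazard_by_subtype = NULL,
                             censoring_rate = 0.3,
                             n_normals = 40,
                             n_cancer_types = 4,
                             seed = 1) {
  K <- n_subtypes
  if (is.null(signature_profiles))
    signature_profiles <- random_signature_profiles(n_signatures, seed = seed)
  if (is.null(exposures_by_subtype)) {
    exposures_by_subtype <- matrix(1, K, n_signatures)
    for (s in seq_len(K))
      exposures_by_subtype[s, ((s - 1L) %% n_signatures) + 1L] <- 8
  }
  if (is.null(driver_genes)) {
    driver_genes <- data.frame(
      gene = sprintf("SMG%03d", seq_len(2L * K)),
      subtype = rep(seq_len(K), each = 2L),
      freq_in = 0.6, freq_bg = 0.05)
  }
  if (is.null(smg_background)) {
    n_bg <- max(0L, 127L - nrow(driver_genes))
    smg_background <- data.frame(
      gene = sprintf("SMG%03d", nrow(driver_genes) + seq_len(n_bg)),
      freq = 0.08)
  }
  if (is.null(driver_fragments)) {
    driver_fragments <- data.frame(
      fragment = sprintf("FRAG%02d", seq_len(2L * K)),
      subtype = rep(seq_len(K), each = 2L),
      direction = rep(c("amp", "del"), K),
      frequency = 0.7,
      gene = sprintf("CNVG_%d_%s", rep(seq_len(K), each = 2L),
                     rep(c("A", "D"), K)),
      expr_effect = rep(c(1.5, -1.5), K))
  }
  if (is.null(driver_cpgs)) {
    driver_cpgs <- data.frame(
      probe = sprintf("cg%06d", seq_len(2L * K)),
      gene = sprintf("METG_%d_%d", rep(seq_len(K), each = 2L), rep(1:2, K)),
      subtype = rep(seq_len(K), each = 2L),
      frequency = 0.8,
      expr_effect = -1.5)
  }
  if (is.null(survival_hazard_by_subtype)) {
    survival_hazard_by_subtype <- rep(0.1, K)
    survival_hazard_by_subtype[checkpoint_subtype] <- 0.3
  }
  cfg <- structure(list(
    n_samples = as.integer(n_samples), n_subtypes = as.integer(K),
    subtype_proportions = subtype_proportions,
    n_signatures = as.integer(n_signatures),
    signature_profiles = signature_profiles,
    exposures_by_subtype = exposures_by_subtype,
    mutations_per_sample = mutations_per_sample,
    driver_genes = driver_genes, smg_background = smg_background,
    driver_fragments = driver_fragments, driver_cpgs = driver_cpgs,
    n_fragments = as.integer(n_fragments),
    cnv_program_size = cnv_program_size, cnv_program_freq = cnv_program_freq,
    n_probes = as.integer(n_probes),
    meth_program_size = meth_program_size,
    meth_program_freq = meth_program_freq,
    background_alteration_rate = background_alteration_rate,
    background_hyper_rate = background_hyper_rate,
    expression_program_size = expression_program_size,
    expression_program_effect = expression_program_effect,
    n_noise_genes = as.integer(n_noise_genes),
    n_checkpoint_genes = as.integer(n_checkpoint_genes),
    checkpoint_effect = checkpoint_effect,
    checkpoint_subtype = as.integer(checkpoint_subtype),
    expression_noise_sd = expression_noise_sd,
    survival_hazard_by_subtype = survival_hazard_by_subtype,
    censoring_rate = censoring_rate,
    n_normals = as.integer(n_normals),
    n_cancer_types = as.integer(n_cancer_types),
    seed = as.integer(seed)), class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (abs(sum(cfg$subtype_proportions) - 1) > 1e-9)
    stop("configuration error: subtype_proportions must sum to 1")
  if (length(cfg$subtype_proportions) != cfg$n_subtypes)
    stop("configuration error: subtype_proportions length != n_subtypes")
  freqs <- c(cfg$driver_genes$freq_in, cfg$driver_genes$freq_bg,
             cfg$smg_background$freq, cfg$driver_fragments$frequency,
             cfg$driver_cpgs$frequency, cfg$cnv_program_freq,
             cfg$meth_program_freq, cfg$background_alteration_rate,
             cfg$background_hyper_rate, cfg$censoring_rate)
  if (any(freqs < 0 | freqs > 1))
    stop("configuration error: all frequencies must lie in [0, 1]")
  sp <- cfg$signature_profiles
  if (ncol(sp) != 96 || any(sp < 0) || any(abs(rowSums(sp) - 1) > 1e-9))
    stop("configuration error: signature_profiles rows must be nonnegative and sum to 1")
  if (nrow(sp) != cfg$n_signatures)
    stop("configuration error: signature_profiles rows != n_signatures")
  if (any(cfg$survival_hazard_by_subtype <= 0))
    stop("configuration error: survival hazards must be positive")
  need_probes <- nrow(cfg$driver_cpgs) +
    cfg$n_subtypes * cfg$meth_program_size + 20
  if (cfg$n_probes < need_probes)
    stop(sprintf(paste("configuration error: n_probes (%d) too small for the",
                       "planted structure (need >= %d)"),
         cfg$n_probes, need_probes))
  need_frags <- nrow(cfg$driver_fragments) +
    cfg$n_subtypes * cfg$cnv_program_size
  if (cfg$n_fragments < need_frags)
    stop(sprintf(paste("configuration error: n_fragments (%d) too small for",
                       "the planted structure (need >= %d)"),
         cfg$n_fragments, need_frags))
  if (!all(cfg$driver_genes$subtype %in% seq_len(cfg$n_subtypes)) ||
      !all(cfg$driver_fragments$subtype %in% seq_len(cfg$n_subtypes)) ||
      !all(cfg$driver_cpgs$subtype %in% seq_len(cfg$n_subtypes)))
    stop("configuration error: driver subtypes out of range")
  invisible(cfg)
}

# Decode a 96-class index into (ref, alt, fivep, threep) on the pyrimidine
# strand; optionally return the purine-strand (reverse-complement) record.
decode_context <- function(class_label, purine_strand = FALSE) {
  ref <- substr(class_label, 3, 3)
  alt <- substr(class_label, 5, 5)
  fivep <- substr(class_label, 1, 1)
  threep <- substr(class_label, 7, 7)
  if (purine_strand) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    list(ref = comp[[ref]], alt = comp[[alt]],
         context = paste0(comp[[threep]], comp[[ref]], comp[[fivep]]))
  } else {
    list(ref = ref, alt = alt, context = paste0(fivep, ref, threep))
  }
}

#' Generate a matched synthetic multiomics cohort
#'
#' Draws a full `multiomics_cohort` from a [synthetic_config()]: mutation
#' records whose trinucleotide contexts follow subtype-specific signature
#' mixtures, a 5-level copy-number matrix, a bimodal methylation beta matrix
#' (plus a normal-tissue panel for driver-CpG filtering), log2-scale
#' expression coupled to the planted drivers, and exponential survival with
#' independent uniform censoring. Deterministic for a fixed config seed.
#'
#' @param config a [synthetic_config()].
#' @return A `multiomics_cohort` list with elements `sample_ids`,
#'   `cancer_type`, `mutation_records`, `cnv`, `methylation`,
#'   `methylation_normal`, `probe_annotation`, `expression`, `clinical` and
#'   `truth` (planted subtypes, drivers, checkpoint subtype).
#' @export
generate_cohort <- function(config) {
  validate_synthetic_config(config)
  cfg <- config
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  n <- cfg$n_samples
  K <- cfg$n_subtypes
  samples <- sprintf("S%04d", seq_len(n))
  subtype <- sample(seq_len(K), n, replace = TRUE,
                    prob = cfg$subtype_proportions)
  names(subtype) <- samples
  cancer_type <- sample(sprintf("CT%02d", seq_len(cfg$n_cancer_types)), n,
                        replace = TRUE)
  names(cancer_type) <- samples
  contexts <- sbs_contexts()

  ## ---- mutation records -------------------------------------------------
  # passenger substitutions: counts ~ Poisson, contexts from the sample's
  # signature mixture (Dirichlet over the subtype's concentration row)
  rec_sample <- character(0); rec_gene <- character(0)
  rec_ref <- character(0); rec_alt <- character(0); rec_ctx <- character(0)
  passenger_pool <- sprintf("PSG%04d", 1:400)
  mix <- matrix(0, n, cfg$n_signatures)
  for (i in seq_len(n))
    mix[i, ] <- rdirichlet1(cfg$exposures_by_subtype[subtype[i], ])
  n_mut <- stats::rpois(n, cfg$mutations_per_sample)
  for (i in seq_len(n)) {
    if (n_mut[i] == 0) next
    sig <- sample.int(cfg$n_signatures, n_mut[i], replace = TRUE,
                      prob = mix[i, ])
    cls <- vapply(sig, function(s)
      sample.int(96, 1, prob = cfg$signature_profiles[s, ]), integer(1))
    strand <- stats::runif(n_mut[i]) < 0.5
    dec <- lapply(seq_along(cls), function(j)
      decode_context(contexts[cls[j]], purine_strand = strand[j]))
    rec_sample <- c(rec_sample, rep(samples[i], n_mut[i]))
    rec_gene <- c(rec_gene, sample(passenger_pool, n_mut[i], replace = TRUE))
    rec_ref <- c(rec_ref, vapply(dec, `[[`, character(1), "ref"))
    rec_alt <- c(rec_alt, vapply(dec, `[[`, character(1), "alt"))
    rec_ctx <- c(rec_ctx, vapply(dec, `[[`, character(1), "context"))
  }
  # SMG / driver gene mutation statuses (one record per mutated gene-sample)
  smg <- rbind(
    data.frame(gene = cfg$driver_genes$gene,
               subtype = cfg$driver_genes$subtype,
               freq_in = cfg$driver_genes$freq_in,
               freq_bg = cfg$driver_genes$freq_bg),
    data.frame(gene = cfg$smg_background$gene, subtype = NA_integer_,
               freq_in = cfg$smg_background$freq,
               freq_bg = cfg$smg_background$freq))
  for (g in seq_len(nrow(smg))) {
    p <- ifelse(!is.na(smg$subtype[g]) & subtype == smg$subtype[g],
                smg$freq_in[g], smg$freq_bg[g])
    hit <- stats::runif(n) < p
    if (!any(hit)) next
    m <- sum(hit)
    cls <- sample.int(96, m, replace = TRUE)
    dec <- lapply(contexts[cls], decode_context)
    rec_sample <- c(rec_sample, samples[hit])
    rec_gene <- c(rec_gene, rep(smg$gene[g], m))
    rec_ref <- c(rec_ref, vapply(dec, `[[`, character(1), "ref"))
    rec_alt <- c(rec_alt, vapply(dec, `[[`, character(1), "alt"))
    rec_ctx <- c(rec_ctx, vapply(dec, `[[`, character(1), "context"))
  }
  nr <- length(rec_sample)
  mutation_records <- data.frame(
    sample = rec_sample, gene = rec_gene,
    chromosome = sample(paste0("chr", 1:22), nr, replace = TRUE),
    position = sample.int(1e8, nr, replace = TRUE),
    ref = rec_ref, alt = rec_alt, context = rec_ctx,
    stringsAsFactors = FALSE)

  ## ---- copy number ------------------------------------------------------
  fragments <- sprintf("FRAG%02d", seq_len(cfg$n_fragments))
  cnv <- matrix(0L, cfg$n_fragments, n, dimnames = list(fragments, samples))
  # unstructured background alterations
  bg <- stats::runif(length(cnv)) < cfg$background_alteration_rate
  cnv[bg] <- sample(c(-2L, -1L, 1L, 2L), sum(bg), replace = TRUE,
                    prob = c(0.05, 0.45, 0.45, 0.05))
  # subtype CNV programs: fixed direction per fragment
  used <- cfg$driver_fragments$fragment
  free <- setdiff(fragments, used)
  program <- list()
  for (s in seq_len(K)) {
    take <- utils::head(free, cfg$cnv_program_size)
    free <- setdiff(free, take)
    program[[s]] <- take
    dir_s <- rep_len(c(1L, -1L), length(take))
    for (j in seq_along(take)) {
      hit <- stats::runif(n) < ifelse(subtype == s, cfg$cnv_program_freq,
                                      cfg$background_alteration_rate)
      lev <- sample(1:2, n, replace = TRUE, prob = c(0.7, 0.3))
      cnv[take[j], hit] <- dir_s[j] * lev[hit]
    }
  }
  # driver fragments with expression coupling
  frag_altered <- matrix(FALSE, nrow(cfg$driver_fragments), n)
  for (f in seq_len(nrow(cfg$driver_fragments))) {
    df <- cfg$driver_fragments[f, ]
    hit <- stats::runif(n) < ifelse(subtype == df$subtype, df$frequency,
                                    cfg$background_alteration_rate)
    sgn <- if (df$direction == "amp") 1L else -1L
    lev <- sample(1:2, n, replace = TRUE, prob = c(0.7, 0.3))
    cnv[df$fragment, ] <- 0L
    cnv[df$fragment, hit] <- sgn * lev[hit]
    frag_altered[f, ] <- hit
  }

  ## ---- methylation ------------------------------------------------------
  probes <- sprintf("cg%06d", seq_len(cfg$n_probes))
  beta <- matrix(NA_real_, cfg$n_probes, n, dimnames = list(probes, samples))
  hyper_state <- matrix(FALSE, cfg$n_probes, n,
                        dimnames = list(probes, samples))
  driver_probe_idx <- match(cfg$driver_cpgs$probe, probes)
  # assign non-driver probes: per-subtype programs, then noise
  free_p <- setdiff(seq_len(cfg$n_probes), driver_probe_idx)
  meth_program <- list()
  for (s in seq_len(K)) {
    take <- utils::head(free_p, cfg$meth_program_size)
    free_p <- setdiff(free_p, take)
    meth_program[[s]] <- take
  }
  noise_p <- free_p
  baseline_high <- rep(FALSE, cfg$n_probes)
  baseline_high[noise_p] <- stats::runif(length(noise_p)) < 0.15
  for (s in seq_len(K)) {
    for (pi in meth_program[[s]]) {
      hyper_state[pi, ] <- stats::runif(n) <
        ifelse(subtype == s, cfg$meth_program_freq, cfg$background_hyper_rate)
    }
  }
  for (f in seq_len(nrow(cfg$driver_cpgs))) {
    dc <- cfg$driver_cpgs[f, ]
    pi <- driver_probe_idx[f]
    hyper_state[pi, ] <- stats::runif(n) <
      ifelse(subtype == dc$subtype, dc$frequency, cfg$background_hyper_rate)
  }
  hyper_state[noise_p[baseline_high[noise_p]], ] <- TRUE
  # bimodal beta: low mode Beta(2,10), high mode Beta(10,2)
  n_high <- sum(hyper_state)
  beta[hyper_state] <- stats::rbeta(n_high, 10, 2)
  beta[!hyper_state] <- stats::rbeta(length(beta) - n_high, 2, 10)
  # normal-tissue panel: program/driver probes unmethylated (tight low mode,
  # Beta(2,18): normal unmethylated CpGs rarely exceed beta 0.3),
  # high-baseline noise probes methylated (these fail the normal criterion)
  normals <- sprintf("N%03d", seq_len(cfg$n_normals))
  beta_normal <- matrix(stats::rbeta(cfg$n_probes * cfg$n_normals, 2, 18),
                        cfg$n_probes, cfg$n_normals,
                        dimnames = list(probes, normals))
  hi <- which(baseline_high)
  if (length(hi))
    beta_normal[hi, ] <- stats::rbeta(length(hi) * cfg$n_normals, 10, 2)
  # probe annotation: a slice of noise probes sits on sex chromosomes or SNPs
  chrom <- sample(paste0("chr", 1:22), cfg$n_probes, replace = TRUE)
  snp <- rep(FALSE, cfg$n_probes)
  sexp <- noise_p[sample.int(length(noise_p),
                             max(1L, round(0.05 * length(noise_p))))]
  chrom[sexp] <- sample(c("chrX", "chrY"), length(sexp), replace = TRUE)
  snp_pool <- setdiff(noise_p, sexp)
  snpp <- snp_pool[sample.int(length(snp_pool),
                              min(length(snp_pool),
                                  max(1L, round(0.05 * length(noise_p)))))]
  snp[snpp] <- TRUE
  probe_gene <- rep(NA_character_, cfg$n_probes)
  probe_gene[driver_probe_idx] <- cfg$driver_cpgs$gene
  probe_annotation <- data.frame(probe = probes, chromosome = chrom,
                                 snp_overlap = snp, gene = probe_gene,
                                 stringsAsFactors = FALSE)

  ## ---- expression -------------------------------------------------------
  prog_genes <- unlist(lapply(seq_len(K), function(s)
    sprintf("PRG_%d_%02d", s, seq_len(cfg$expression_program_size))))
  stim_genes <- sprintf("ICSTIM%02d", seq_len(cfg$n_checkpoint_genes))
  inhib_genes <- sprintf("ICINH%02d", seq_len(cfg$n_checkpoint_genes))
  noise_genes <- sprintf("NSG%04d", seq_len(cfg$n_noise_genes))
  genes <- c(prog_genes, cfg$driver_fragments$gene, cfg$driver_cpgs$gene,
             stim_genes, inhib_genes, noise_genes)
  genes <- unique(genes)
  baseline <- stats::rnorm(length(genes), mean = 5, sd = 1.5)
  names(baseline) <- genes
  # checkpoint genes share one baseline so the stimulatory-vs-inhibitory
  # score comparison is calibrated at null (categories ~50/50 off-focal)
  baseline[c(stim_genes, inhib_genes)] <- 5
  expr <- matrix(stats::rnorm(length(genes) * n, 0, cfg$expression_noise_sd),
                 length(genes), n, dimnames = list(genes, samples))
  expr <- expr + baseline
  for (s in seq_len(K)) {
    gs <- sprintf("PRG_%d_%02d", s, seq_len(cfg$expression_program_size))
    expr[gs, subtype == s] <- expr[gs, subtype == s] +
      cfg$expression_program_effect
  }
  for (f in seq_len(nrow(cfg$driver_fragments))) {
    df <- cfg$driver_fragments[f, ]
    expr[df$gene, frag_altered[f, ]] <-
      expr[df$gene, frag_altered[f, ]] + df$expr_effect
  }
  for (f in seq_len(nrow(cfg$driver_cpgs))) {
    dc <- cfg$driver_cpgs[f, ]
    on <- hyper_state[driver_probe_idx[f], ]
    expr[dc$gene, on] <- expr[dc$gene, on] + dc$expr_effect
  }
  expr[inhib_genes, subtype == cfg$checkpoint_subtype] <-
    expr[inhib_genes, subtype == cfg$checkpoint_subtype] +
    cfg$checkpoint_effect

  ## ---- survival ---------------------------------------------------------
  clinical <- data.frame(sample = samples,
                         os_time = NA_real_, os_event = NA_integer_,
                         dss_time = NA_real_, dss_event = NA_integer_)
  for (endpoint in c("os", "dss")) {
    lam <- cfg$survival_hazard_by_subtype[subtype]
    t_event <- stats::rexp(n, rate = lam)
    cmax <- censoring_horizon(cfg$survival_hazard_by_subtype,
                              cfg$subtype_proportions, cfg$censoring_rate)
    t_cens <- stats::runif(n, 0, cmax)
    clinical[[paste0(endpoint, "_time")]] <- pmax(pmin(t_event, t_cens), 1e-6)
    clinical[[paste0(endpoint, "_event")]] <- as.integer(t_event <= t_cens)
  }

  truth_drivers <- rbind(
    data.frame(feature = cfg$driver_genes$gene, event_type = "mutation",
               subtype = cfg$driver_genes$subtype,
               gene = cfg$driver_genes$gene),
    data.frame(feature = cfg$driver_fragments$fragment,
               event_type = ifelse(cfg$driver_fragments$direction == "amp",
                                   "amplification", "deletion"),
               subtype = cfg$driver_fragments$subtype,
               gene = cfg$driver_fragments$gene),
    data.frame(feature = cfg$driver_cpgs$probe,
               event_type = "hypermethylation",
               subtype = cfg$driver_cpgs$subtype, gene = cfg$driver_cpgs$gene))

  structure(list(
    sample_ids = samples,
    cancer_type = cancer_type,
    mutation_records = mutation_records,
    cnv = cnv,
    methylation = beta,
    methylation_normal = beta_normal,
    probe_annotation = probe_annotation,
    expression = expr,
    clinical = clinical,
    truth = list(subtype = subtype,
                 drivers = truth_drivers,
                 checkpoint_subtype = cfg$checkpoint_subtype,
                 checkpoint_sets = list(stimulatory = stim_genes,
                                        inhibitory = inhib_genes),
                 signature_profiles = cfg$signature_profiles,
                 smg_genes = smg$gene),
    config = cfg), class = "multiomics_cohort")
}

# Uniform-censoring horizon giving the target marginal censoring fraction
# for an exponential mixture: P(C < T) = sum_s pi_s (1 - (1-e^{-l_s c})/(l_s c)).
censoring_horizon <- function(hazards, proportions, rate) {
  if (rate <= 0) return(Inf)
  f <- function(cmax) {
    sum(proportions * (1 - (1 - exp(-hazards * cmax)) / (hazards * cmax))) -
      rate
  }
  stats::uniroot(f, lower = 1e-6, upper = 1e6)$root
}

#' @export
print.multiomics_cohort <- function(x, ...) {
  cat(sprintf(paste0("<multiomics_cohort> %d samples | %d mutation records | ",
                     "%d fragments | %d probes | %d genes\n"),
              length(x$sample_ids), nrow(x$mutation_records), nrow(x$cnv),
              nrow(x$methylation), nrow(x$expression)))
  if (!is.null(x$truth))
    cat(sprintf("planted subtypes: %s\n",
                paste(table(x$truth$subtype), collapse = "/")))
  invisible(x)
}

#' Generate a synthetic cancer-cell-line panel
#'
#' Emulates a GDSC/CTRP-like screen: cell lines carry the same planted
#' subtype expression programs as the patient cohort (with extra noise), and
#' a drug x cell-line AUC matrix in which planted sensitive (drug, subtype)
#' pairs have lower AUC in cell lines of the paired subtype. Missing AUC
#' entries are placed completely at random.
#'
#' @param config a [synthetic_config()] (defines subtypes and expression
#'   programs).
#' @param n_cell_lines,n_drugs panel dimensions (both >= 2).
#' @param missing_rate fraction of AUC entries set missing, in `[0, 1)`.
#' @param sensitive_pairs data frame (drug, subtype, effect) of planted
#'   sensitivities; `effect` is the additive AUC shift (negative = sensitive).
#' @param seed integer seed (independent of the cohort's).
#' @param auc_noise_sd Gaussian noise SD of AUC values.
#' @return A `ccl_panel` list with `cell_line_ids`, `expression`, `auc`,
#'   `missing_fraction` (per drug) and `truth`.
#' @export
generate_ccl_panel <- function(config, n_cell_lines = 120, n_drugs = 50,
                               missing_rate = 0.1,
                               sensitive_pairs = NULL, seed = 1,
                               auc_noise_sd = 0.5) {
  if (n_cell_lines < 2 || n_drugs < 2)
    stop("configuration error: n_cell_lines and n_drugs must both be >= 2")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("configuration error: missing_rate must lie in [0, 1)")
  validate_synthetic_config(config)
  cfg <- config
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  K <- cfg$n_subtypes
  lines <- sprintf("CL%03d", seq_len(n_cell_lines))
  subtype <- sample(seq_len(K), n_cell_lines, replace = TRUE,
                    prob = cfg$subtype_proportions)
  names(subtype) <- lines
  prog_genes <- unlist(lapply(seq_len(K), function(s)
    sprintf("PRG_%d_%02d", s, seq_len(cfg$expression_program_size))))
  stim_genes <- sprintf("ICSTIM%02d", seq_len(cfg$n_checkpoint_genes))
  inhib_genes <- sprintf("ICINH%02d", seq_len(cfg$n_checkpoint_genes))
  noise_genes <- sprintf("NSG%04d", seq_len(cfg$n_noise_genes))
  genes <- unique(c(prog_genes, cfg$driver_fragments$gene,
                    cfg$driver_cpgs$gene, stim_genes, inhib_genes,
                    noise_genes))
  baseline <- stats::rnorm(length(genes), 5, 1.5)
  baseline[match(c(stim_genes, inhib_genes), genes)] <- 5
  expr <- matrix(stats::rnorm(length(genes) * n_cell_lines, 0,
                              cfg$expression_noise_sd * 1.2),
                 length(genes), n_cell_lines,
                 dimnames = list(genes, lines))
  expr <- expr + baseline
  for (s in seq_len(K)) {
    gs <- sprintf("PRG_%d_%02d", s, seq_len(cfg$expression_program_size))
    expr[gs, subtype == s] <- expr[gs, subtype == s] +
      cfg$expression_program_effect
  }
  drugs <- sprintf("DRUG%03d", seq_len(n_drugs))
  mu <- stats::runif(n_drugs, 8, 14)
  auc <- matrix(stats::rnorm(n_drugs * n_cell_lines, 0, auc_noise_sd),
                n_drugs, n_cell_lines, dimnames = list(drugs, lines))
  auc <- auc + mu
  if (!is.null(sensitive_pairs) && nrow(sensitive_pairs) > 0) {
    for (i in seq_len(nrow(sensitive_pairs))) {
      sp <- sensitive_pairs[i, ]
      auc[sp$drug, subtype == sp$subtype] <-
        auc[sp$drug, subtype == sp$subtype] + sp$effect
    }
  }
  auc <- pmax(auc, 0.01)
  if (missing_rate > 0) {
    mask <- stats::runif(length(auc)) < missing_rate
    auc[mask] <- NA_real_
  }
  structure(list(cell_line_ids = lines,
                 expression = expr,
                 auc = auc,
                 missing_fraction = rowMeans(is.na(auc)),
                 truth = list(subtype = subtype,
                              sensitive_pairs = sensitive_pairs)),
            class = "ccl_panel")
}

#' @export
print.ccl_panel <- function(x, ...) {
  cat(sprintf("<ccl_panel> %d cell lines x %d drugs (%.1f%% AUC missing)\n",
              length(x$cell_line_ids), nrow(x$auc),
              100 * mean(is.na(x$auc))))
  invisible(x)
}
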