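# 96-context motif matrix construction from MAF-like substitution records.

#' The 96 pyrimidine-normalized trinucleotide substitution classes
#'
#' Column order is fixed: substitution-major (C>A, C>G, C>T, T>A, T>C, T>G),
#' then 5' flank (A, C, G, T), then 3' flank (A, C, G, T), giving labels
#' `A[C>A]A`, `A[C>A]C`, ..., `T[T>G]T`.
#'
#' @return Character vector of length 96.
#' @export
sbs_contexts <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs) {
    ref <- substr(s, 1, 1)
    alt <- substr(s, 3, 3)
    for (b5 in bases) for (b3 in bases)
      out <- c(out, sprintf("%s[%s>%s]%s", b5, ref, alt, b3))
  }
  out
}

revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(x, ""), function(ch)
    paste(rev(unname(comp[ch])), collapse = ""), character(1))
}

#' Build the sample x 96 motif matrix from substitution records
#'
#' Counts single-nucleotide substitutions per sample in the 96
#' pyrimidine-normalized trinucleotide classes. Records with a purine
#' reference allele (A/G) are reverse-complemented into the pyrimidine class.
#' Records that are not single-base substitutions, or whose context string is
#' malformed (length != 3 or middle base != reference allele), are skipped
#' and counted in the `skipped` attribute, with a warning.
#'
#' @param mutation_records data frame with columns `sample`, `ref`, `alt`,
#'   `context` (5'-ref-3' trinucleotide on the reported strand).
#' @param sample_ids character vector of samples to report rows for; samples
#'   without valid substitutions get zero rows.
#' @return Integer matrix `length(sample_ids) x 96` with columns
#'   [sbs_contexts()] and attribute `skipped` (number of invalid records).
#' @export
build_motif_matrix <- function(mutation_records, sample_ids) {
  contexts <- sbs_contexts()
  counts <- matrix(0L, length(sample_ids), 96,
                   dimnames = list(sample_ids, contexts))
  if (is.null(mutation_records) || nrow(mutation_records) == 0) {
    attr(counts, "skipped") <- 0L
    return(counts)
  }
  stopifnot(all(c("sample", "ref", "alt", "context") %in%
                  names(mutation_records)))
  rec <- mutation_records[mutation_records$sample %in% sample_ids, ,
                          drop = FALSE]
  ref <- toupper(rec$ref); alt <- toupper(rec$alt)
  ctx <- toupper(rec$context)
  bases <- c("A", "C", "G", "T")
  is_snv <- nchar(ref) == 1 & nchar(alt) == 1 & ref %in% bases &
    alt %in% bases & ref != alt
  valid_ctx <- nchar(ctx) == 3 & substr(ctx, 2, 2) == ref &
    !is.na(ctx) & grepl("^[ACGT]{3}$", ctx)
  keep <- is_snv & valid_ctx
  n_skip <- sum(is_snv & !valid_ctx)  # malformed contexts on true SNVs
  if (n_skip > 0)
    warning(sprintf("skipped %d record(s) with malformed context", n_skip))
  rec <- rec[keep, , drop = FALSE]
  ref <- ref[keep]; alt <- alt[keep]; ctx <- ctx[keep]
  if (nrow(rec) > 0) {
    purine <- ref %in% c("A", "G")
    if (any(purine)) {
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      ref[purine] <- unname(comp[ref[purine]])
      alt[purine] <- unname(comp[alt[purine]])
      ctx[purine] <- revcomp(ctx[purine])
    }
    label <- sprintf("%s[%s>%s]%s", substr(ctx, 1, 1), ref, alt,
                     substr(ctx, 3, 3))
    tab <- table(factor(rec$sample, levels = sample_ids),
                 factor(label, levels = contexts))
    counts <- counts + unclass(tab)
  }
  storage.mode(counts) <- "integer"
  attr(counts, "skipped") <- n_skip
  counts
}
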