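# Plain-text readers and writers for the cohort's standard shapes:
# MAF-like mutation TSV, feature x sample matrix TSV, clinical TSV,
# gene lists, truth JSON and YAML configs.

#' Write / read a feature x sample matrix as TSV
#'
#' First column `feature`, remaining columns the sample ids.
#'
#' @param x matrix with row and column names.
#' @param path file path.
#' @return `read_feature_matrix` returns a numeric matrix.
#' @export
write_feature_matrix <- function(x, path) {
  df <- data.frame(feature = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read / write MAF-like mutation records
#'
#' Columns follow the MAF convention: `Tumor_Sample_Barcode`, `Hugo_Symbol`,
#' `Chromosome`, `Start_Position`, `Reference_Allele`, `Tumor_Seq_Allele2`,
#' plus a `context` column holding the trinucleotide context.
#'
#' @param mutation_records data frame as in a `multiomics_cohort`.
#' @param path file path.
#' @return `read_maf` returns a mutation-record data frame with the
#'   package's internal column names.
#' @export
write_maf <- function(mutation_records, path) {
  out <- data.frame(Tumor_Sample_Barcode = mutation_records$sample,
                    Hugo_Symbol = mutation_records$gene,
                    Chromosome = mutation_records$chromosome,
                    Start_Position = mutation_records$position,
                    Reference_Allele = mutation_records$ref,
                    Tumor_Seq_Allele2 = mutation_records$alt,
                    context = mutation_records$context)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_maf
#' @export
read_maf <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(Chromosome = "character"))
  data.frame(sample = df$Tumor_Sample_Barcode, gene = df$Hugo_Symbol,
             chromosome = df$Chromosome, position = df$Start_Position,
             ref = df$Reference_Allele, alt = df$Tumor_Seq_Allele2,
             context = df$context, stringsAsFactors = FALSE)
}

#' Read a plain-text gene list (one gene per line)
#'
#' @param path file path.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Write a cluster assignment as a two-column TSV (sample, label)
#'
#' @param assignment a [cluster_assignment()] or named label vector.
#' @param path file path.
#' @export
write_cluster_assignment <- function(assignment, path) {
  lab <- as_labels(assignment)
  utils::write.table(data.frame(sample = names(lab), label = unname(lab)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Emits `mutations.maf.tsv`, `cnv.tsv`, `methylation.tsv`,
#' `methylation_normal.tsv`, `probe_annotation.tsv`, `expression.tsv`,
#' `clinical.tsv`, `truth.json` and `config.yaml`.
#'
#' @param cohort a `multiomics_cohort`.
#' @param dir output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_maf(cohort$mutation_records, file.path(dir, "mutations.maf.tsv"))
  write_feature_matrix(cohort$cnv, file.path(dir, "cnv.tsv"))
  write_feature_matrix(cohort$methylation, file.path(dir, "methylation.tsv"))
  write_feature_matrix(cohort$methylation_normal,
                       file.path(dir, "methylation_normal.tsv"))
  utils::write.table(cohort$probe_annotation,
                     file.path(dir, "probe_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_feature_matrix(cohort$expression, file.path(dir, "expression.tsv"))
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$truth)) {
    truth <- cohort$truth
    truth$signature_profiles <- NULL  # large; regenerable from the config
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(cohort$config)) {
    cfg <- cohort$config
    cfg$signature_profiles <- NULL
    cfg$exposures_by_subtype <- NULL
    yaml::write_yaml(lapply(unclass(cfg), function(el)
      if (is.data.frame(el)) as.list(el) else el),
      file.path(dir, "config.yaml"))
  }
  invisible(dir)
}
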