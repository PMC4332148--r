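# Plain-text input / output ------------------------------------------------

#' Read / write peptide quantification tables (TSV)
#'
#' The on-disk dialect is a tab-separated table with columns `sample_id`,
#' `protein`, `peptide_id`, `xic_area`, `sn_ratio`, `is_standard`.
#'
#' @param path file path.
#' @return [read_peptide_table()]: a keyed data.table;
#'   [write_peptide_table()]: `path`, invisibly.
#' @export
read_peptide_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", encoding = "UTF-8")
  as_peptide_table(dt)
}

#' @rdname read_peptide_table
#' @param table peptide table to write.
#' @export
write_peptide_table <- function(table, path) {
  data.table::fwrite(data.table::as.data.table(table), path, sep = "\t")
  invisible(path)
}

#' Read / write a PAI matrix (TSV)
#'
#' Wide TSV: first column `protein`, then one column per sample; the peptide
#' support (reference peptide count, median S/N) travels in companion
#' columns `n_peptides` and `median_sn` placed after the samples.
#'
#' @param pai a `pai_matrix`.
#' @param path file path.
#' @return [read_pai_matrix()]: a `pai_matrix`; the writer returns `path`.
#' @export
write_pai_matrix <- function(pai, path) {
  stopifnot(inherits(pai, "pai_matrix"))
  df <- data.frame(protein = rownames(pai$values), pai$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  idx <- match(df$protein, pai$peptide_support$protein)
  df$n_peptides <- pai$peptide_support$n_peptides[idx]
  df$median_sn <- pai$peptide_support$median_sn[idx]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' @rdname write_pai_matrix
#' @export
read_pai_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, encoding = "UTF-8",
                          na.strings = "")
  meta_cols <- c("protein", "n_peptides", "median_sn")
  sample_cols <- setdiff(names(df), meta_cols)
  values <- as.matrix(df[, sample_cols, drop = FALSE])
  rownames(values) <- df$protein
  ps <- data.frame(protein = df$protein, n_peptides = df$n_peptides,
                   median_sn = df$median_sn, stringsAsFactors = FALSE)
  structure(list(values = values, peptide_support = ps, refs = NULL),
            class = "pai_matrix")
}

#' Write a simulated dataset to a directory
#'
#' Emits `peptides.tsv` (the peptide quantification table), `metadata.tsv`
#' (sample annotations) and `truth.json` (ground-truth model parameters and
#' realized per-sample abundances) so downstream stages can be re-run from
#' plain files.
#'
#' @param sim a `sim_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_peptide_table(sim$peptide_table, file.path(dir, "peptides.tsv"))
  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  truth <- sim$truth
  tr <- list(
    seed = truth$model$seed,
    capture_yield = truth$model$capture_yield,
    peptide_model = truth$model$peptide_model,
    cell_lines = truth$model$cell_lines,
    association_propensity = list(
      regulators = rownames(truth$model$association_propensity),
      subtypes = colnames(truth$model$association_propensity),
      values = unname(as.data.frame(truth$model$association_propensity))),
    subtype_abundance = if (is.null(truth$subtype_abundance)) NULL else
      list(subtypes = rownames(truth$subtype_abundance),
           samples = colnames(truth$subtype_abundance),
           values = unname(as.data.frame(truth$subtype_abundance))),
    protein_truth = list(proteins = rownames(truth$protein_truth),
                         samples = colnames(truth$protein_truth),
                         values = unname(as.data.frame(truth$protein_truth))),
    run_scale = as.list(truth$run_scale))
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write a data.frame as UTF-8 TSV without quoting
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
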