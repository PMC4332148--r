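# Internal-standard calibration and TOP3 protein abundance indexes --------

#' Validate / coerce a peptide quantification table
#'
#' Long-form table with one row per peptide ion per sample: columns
#' `sample_id`, `protein`, `peptide_id`, `xic_area` (>= 0), optional
#' `sn_ratio`, and logical `is_standard` flagging spiked isotopically
#' labeled standard peptides. `(sample_id, protein, peptide_id)` must be
#' unique.
#'
#' @param x data.frame or data.table.
#' @return A keyed data.table.
#' @export
as_peptide_table <- function(x) {
  dt <- data.table::as.data.table(x)
  need <- c("sample_id", "protein", "peptide_id", "xic_area")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("peptide table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!"is_standard" %in% names(dt)) dt[, is_standard := FALSE]
  if (!"sn_ratio" %in% names(dt)) dt[, sn_ratio := NA_real_]
  if (any(dt$xic_area < 0, na.rm = TRUE)) stop("xic_area must be >= 0")
  if (anyDuplicated(dt, by = c("sample_id", "protein", "peptide_id")))
    stop("duplicate (sample_id, protein, peptide_id) rows")
  data.table::setkey(dt, sample_id, protein, peptide_id)
  dt[]
}

#' Calibrate inter-run signal with spiked internal standards
#'
#' For each sample, the scale factor is the median over the standard
#' peptides of (cross-sample mean intensity of that standard / its intensity
#' in this sample). Every row of the sample (standards included) is
#' multiplied by the factor, which removes per-run drift; a run with no
#' observed standard is an error.
#'
#' @param table a peptide quantification table (see [as_peptide_table()]).
#' @return List with `table` (calibrated data.table) and `factors`
#'   (data.frame `sample_id`, `factor`).
#' @examples
#' tab <- data.frame(sample_id = rep(c("a", "b"), each = 2),
#'                   protein = "P1", peptide_id = rep(c("p1", "s1"), 2),
#'                   xic_area = c(10, 100, 20, 200),
#'                   is_standard = rep(c(FALSE, TRUE), 2))
#' calibrate_runs(tab)$factors
#' @export
calibrate_runs <- function(table) {
  dt <- as_peptide_table(table)
  samples <- unique(dt$sample_id)
  std <- dt[is_standard & xic_area > 0]
  no_std <- setdiff(samples, unique(std$sample_id))
  if (length(no_std))
    stop("sample(s) without observed internal standards: ",
         paste(no_std, collapse = ", "))
  std[, ref := mean(xic_area), by = peptide_id]
  fac <- std[, .(factor = stats::median(ref / xic_area)), by = sample_id]
  out <- data.table::copy(dt)
  fmap <- stats::setNames(fac$factor, fac$sample_id)
  out[, xic_area := xic_area * fmap[sample_id]]
  list(table = out[], factors = as.data.frame(fac))
}

#' Select up to three reference peptides per protein (TOP3)
#'
#' Peptides are ranked by their summed calibrated intensity across all
#' samples (a peptide missing in a sample contributes 0) and the top three
#' retained; proteins with fewer peptides keep them all. Exact ties are
#' broken lexicographically by `peptide_id` so the selection is
#' deterministic. Standard peptides are never selected.
#'
#' @param table a calibrated peptide table.
#' @return Named list: protein -> character vector of <= 3 peptide ids.
#' @export
select_reference_peptides <- function(table) {
  dt <- as_peptide_table(table)[!(is_standard)]
  sums <- dt[, .(total = sum(xic_area)), by = .(protein, peptide_id)]
  data.table::setorder(sums, protein, -total, peptide_id)
  top <- sums[, utils::head(.SD, 3L), by = protein]
  split(top$peptide_id, top$protein)
}

#' Compute protein abundance indexes (PAIs)
#'
#' The PAI of a protein in a sample is the arithmetic mean of its reference
#' peptides' calibrated intensities in that sample. A reference peptide not
#' observed in a sample is, by default, left out of the mean
#' (`missing_ref = "mean"`); with `missing_ref = "zero"` it contributes 0.
#' If no reference peptide is observed the PAI is missing (`NA`).
#'
#' @param table a calibrated peptide table.
#' @param refs reference-peptide map from [select_reference_peptides()]
#'   computed on the same table (computed on the fly when `NULL`).
#' @param missing_ref `"mean"` (mean over observed reference peptides) or
#'   `"zero"` (unobserved reference peptides impute 0).
#' @return Object of class `pai_matrix`: list with `values` (numeric matrix,
#'   proteins x samples, `NA` = missing), `peptide_support` (data.frame
#'   `protein`, `n_peptides` in 1..3, `median_sn`) and `refs`.
#' @export
compute_pai <- function(table, refs = NULL,
                        missing_ref = c("mean", "zero")) {
  missing_ref <- match.arg(missing_ref)
  dt <- as_peptide_table(table)
  if (is.null(refs)) refs <- select_reference_peptides(dt)
  samples <- sort(unique(dt$sample_id))
  ref_dt <- data.table::data.table(
    protein = rep(names(refs), lengths(refs)),
    peptide_id = unlist(refs, use.names = FALSE))
  obs <- dt[!(is_standard)][ref_dt, on = c("protein", "peptide_id"),
                            nomatch = NULL]
  if (missing_ref == "mean") {
    pai <- obs[, .(pai = mean(xic_area)), by = .(protein, sample_id)]
  } else {
    n_ref <- stats::setNames(lengths(refs), names(refs))
    pai <- obs[, .(pai = sum(xic_area) / n_ref[[protein[1]]]),
               by = .(protein, sample_id)]
  }
  proteins <- sort(names(refs))
  values <- matrix(NA_real_, length(proteins), length(samples),
                   dimnames = list(proteins, samples))
  values[cbind(pai$protein, pai$sample_id)] <- pai$pai
  support <- dt[!(is_standard),
                .(n_all = data.table::uniqueN(peptide_id),
                  median_sn = stats::median(sn_ratio, na.rm = TRUE)),
                by = protein]
  support <- support[match(proteins, protein)]
  ps <- data.frame(protein = proteins,
                   n_peptides = pmin(unname(lengths(refs[proteins])), 3L),
                   n_distinct_peptides = support$n_all,
                   median_sn = support$median_sn,
                   stringsAsFactors = FALSE)
  structure(list(values = values, peptide_support = ps, refs = refs),
            class = "pai_matrix")
}

#' @export
print.pai_matrix <- function(x, ...) {
  cat(sprintf("pai_matrix: %d proteins x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' One-call quantification: calibrate, pick references, compute PAIs
#'
#' @param table a raw peptide quantification table.
#' @param calibrate apply internal-standard run calibration first.
#' @inheritParams compute_pai
#' @return A `pai_matrix` with the calibration factors attached as attribute
#'   `"calibration_factors"` (NULL when `calibrate = FALSE`).
#' @export
quantify <- function(table, calibrate = TRUE,
                     missing_ref = c("mean", "zero")) {
  missing_ref <- match.arg(missing_ref)
  fac <- NULL
  if (calibrate) {
    cal <- calibrate_runs(table)
    table <- cal$table
    fac <- cal$factors
  }
  refs <- select_reference_peptides(table)
  out <- compute_pai(table, refs, missing_ref = missing_ref)
  attr(out, "calibration_factors") <- fac
  out
}

#' Subset a PAI matrix to a sample set (keeping order)
#'
#' @param pai a `pai_matrix`.
#' @param samples character vector of sample ids (must all be present).
#' @return A `pai_matrix` restricted to `samples`.
#' @export
subset_samples <- function(pai, samples) {
  stopifnot(inherits(pai, "pai_matrix"))
  miss <- setdiff(samples, colnames(pai$values))
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  pai$values <- pai$values[, samples, drop = FALSE]
  pai
}
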