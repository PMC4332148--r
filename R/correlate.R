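# Cross-purification abundance correlation (R / R2) -----------------------

#' Reference complex abundances across an AP-MS sample set
#'
#' For each complex definition, the per-sample abundance is the median, mean
#' or single member's PAI over the detected members (intersection rule);
#' member PAIs missing in a sample are treated as 0, since absence from an
#' immunoprecipitate of a fixed bait is informative.
#'
#' @param pai a `pai_matrix` (AP-MS mode: samples are purifications).
#' @param defs named list of `complex_definition`.
#' @param catalog a `subunit_catalog`.
#' @return List of class `reference_abundances`: `values` (matrix,
#'   references x samples) and `members_used` (named list of accessions).
#' @export
build_reference_abundances <- function(pai, defs, catalog) {
  stopifnot(inherits(pai, "pai_matrix"))
  mat <- pai$values
  mat[is.na(mat)] <- 0
  rows <- lapply(defs, function(def) {
    accs <- subunit_accessions(def$members, catalog)
    used <- intersect(accs, rownames(mat))
    if (length(used) == 0L)
      stop("no member of reference '", def$name, "' detected")
    sub <- mat[used, , drop = FALSE]
    val <- switch(def$aggregation,
                  median = apply(sub, 2L, stats::median),
                  mean = colMeans(sub),
                  single = sub[1L, ])
    list(val = val, used = used)
  })
  values <- do.call(rbind, lapply(rows, `[[`, "val"))
  rownames(values) <- vapply(defs, `[[`, "", "name")
  structure(list(values = values,
                 members_used = stats::setNames(lapply(rows, `[[`, "used"),
                                                rownames(values))),
            class = "reference_abundances")
}

#' Pearson correlation record between two abundance vectors
#'
#' Missing values are set to 0 in both vectors; at least 3 samples are
#' required. The correlation is computed on raw (untransformed) values and
#' the coefficient of determination is its square. A zero-variance vector
#' yields an `undefined` record (r = NA), which downstream consumers
#' exclude.
#'
#' @param x,y numeric vectors over the same samples.
#' @return List of class `correlation_record`: `r`, `r2`, `n`, `undefined`.
#' @examples
#' correlate(c(1, 2, 3, 4), c(2, 4, 6, 8))$r2  # 1
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("vectors cover different sample sets")
  x[is.na(x)] <- 0
  y[is.na(y)] <- 0
  if (length(x) < 3L) stop("need at least 3 samples")
  undef <- stats::sd(x) == 0 || stats::sd(y) == 0
  r <- if (undef) NA_real_ else stats::cor(x, y)
  structure(list(r = r, r2 = r^2, n = length(x), undefined = undef),
            class = "correlation_record")
}

#' Correlation matrix of target proteins against references
#'
#' @param pai a `pai_matrix`.
#' @param refs a `reference_abundances` over the same samples.
#' @param targets character vector of protein accessions (subset of the
#'   matrix rows; default all proteins).
#' @return List with `r2` and `r` matrices (targets x references, `NA` for
#'   undefined records) and `n` (samples used).
#' @export
correlation_matrix <- function(pai, refs, targets = NULL) {
  stopifnot(inherits(pai, "pai_matrix"),
            inherits(refs, "reference_abundances"))
  if (is.null(targets)) targets <- rownames(pai$values)
  miss <- setdiff(targets, rownames(pai$values))
  if (length(miss)) stop("target(s) not in matrix: ",
                         paste(miss, collapse = ", "))
  if (!identical(colnames(pai$values), colnames(refs$values)))
    stop("pai and references cover different samples")
  X <- pai$values[targets, , drop = FALSE]
  X[is.na(X)] <- 0
  R <- refs$values
  r <- matrix(NA_real_, length(targets), nrow(R),
              dimnames = list(targets, rownames(R)))
  ok_t <- apply(X, 1L, stats::sd) > 0
  ok_r <- apply(R, 1L, stats::sd) > 0
  if (any(ok_t) && any(ok_r))
    r[ok_t, ok_r] <- stats::cor(t(X[ok_t, , drop = FALSE]),
                                t(R[ok_r, , drop = FALSE]))
  list(r2 = r^2, r = r, n = ncol(X))
}

#' Confidence filter for putative complex-interacting proteins
#'
#' Keeps proteins that (i) correlate (signed Pearson r strictly above
#' `r_threshold`) with at least one of the subtype references, (ii) are
#' quantified with at least `min_peptides` reference peptides, and (iii)
#' have a median signal-to-noise ratio strictly above `min_median_sn`. Each
#' kept protein is labeled with the subtype reference of maximal r.
#'
#' @param pai a `pai_matrix` (provides peptide support and S/N).
#' @param r_matrix signed r matrix (targets x references) from
#'   [correlation_matrix()].
#' @param subtype_refs the three reference columns defining the filter
#'   (default `ncP20S`, `sP20S`, `iP20S`).
#' @param r_threshold signed-r threshold (default 0.8); anticorrelation does
#'   not pass.
#' @param min_peptides minimum reference peptides (default 2).
#' @param min_median_sn minimum median S/N (default 10).
#' @return data.frame of survivors: `protein`, `best_reference`, `best_r`,
#'   `n_peptides`, `median_sn`. May have zero rows.
#' @export
filter_pips <- function(pai, r_matrix,
                        subtype_refs = c("ncP20S", "sP20S", "iP20S"),
                        r_threshold = 0.8, min_peptides = 2,
                        min_median_sn = 10) {
  stopifnot(inherits(pai, "pai_matrix"))
  miss <- setdiff(subtype_refs, colnames(r_matrix))
  if (length(miss)) stop("r_matrix lacks reference column(s): ",
                         paste(miss, collapse = ", "))
  sub <- r_matrix[, subtype_refs, drop = FALSE]
  ps <- pai$peptide_support
  idx <- match(rownames(sub), ps$protein)
  best <- apply(sub, 1L, function(v) if (all(is.na(v))) NA_real_ else
    max(v, na.rm = TRUE))
  keep <- !is.na(best) & best > r_threshold &
    ps$n_peptides[idx] >= min_peptides &
    !is.na(ps$median_sn[idx]) & ps$median_sn[idx] > min_median_sn
  kept <- which(keep)
  data.frame(
    protein = rownames(sub)[kept],
    best_reference = subtype_refs[apply(sub[kept, , drop = FALSE], 1L,
                                        which.max)],
    best_r = best[kept],
    n_peptides = ps$n_peptides[idx][kept],
    median_sn = ps$median_sn[idx][kept],
    row.names = NULL, stringsAsFactors = FALSE)
}
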