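# Differential regulator association between conditions -------------------

#' Per-sample regulator abundance (mean of member PAIs)
#'
#' Unlike the eight correlation references (median aggregation), the
#' differential analysis uses the arithmetic mean of the PAIs of all the
#' proteins belonging to the regulator, per sample; a member PAI missing in
#' a sample contributes 0.
#'
#' @param pai a `pai_matrix`.
#' @param def a `complex_definition` for the regulator.
#' @param catalog a `subunit_catalog`.
#' @return List: `values` (named numeric per sample), `members_used`.
#' @export
regulator_pai <- function(pai, def, catalog) {
  stopifnot(inherits(pai, "pai_matrix"), inherits(def, "complex_definition"))
  mat <- pai$values
  mat[is.na(mat)] <- 0
  accs <- subunit_accessions(def$members, catalog)
  used <- intersect(accs, rownames(mat))
  if (length(used) == 0L)
    stop("no member of regulator '", def$name, "' detected")
  list(values = colMeans(mat[used, , drop = FALSE]), members_used = used)
}

#' Normalize a regulator PAI by the core-particle PAI
#'
#' Per sample, the ratio of the regulator's PAI to the ncP20S PAI. The
#' denominator cancels global per-sample intensity scale, so the ratio
#' reflects regulator load per 20S core particle. Samples with a zero
#' denominator are excluded and reported.
#'
#' @param reg regulator per-sample values (from [regulator_pai()] or a
#'   named numeric vector).
#' @param nc ncP20S per-sample values (same samples).
#' @return List: `values` (named ratios over retained samples), `excluded`
#'   (samples with nc == 0).
#' @export
normalized_pai <- function(reg, nc) {
  rv <- if (is.list(reg)) reg$values else reg
  nv <- if (is.list(nc)) nc$values else nc
  if (!identical(names(rv), names(nv)))
    stop("regulator and ncP20S values cover different samples")
  bad <- names(nv)[nv == 0]
  keep <- nv > 0
  list(values = rv[keep] / nv[keep], excluded = bad)
}

#' Relative normalized PAIs between conditions with Student t-tests
#'
#' Per condition, the mean of the per-sample normalized PAIs is divided by
#' the reference condition's mean, so the reference is exactly 1. Each
#' non-reference condition is compared to the reference with a two-sided
#' two-sample Student t-test (equal-variance by default; set
#' `var_equal = FALSE` for the Welch variant). Conditions with fewer than
#' two replicates get a ratio but an NA p-value. Significance tiers at
#' 0.05 / 0.01 / 0.001 are annotated; no multiple-testing correction is
#' applied by default (set `adjust = "BH"` for Benjamini-Hochberg).
#'
#' @param groups named list: condition -> numeric vector of per-sample
#'   normalized PAIs.
#' @param reference_condition name of the reference condition (>= 2
#'   replicates required).
#' @param var_equal use the equal-variance Student statistic (default TRUE).
#' @param adjust p-value adjustment method (default "none").
#' @return data.frame: `condition`, `relative_value`, `n`, `p_value`,
#'   `p_adj`, `stars` ("", "*", "**", "***").
#' @export
relative_normalized_pai <- function(groups, reference_condition,
                                    var_equal = TRUE, adjust = "none") {
  if (!reference_condition %in% names(groups))
    stop("reference condition '", reference_condition, "' not in groups")
  ref <- groups[[reference_condition]]
  if (length(ref) < 2L) stop("reference condition needs >= 2 replicates")
  ref_mean <- mean(ref)
  if (ref_mean == 0) stop("reference condition has zero mean")
  rows <- lapply(names(groups), function(cond) {
    v <- groups[[cond]]
    p <- if (cond == reference_condition) {
      NA_real_
    } else if (length(v) < 2L) {
      NA_real_
    } else {
      stats::t.test(v, ref, var.equal = var_equal)$p.value
    }
    data.frame(condition = cond,
               relative_value = if (cond == reference_condition) 1 else
                 mean(v) / ref_mean,
               n = length(v), p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = adjust)
  out$stars <- cut(out$p_adj, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", ""))
  out$stars <- as.character(out$stars)
  out$stars[is.na(out$p_adj)] <- ""
  out
}

#' End-to-end differential regulator analysis
#'
#' From a raw peptide table and sample metadata: quantify (calibration +
#' TOP3 PAIs), compute each regulator's mean-member PAI, normalize by
#' ncP20S, group by condition and report relative normalized PAIs with
#' t-tests against the reference condition.
#'
#' @param table peptide quantification table.
#' @param metadata data.frame with `sample_id` and `condition`.
#' @param reference_condition condition whose relative value is set to 1.
#' @param regulators names of regulator complexes (default the five
#'   regulators of the shipped catalog).
#' @param defs,catalog catalog objects (default: shipped).
#' @param ... passed to [relative_normalized_pai()].
#' @return data.frame with one row per regulator x condition.
#' @export
differential_association <- function(table, metadata, reference_condition,
                                     regulators = NULL, defs = NULL,
                                     catalog = NULL, ...) {
  if (is.null(defs) || is.null(catalog)) {
    cat6 <- default_catalog()
    defs <- defs %||% cat6$complexes
    catalog <- catalog %||% cat6$catalog
  }
  if (is.null(regulators))
    regulators <- intersect(c("19S", paste0("PA28", .alpha, .beta),
                              paste0("PA28", .gamma), "PA200", "PI31"),
                            names(defs))
  pai <- quantify(table)
  nc <- regulator_pai(pai, defs[["ncP20S"]], catalog)
  cond <- stats::setNames(metadata$condition, metadata$sample_id)
  res <- lapply(regulators, function(rg) {
    np <- normalized_pai(regulator_pai(pai, defs[[rg]], catalog), nc)
    groups <- split(unname(np$values), cond[names(np$values)])
    out <- relative_normalized_pai(groups, reference_condition, ...)
    out$regulator <- rg
    out
  })
  out <- do.call(rbind, res)
  out[, c("regulator", setdiff(names(out), "regulator"))]
}
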