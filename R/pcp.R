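# Sedimentation profiles and chi-squared profile distances ----------------

#' Build normalized sedimentation profiles from a per-fraction PAI matrix
#'
#' Columns of the matrix are the ordered fractions of one gradient
#' replicate. Missing PAIs are set to 0 (absence of signal across a
#' gradient, not missing-at-random) and each protein's profile is divided by
#' its total so profiles sum to 1. Proteins with an all-zero profile are
#' excluded and reported.
#'
#' @param pai a `pai_matrix` whose samples are the ordered fractions of one
#'   replicate, or a plain numeric matrix (proteins x fractions).
#' @return List with `profiles` (matrix, rows sum to 1) and `dropped`
#'   (character vector of all-zero proteins).
#' @export
build_profiles <- function(pai) {
  mat <- if (inherits(pai, "pai_matrix")) pai$values else as.matrix(pai)
  if (ncol(mat) < 2L) stop("need at least 2 fractions")
  mat[is.na(mat)] <- 0
  tot <- rowSums(mat)
  dropped <- rownames(mat)[tot == 0]
  keep <- tot > 0
  list(profiles = mat[keep, , drop = FALSE] / tot[keep], dropped = dropped)
}

#' Reference profile of a complex
#'
#' Per fraction, the median (or mean, or the single member's value, per the
#' complex definition) of the member profiles, re-normalized to sum 1.
#' Members are matched by accession against the profile rows via the
#' catalog; only detected members are used (the intersection rule), and an
#' error is raised when none is detected.
#'
#' @param def a `complex_definition`.
#' @param profiles normalized profile matrix from [build_profiles()].
#' @param catalog a `subunit_catalog` mapping member names to accessions.
#' @return A list with `profile` (numeric vector summing to 1) and
#'   `members_used` (accessions found among the profiles).
#' @export
reference_profile <- function(def, profiles, catalog) {
  stopifnot(inherits(def, "complex_definition"))
  accs <- subunit_accessions(def$members, catalog)
  used <- intersect(accs, rownames(profiles))
  if (length(used) == 0L)
    stop("no member of reference '", def$name, "' detected among profiles")
  sub <- profiles[used, , drop = FALSE]
  agg <- switch(def$aggregation,
                median = apply(sub, 2L, stats::median),
                mean = colMeans(sub),
                single = sub[1L, ])
  if (sum(agg) == 0) stop("reference '", def$name, "' aggregates to zero")
  list(profile = agg / sum(agg), members_used = used)
}

#' Chi-squared distance between a profile and a reference profile
#'
#' \deqn{\chi^2 = \sum_i (x_i - p_i)^2 / \max(p_i, \epsilon)}
#' over fractions \eqn{i}, with \eqn{x} the protein's sum-normalized profile
#' and \eqn{p} the (sum-normalized) reference profile. The reference sits in
#' the denominator, so the distance is asymmetric; the epsilon floor keeps
#' fractions where the reference is empty from dividing by zero while still
#' penalizing mass placed there.
#'
#' @param x numeric profile (sums to 1).
#' @param p reference profile on the same fraction grid (sums to 1).
#' @param epsilon denominator floor (default 1e-4 of unit mass).
#' @return Non-negative scalar; 0 iff `x == p` on the grid.
#' @examples
#' chi2(c(0.5, 0.5, 0, 0), rep(0.25, 4))  # 1
#' @export
chi2 <- function(x, p, epsilon = 1e-4) {
  if (length(x) != length(p)) stop("profiles are on different fraction grids")
  sum((x - p)^2 / pmax(p, epsilon))
}

chi2_to_reference <- function(profiles, ref, epsilon = 1e-4) {
  d <- sweep(profiles, 2L, ref, `-`)
  as.numeric(d^2 %*% (1 / pmax(ref, epsilon)))
}

#' Screen a gradient for proteins co-sedimenting with a reference complex
#'
#' For every protein profiled in all replicates, the chi-squared distance to
#' the reference profile is computed per replicate (the reference is rebuilt
#' within each replicate from its detected members); proteins are ranked by
#' the mean distance across replicates, ascending. The per-replicate columns
#' support the replicate-1 vs replicate-2 concordance scatter.
#'
#' @param pai_list list of `pai_matrix` objects (or matrices), one per
#'   gradient replicate, columns ordered by fraction.
#' @param reference name of the reference complex (must be in `defs`).
#' @param defs named list of `complex_definition` (default: the shipped
#'   eight references).
#' @param catalog a `subunit_catalog` (default: shipped catalog).
#' @param epsilon denominator floor passed to [chi2()].
#' @return data.frame: `protein`, one `chi2_rep<k>` column per replicate,
#'   `mean_chi2`, `rank` (1 = closest). Attribute `"reference_members"`
#'   lists the member accessions used per replicate.
#' @export
pcp_screen <- function(pai_list, reference, defs = NULL, catalog = NULL,
                       epsilon = 1e-4) {
  if (length(pai_list) < 2L) stop("need at least 2 replicates")
  if (is.null(defs) || is.null(catalog)) {
    cat6 <- default_catalog()
    defs <- defs %||% cat6$complexes
    catalog <- catalog %||% cat6$catalog
  }
  def <- defs[[reference]]
  if (is.null(def)) stop("unknown reference complex: ", reference)

  prof_list <- lapply(pai_list, build_profiles)
  shared <- Reduce(intersect, lapply(prof_list, function(p) rownames(p$profiles)))
  if (length(shared) == 0L) stop("no protein profiled in all replicates")
  members_used <- list()
  chi2_mat <- vapply(seq_along(prof_list), function(k) {
    pr <- prof_list[[k]]$profiles[shared, , drop = FALSE]
    ref <- reference_profile(def, prof_list[[k]]$profiles, catalog)
    members_used[[k]] <<- ref$members_used
    chi2_to_reference(pr, ref$profile, epsilon)
  }, numeric(length(shared)))
  colnames(chi2_mat) <- paste0("chi2_rep", seq_along(prof_list))
  out <- data.frame(protein = shared, chi2_mat,
                    mean_chi2 = rowMeans(chi2_mat),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mean_chi2, out$protein), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "reference_members") <- members_used
  out
}
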