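# Supervised and unsupervised clustering of abundance patterns ------------

#' Max-normalize a PAI matrix
#'
#' Each protein's row is divided by its maximum observed PAI, so the highest
#' value per protein becomes exactly 1. Missing values stay missing (they
#' are imputed 0 only on entry to clustering / PCA, where this is reported);
#' all-missing rows are excluded and reported.
#'
#' @param pai a `pai_matrix` or numeric matrix (proteins x samples).
#' @return List with `values` (normalized matrix) and `dropped` (all-missing
#'   proteins).
#' @export
max_normalize <- function(pai) {
  mat <- if (inherits(pai, "pai_matrix")) pai$values else as.matrix(pai)
  mx <- apply(mat, 1L, function(v) if (all(is.na(v))) NA_real_ else
    max(v, na.rm = TRUE))
  dropped <- rownames(mat)[is.na(mx) | mx == 0]
  keep <- !(is.na(mx) | mx == 0)
  list(values = mat[keep, , drop = FALSE] / mx[keep], dropped = dropped)
}

#' Supervised clustering of an R2 matrix
#'
#' Rows (proteins) are hierarchically clustered on their reference-R2
#' vectors; the column (reference) order is kept fixed. The distance metric
#' and linkage are configurable (the analysis default is Euclidean distance
#' with average linkage); rows containing undefined cells must be excluded
#' upstream.
#'
#' @param r2_matrix numeric matrix (proteins x references), no NA.
#' @param method linkage passed to [stats::hclust()] (default "average").
#' @param metric distance passed to [stats::dist()] (default "euclidean").
#' @return List with `hclust`, `order` (row labels in dendrogram order) and
#'   `matrix` (input reordered for heat-map export).
#' @export
supervised_cluster <- function(r2_matrix, method = "average",
                               metric = "euclidean") {
  if (nrow(r2_matrix) < 2L) stop("need at least 2 rows to cluster")
  if (anyNA(r2_matrix)) stop("undefined cells must be excluded upstream")
  hc <- stats::hclust(stats::dist(r2_matrix, method = metric),
                      method = method)
  list(hclust = hc, order = rownames(r2_matrix)[hc$order],
       matrix = r2_matrix[hc$order, , drop = FALSE])
}

#' Cut a clustering into k groups
#'
#' Thin wrapper over [stats::cutree()] returning named memberships.
#'
#' @param clustering result of [supervised_cluster()] or [ahc_upgma()].
#' @param k number of groups.
#' @return Named integer vector of cluster memberships.
#' @export
cut_clusters <- function(clustering, k) {
  stats::cutree(clustering$hclust, k = k)
}

#' Principal component analysis of Pearson (n) type
#'
#' PCA on the Pearson correlation matrix of the variables: each variable
#' (sample) is standardized with the population (n-denominator) standard
#' deviation before projection, which is the "Pearson (n)" convention of
#' common statistics suites. Missing values are imputed 0 on entry;
#' zero-variance variables are dropped and reported. Component signs are
#' fixed by forcing each component's largest-magnitude loading positive.
#'
#' @param norm a max-normalized matrix (from [max_normalize()]) or any
#'   numeric matrix; rows are observations (proteins), columns variables
#'   (samples).
#' @return List with `scores` (observations x components), `loadings`
#'   (variables x components), `explained` (variance fractions summing to
#'   1), `dropped` (zero-variance variables).
#' @export
pca_pearson <- function(norm) {
  mat <- if (is.list(norm) && !is.null(norm$values)) norm$values else
    as.matrix(norm)
  if (nrow(mat) < 3L || ncol(mat) < 3L)
    stop("need at least 3 observations and 3 variables")
  mat[is.na(mat)] <- 0
  n <- nrow(mat)
  mu <- colMeans(mat)
  sd_pop <- sqrt(colMeans(mat^2) - mu^2)
  dropped <- colnames(mat)[sd_pop <= .Machine$double.eps^0.5]
  keep <- sd_pop > .Machine$double.eps^0.5
  if (sum(keep) < 2L) stop("fewer than 2 variables with nonzero variance")
  Z <- sweep(sweep(mat[, keep, drop = FALSE], 2L, mu[keep], `-`),
             2L, sd_pop[keep], `/`)
  C <- crossprod(Z) / n                      # Pearson correlation matrix
  eg <- eigen(C, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  loadings <- eg$vectors
  flip <- apply(loadings, 2L, function(v) sign(v[which.max(abs(v))]))
  loadings <- sweep(loadings, 2L, flip, `*`)
  scores <- Z %*% loadings
  dimnames(loadings) <- list(colnames(mat)[keep],
                             paste0("PC", seq_len(ncol(loadings))))
  dimnames(scores) <- list(rownames(mat), colnames(loadings))
  list(scores = scores, loadings = loadings,
       explained = vals / sum(vals), dropped = dropped)
}

#' Agglomerative hierarchical clustering (UPGMA, 1 - Pearson r)
#'
#' Proteins (rows) are the clustered observations, samples the variables.
#' Pairwise dissimilarity is d = 1 - r (Pearson across samples, missing
#' imputed 0); pairs where r is undefined (zero variance) get the maximum
#' dissimilarity 2 and are reported. Agglomeration is the unweighted
#' pair-group average method (UPGMA), whose merge heights equal the average
#' pairwise dissimilarity between the merged groups and are non-decreasing.
#'
#' @param norm matrix or [max_normalize()] result; rows proteins, columns
#'   samples.
#' @return Object of class `upgma_dendrogram`: list with `hclust`, `merges`
#'   (data.frame node1, node2, height), `leaves` (row labels),
#'   `undefined_pairs` (count of zero-variance pairs set to d = 2).
#' @export
ahc_upgma <- function(norm) {
  mat <- if (is.list(norm) && !is.null(norm$values)) norm$values else
    as.matrix(norm)
  if (nrow(mat) < 2L) stop("need at least 2 proteins")
  mat[is.na(mat)] <- 0
  sds <- apply(mat, 1L, stats::sd)
  r <- suppressWarnings(stats::cor(t(mat)))
  d <- 1 - r
  undef <- outer(sds == 0, sds == 0, `|`)
  diag(undef) <- FALSE
  d[undef] <- 2
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  structure(list(hclust = hc,
                 merges = data.frame(node1 = hc$merge[, 1],
                                     node2 = hc$merge[, 2],
                                     height = hc$height),
                 leaves = rownames(mat),
                 undefined_pairs = sum(undef[upper.tri(undef)])),
            class = "upgma_dendrogram")
}

#' @export
print.upgma_dendrogram <- function(x, ...) {
  cat(sprintf("UPGMA dendrogram: %d leaves, height range [%.3g, %.3g]\n",
              length(x$leaves), min(x$merges$height), max(x$merges$height)))
  invisible(x)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths follow the ultrametric merge heights (each child edge is
#' the height difference between parent and child node).
#'
#' @param dend an `ahc_upgma()` result or an object with an `hclust` field.
#' @return Newick string (terminated by ";").
#' @export
as_newick <- function(dend) {
  hc <- if (inherits(dend, "hclust")) dend else dend$hclust
  labs <- hc$labels
  node_str <- character(nrow(hc$merge))
  node_h <- hc$height
  render <- function(id, parent_h) {
    if (id < 0) paste0(labs[-id], ":", format(parent_h, digits = 10))
    else paste0(node_str[id], ":", format(parent_h - node_h[id], digits = 10))
  }
  for (i in seq_len(nrow(hc$merge))) {
    a <- render(hc$merge[i, 1], hc$height[i])
    b <- render(hc$merge[i, 2], hc$height[i])
    node_str[i] <- paste0("(", a, ",", b, ")")
  }
  paste0(node_str[nrow(hc$merge)], ";")
}
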