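# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Pearson correlation from the raw definition sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - sum(x) * sum(y) / n
  den <- sqrt((sum(x^2) - sum(x)^2 / n) * (sum(y^2) - sum(y)^2 / n))
  num / den
}

# chi-squared profile distance by direct summation
oracle_chi2 <- function(x, p, epsilon = 1e-4) {
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - p[i])^2 / max(p[i], epsilon)
  s
}

# TOP3 PAI by explicit rank / slice / mean on a plain data.frame
# (sums with missing = 0, ties broken lexicographically, mean over observed)
oracle_pai <- function(df) {
  df <- df[!df$is_standard, ]
  samples <- sort(unique(df$sample_id))
  out <- list()
  for (prot in sort(unique(df$protein))) {
    sub <- df[df$protein == prot, ]
    sums <- tapply(sub$xic_area, sub$peptide_id, sum)
    ord <- order(-sums, names(sums))
    refs <- names(sums)[ord][seq_len(min(3, length(sums)))]
    vals <- sapply(samples, function(s) {
      obs <- sub$xic_area[sub$sample_id == s & sub$peptide_id %in% refs]
      if (length(obs) == 0) NA_real_ else mean(obs)
    })
    out[[prot]] <- vals
  }
  mat <- do.call(rbind, out)
  colnames(mat) <- samples
  mat
}

# Naive O(n^3) UPGMA on a dissimilarity matrix: at each step merge the two
# clusters with the smallest average pairwise dissimilarity (ties: smallest
# leaf index first). Returns the merge history as member sets + heights.
oracle_upgma <- function(D) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  merges <- list()
  avg_d <- function(a, b) mean(D[a, b])
  while (length(clusters) > 1) {
    best <- NULL
    best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d <- avg_d(clusters[[i]], clusters[[j]])
      key <- c(min(clusters[[i]]), min(clusters[[j]]))
      if (d < best_d - 1e-12 ||
          (abs(d - best_d) <= 1e-12 && !is.null(best) &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best_d <- d
        best <- list(i = i, j = j, key = sort(key))
      }
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    merges[[length(merges) + 1]] <- list(members = merged, height = best_d)
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  merges
}

# member sets of every internal node of an hclust tree, in merge order
hclust_member_sets <- function(hc) {
  n <- length(hc$order)
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    grab <- function(id) if (id < 0) -id else sets[[id]]
    sets[[i]] <- sort(c(grab(hc$merge[i, 1]), grab(hc$merge[i, 2])))
  }
  sets
}

# do cluster memberships match a planted partition (up to label permutation)?
same_partition <- function(membership, planted) {
  length(unique(membership)) == length(unique(planted)) &&
    all(tapply(planted, membership, function(v) length(unique(v))) == 1)
}

# small random peptide table for oracle-equivalence tests
random_peptide_table <- function(n_prot = 4, n_pep = 5, n_samp = 4,
                                 missing = 0.2) {
  prot <- sprintf("P%02d", seq_len(n_prot))
  grid <- expand.grid(protein = prot,
                      peptide_id = sprintf("pep%02d", seq_len(n_pep)),
                      sample_id = sprintf("s%02d", seq_len(n_samp)),
                      stringsAsFactors = FALSE)
  grid$peptide_id <- paste(grid$protein, grid$peptide_id, sep = "_")
  grid <- grid[runif(nrow(grid)) > missing, ]
  grid$xic_area <- rlnorm(nrow(grid), meanlog = 5)
  grid$is_standard <- FALSE
  grid$sn_ratio <- grid$xic_area / 100
  grid
}
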