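#!/usr/bin/env Rscript
# Supervised and unsupervised clustering of the AP-MS abundance patterns:
# hierarchical clustering of each complex protein's R2 vector against the
# eight references (heat-map row order), Pearson(n) PCA and UPGMA (1 - r)
# clustering of max-normalized PAIs. Reports whether the immuno, standard
# and core/19S groups emerge as the three top-level clusters.

suppressPackageStartupMessages(library(proteoPCP))
out <- "results/clustering"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cat6 <- default_catalog()

pai <- read_pai_matrix("results/apms_correlation/pai.tsv")
r2 <- as.matrix(utils::read.delim("results/apms_correlation/r2_matrix.tsv",
                                  row.names = 1, check.names = FALSE,
                                  encoding = "UTF-8"))

groups <- list(
  immuno = subunit_accessions(c("β1i", "β2i", "β5i", "PA28α", "PA28β"),
                              cat6$catalog),
  standard = subunit_accessions(c("β1", "β2", "β5", "PI31", "PA200"),
                                cat6$catalog),
  core_19S = subunit_accessions(
    c(paste0("α", 1:7), paste0("β", c(3, 4, 6, 7)),
      paste0("Rpt", 1:6), paste0("Rpn", c(1:3, 5:14))), cat6$catalog))
members <- unlist(groups)
planted <- rep(names(groups), lengths(groups))

sup <- supervised_cluster(r2[members, ])
write_tsv(data.frame(protein = sup$order,
                     cluster3 = cut_clusters(sup, 3)[sup$order]),
          file.path(out, "supervised_row_order.tsv"))

norm <- max_normalize(pai)
pca <- pca_pearson(norm$values[members, ])
write_tsv(data.frame(protein = members, pca$scores[, 1:3],
                     group = planted, check.names = FALSE),
          file.path(out, "pca_scores.tsv"))
cat(sprintf("PCA: first two components explain %.1f%% + %.1f%% of variance\n",
            100 * pca$explained[1], 100 * pca$explained[2]))

dend <- ahc_upgma(norm$values[members, ])
writeLines(as_newick(dend), file.path(out, "upgma.nwk"))

agree <- function(membership) {
  all(tapply(planted, membership, function(v) length(unique(v))) == 1)
}
cat(sprintf("3-cluster cut matches the planted groups: supervised %s, UPGMA %s\n",
            agree(cut_clusters(sup, 3)[members]),
            agree(cut_clusters(dend, 3)[members])))
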