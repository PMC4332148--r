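#!/usr/bin/env Rscript
# Protein correlation profiling of the simulated glycerol gradient: calibrate
# and quantify each replicate, build sum-normalized sedimentation profiles,
# and rank every protein by its mean chi-squared distance to the 19S, total
# 20S and PA28 alpha/beta reference profiles. The PA28 alpha/beta screen is
# the one that singles out the immunoproteasome proxy beta2i.

suppressPackageStartupMessages(library(proteoPCP))
out <- "results/gradient_pcp"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cat6 <- default_catalog()

tab <- read_peptide_table("results/datasets/gradient/peptides.tsv")
md <- utils::read.delim("results/datasets/gradient/metadata.tsv",
                        encoding = "UTF-8")

pai_list <- lapply(split(md, md$replicate), function(m) {
  m <- m[order(m$fraction), ]
  subset_samples(quantify(tab[tab$sample_id %in% m$sample_id]), m$sample_id)
})

for (ref in c("19S", "ncP20S", paste0("PA28", "α", "β"))) {
  scr <- pcp_screen(pai_list, ref, defs = cat6$complexes,
                    catalog = cat6$catalog)
  safe <- c("19S" = "19S", "ncP20S" = "ncP20S")[ref]
  if (is.na(safe)) safe <- "PA28ab"
  write_tsv(scr, file.path(out, paste0("chi2_", safe, ".tsv")))
  cat(sprintf("reference %s: %d proteins screened, top hit %s (mean chi2 %.3g)\n",
              safe, nrow(scr), scr$protein[1], scr$mean_chi2[1]))
}

scr <- utils::read.delim(file.path(out, "chi2_PA28ab.tsv"))
pa <- subunit_accessions(c("PA28α", "PA28β"), cat6$catalog)
b2i <- subunit_accessions("β2i", cat6$catalog)
non_pa <- scr[!scr$protein %in% pa, ]
cat(sprintf(
  "beta2i mean chi2 vs PA28ab reference: %.3g (rank %d among %d non-PA28 proteins)\n",
  scr$mean_chi2[scr$protein == b2i],
  which(non_pa$protein[order(non_pa$mean_chi2)] == b2i), nrow(non_pa)))
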