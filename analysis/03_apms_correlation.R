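#!/usr/bin/env Rscript
# Cross-purification correlation analysis of the 24-sample AP-MS series:
# internal-standard calibration, TOP3 PAIs, the eight reference sub-complex
# abundances, the R/R2 matrix of every protein against every reference, and
# the confidence filter (r > 0.8 vs a 20S subtype, >= 2 peptides, median
# S/N > 10) for putative complex-interacting proteins.

suppressPackageStartupMessages(library(proteoPCP))
out <- "results/apms_correlation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cat6 <- default_catalog()

tab <- read_peptide_table("results/datasets/apms/peptides.tsv")
pai <- quantify(tab)
write_pai_matrix(pai, file.path(out, "pai.tsv"))

refs <- build_reference_abundances(pai, cat6$complexes, cat6$catalog)
cm <- correlation_matrix(pai, refs)
write_tsv(data.frame(protein = rownames(cm$r2), cm$r2, check.names = FALSE),
          file.path(out, "r2_matrix.tsv"))
write_tsv(data.frame(protein = rownames(cm$r), cm$r, check.names = FALSE),
          file.path(out, "r_matrix.tsv"))

a6 <- subunit_accessions("α6", cat6$catalog)
a7 <- subunit_accessions("α7", cat6$catalog)
cat(sprintf("R2(alpha6, alpha7) across %d purifications: %.3f\n",
            ncol(pai$values),
            correlate(pai$values[a6, ], pai$values[a7, ])$r2))
rr <- stats::cor(t(refs$values))
cat(sprintf("R2 of reference pairs: iP20S~PA28ab %.3f | sP20S~PA28ab %.4f | ncP20S~19S %.3f | sP20S~PI31 %.3f\n",
            rr["iP20S", "PA28αβ"]^2, rr["sP20S", "PA28αβ"]^2,
            rr["ncP20S", "19S"]^2, rr["sP20S", "PI31"]^2))

pips <- filter_pips(pai, cm$r)
write_tsv(pips, file.path(out, "confident_pips.tsv"))
cat(sprintf("confidence filter keeps %d of %d quantified proteins\n",
            nrow(pips), nrow(pai$values)))
print(table(pips$best_reference))
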