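#!/usr/bin/env Rscript
# Generate the three study-condition datasets from their ground-truth models:
# the 24-sample AP-MS purification series across nine cell lines, the
# 19-fraction glycerol-gradient PCP experiment (two replicates), and the
# interferon-gamma induction time course (4 time points x 3 replicates).
# Every downstream script starts from the plain-text tables written here.

suppressPackageStartupMessages(library(proteoPCP))
seed <- 1L
out <- "results/datasets"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

apms <- simulate_apms(default_apms_model(seed = seed))
write_sim_dataset(apms, file.path(out, "apms"))
cat(sprintf("AP-MS series: %d samples from %d cell lines, %d peptide rows\n",
            nrow(apms$metadata), length(unique(apms$metadata$cell_line)),
            nrow(apms$peptide_table)))

grad <- simulate_gradient(default_gradient_model(seed = seed + 7L),
                          replicates = 2)
write_sim_dataset(grad, file.path(out, "gradient"))
cat(sprintf("Gradient PCP: %d fractions x %d replicates, %d peptide rows\n",
            max(grad$metadata$fraction), max(grad$metadata$replicate),
            nrow(grad$peptide_table)))

tc <- simulate_ifng_timecourse(ifng_model(seed = seed + 29L),
                               timepoints = names(ifng_schedule()$iP20S),
                               fold_schedule = ifng_schedule())
write_sim_dataset(tc, file.path(out, "timecourse"))
cat(sprintf("IFN-gamma time course: %d samples over %d time points\n",
            nrow(tc$metadata), length(unique(tc$metadata$condition))))
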