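noise_free <- function(model_fun, ...) {
  model_fun(..., noise_cv = 0,
            peptide_model = list(noise_cv = 0, missing_rate = 0),
            loading_cv = 0, run_drift_sigma = 0)
}

test_that("model validation enforces its invariants", {
  cl <- data.frame(name = "x", f_sP20S = 0.6, f_iP20S = 0.5, total_20S = 1)
  ap <- matrix(0.5, 1, 2, dimnames = list("PI31", c("sP20S", "iP20S")))
  expect_error(ground_truth_model(cl, ap), "sum to 1")
  cl$f_iP20S <- 0.4
  expect_error(ground_truth_model(cl, ap, capture_yield = 0), "capture_yield")
  ap2 <- ap; ap2[1] <- 1.5
  expect_error(ground_truth_model(cl, ap2), "\\[0, 1\\]")
  expect_s3_class(ground_truth_model(cl, ap), "ground_truth_model")
})

test_that("fixed seed gives byte-identical output; new seed same schema", {
  a <- simulate_apms(default_apms_model(seed = 42))
  b <- simulate_apms(default_apms_model(seed = 42))
  expect_identical(a$peptide_table, b$peptide_table)
  expect_identical(a$truth$run_scale, b$truth$run_scale)
  c <- simulate_apms(default_apms_model(seed = 43))
  expect_false(identical(a$peptide_table$xic_area, c$peptide_table$xic_area))
  expect_identical(names(a$peptide_table), names(c$peptide_table))
})

test_that("default study designs emit the right sample counts", {
  sim <- simulate_apms(default_apms_model(seed = 1))
  expect_equal(nrow(sim$metadata), 24)
  expect_equal(length(unique(sim$metadata$cell_line)), 9)
  reps <- table(sim$metadata$cell_line)
  expect_true(all(reps %in% 2:3))

  tc <- simulate_ifng_timecourse(ifng_model(seed = 1),
                                 timepoints = names(ifng_schedule()$iP20S),
                                 fold_schedule = ifng_schedule())
  expect_equal(nrow(tc$metadata), 12)
})

test_that("degenerate noise-free capture reproduces the generative formula", {
  # one line, one subtype, yield 1: every 20S subunit equals total_20S
  cl <- data.frame(name = "x", f_sP20S = 1, f_iP20S = 0, total_20S = 2.5)
  ap <- matrix(c(0, 1), 1, 2,
               dimnames = list("PA28αβ", c("sP20S", "iP20S")))
  m <- ground_truth_model(cl, ap, capture_yield = 1,
                          peptide_model = list(noise_cv = 0, missing_rate = 0),
                          background = list(n_contaminants = 0),
                          loading_cv = 0, run_drift_sigma = 0, seed = 9)
  sim <- simulate_apms(m, replicates_per_line = 1)
  tm <- sim$truth$protein_truth
  cat6 <- default_catalog()
  core <- subunit_accessions(c(paste0("α", 1:7), paste0("β", c(3, 4, 6, 7)),
                               paste0("β", c(1, 2, 5))), cat6$catalog)
  expect_true(all(abs(tm[core, 1] - 2.5) < 1e-12))
  # propensity 1 on the absent subtype: regulator absent
  pa28 <- subunit_accessions(c("PA28α", "PA28β"), cat6$catalog)
  expect_true(all(tm[pa28, 1] == 0))
})

test_that("regulator abundance is proportional to its subtype (noise-free)", {
  cl <- data.frame(name = c("a", "b", "c"),
                   f_sP20S = c(0.9, 0.6, 0.4), f_iP20S = c(0.1, 0.4, 0.6),
                   total_20S = c(1, 2, 0.5))
  ap <- matrix(c(0, 1), 1, 2,
               dimnames = list("PA28αβ", c("sP20S", "iP20S")))
  m <- ground_truth_model(cl, ap,
                          peptide_model = list(noise_cv = 0, missing_rate = 0),
                          background = list(n_contaminants = 0),
                          loading_cv = 0, run_drift_sigma = 0, seed = 4)
  sim <- simulate_apms(m, replicates_per_line = 2)
  cat6 <- default_catalog()
  pa <- subunit_accessions("PA28α", cat6$catalog)
  ip <- sim$truth$subtype_abundance["iP20S", ]
  ratio <- sim$truth$protein_truth[pa, ] / ip
  expect_true(diff(range(ratio)) < 1e-12)
})

test_that("noise-free peptide sums are proportional to true abundance with a
           shared constant across samples", {
  m <- noise_free(default_apms_model, seed = 7)
  sim <- simulate_apms(m, replicates_per_line = 2)
  tab <- sim$peptide_table[!sim$peptide_table$is_standard]
  sums <- tapply(tab$xic_area, list(tab$protein, tab$sample_id), sum)
  truth <- sim$truth$protein_truth[rownames(sums), colnames(sums)]
  const <- sums / truth
  # same constant across samples for each protein
  spread <- apply(const, 1L, function(v) diff(range(v)) / max(v))
  expect_true(all(spread < 1e-9))
})

test_that("standards carry only per-run drift", {
  sim <- simulate_apms(default_apms_model(seed = 3), replicates_per_line = 2)
  std <- sim$peptide_table[sim$peptide_table$is_standard]
  corrected <- std$xic_area / sim$truth$run_scale[std$sample_id]
  cv <- tapply(corrected, std$peptide_id,
               function(v) sd(v) / mean(v))
  expect_true(all(cv < 1e-12))
})

test_that("gradient: single-species protein peaks at the declared center", {
  m <- noise_free(default_gradient_model, seed = 2)
  sim <- simulate_gradient(m, replicates = 1)
  cat6 <- default_catalog()
  b2i <- subunit_accessions("β2i", cat6$catalog)
  prof <- sim$truth$protein_truth[b2i, order(sim$metadata$fraction)]
  expect_equal(unname(which.max(prof)), 12L)  # iP20S-PA28ab species center
})

test_that("gradient replicates are identical up to the per-run scale", {
  m <- noise_free(default_gradient_model, seed = 6)
  sim <- simulate_gradient(m, replicates = 2)
  tab <- as.data.frame(sim$peptide_table[!sim$peptide_table$is_standard])
  tab$corrected <- tab$xic_area / sim$truth$run_scale[tab$sample_id]
  md <- sim$metadata
  tab$fraction <- md$fraction[match(tab$sample_id, md$sample_id)]
  tab$replicate <- md$replicate[match(tab$sample_id, md$sample_id)]
  wide <- reshape(tab[, c("protein", "peptide_id", "fraction", "replicate",
                          "corrected")],
                  idvar = c("protein", "peptide_id", "fraction"),
                  timevar = "replicate", direction = "wide")
  ok <- stats::complete.cases(wide)
  expect_gt(sum(ok), 0)
  expect_equal(wide$corrected.1[ok], wide$corrected.2[ok], tolerance = 1e-12)
})

test_that("planted co-complex gives beta2i the PA28 profile (noise-free)", {
  m <- noise_free(default_gradient_model, seed = 8)
  sim <- simulate_gradient(m, replicates = 1)
  cat6 <- default_catalog()
  accs <- subunit_accessions(c("β2i", "PA28α"), cat6$catalog)
  tm <- sim$truth$protein_truth[accs, ]
  p1 <- tm[1, ] / sum(tm[1, ])
  p2 <- tm[2, ] / sum(tm[2, ])
  expect_equal(unname(p1), unname(p2), tolerance = 1e-12)
})

test_that("time-course fold schedule is honored exactly (noise-free)", {
  m <- noise_free(ifng_model, seed = 5)
  sched <- list(iP20S = c(`0h` = 1, `72h` = 8), sP20S = c(`0h` = 1, `72h` = 0.5))
  sim <- simulate_ifng_timecourse(m, c("0h", "72h"), sched, replicates = 1)
  ab <- sim$truth$subtype_abundance
  md <- sim$metadata
  s0 <- md$sample_id[md$condition == "0h"]
  s72 <- md$sample_id[md$condition == "72h"]
  expect_equal(unname(ab["iP20S", s72] / ab["iP20S", s0]), 8)
  expect_equal(unname(ab["sP20S", s72] / ab["sP20S", s0]), 0.5)
  expect_error(
    simulate_ifng_timecourse(m, c("0h", "48h"), sched, replicates = 1),
    "48h")
})
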