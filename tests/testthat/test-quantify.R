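std_rows <- function(samples, value = 100) {
  data.frame(sample_id = samples, protein = "STD", peptide_id = "std1",
             xic_area = value, is_standard = TRUE)
}

test_that("calibration: identical standards leave the table unchanged", {
  tab <- rbind(
    data.frame(sample_id = c("a", "b"), protein = "P1", peptide_id = "p1",
               xic_area = c(10, 20), is_standard = FALSE),
    std_rows(c("a", "b")))
  cal <- calibrate_runs(tab)
  expect_equal(cal$factors$factor, c(1, 1))
  expect_equal(sort(cal$table[!(is_standard)]$xic_area), c(10, 20))
})

test_that("calibration: a run at half the standard mean gets factor 2", {
  tab <- rbind(
    data.frame(sample_id = c("a", "b", "c"), protein = "P1",
               peptide_id = "p1", xic_area = c(10, 10, 10),
               is_standard = FALSE),
    data.frame(sample_id = c("a", "b", "c"), protein = "STD",
               peptide_id = "std1", xic_area = c(75, 75, 30),
               is_standard = TRUE))
  cal <- calibrate_runs(tab)
  fac <- setNames(cal$factors$factor, cal$factors$sample_id)
  expect_equal(unname(fac["c"]), 2)  # standard at half the cross-sample mean
  expect_equal(cal$table[sample_id == "c" & !(is_standard)]$xic_area, 20)
  # a sample with no standards is an error naming the sample
  bad <- tab[!(tab$sample_id == "b" & tab$is_standard), ]
  expect_error(calibrate_runs(bad), "b")
})

test_that("calibration removes planted inter-run drift", {
  sim <- simulate_apms(default_apms_model(seed = 12, noise_cv = 0),
                       replicates_per_line = 2)
  cal <- calibrate_runs(sim$peptide_table)
  std <- cal$table[(is_standard)]
  cv <- tapply(std$xic_area, std$peptide_id, function(v) sd(v) / mean(v))
  expect_true(all(cv < 1e-10))
  # recovered factors invert the planted scales (up to one global constant)
  fac <- setNames(cal$factors$factor, cal$factors$sample_id)
  prod <- fac * sim$truth$run_scale[names(fac)]
  expect_lt(diff(range(prod)) / mean(prod), 1e-10)
})

test_that("reference peptide selection: top-3 by cross-sample sum, ties
           lexicographic, short proteins keep all peptides", {
  tab <- rbind(
    data.frame(sample_id = "s1", protein = "P1",
               peptide_id = c("pA", "pB", "pC", "pD"),
               xic_area = c(10, 30, 20, 5), is_standard = FALSE),
    data.frame(sample_id = "s1", protein = "P2",
               peptide_id = c("q1", "q2"), xic_area = c(1, 2),
               is_standard = FALSE),
    # P3: exact tie between 3rd and 4th peptide
    data.frame(sample_id = "s1", protein = "P3",
               peptide_id = c("r1", "r2", "r3", "r4"),
               xic_area = c(9, 9, 5, 5), is_standard = FALSE))
  refs <- select_reference_peptides(tab)
  expect_setequal(refs$P1, c("pB", "pC", "pA"))
  expect_setequal(refs$P2, c("q1", "q2"))
  expect_true("r3" %in% refs$P3 && !"r4" %in% refs$P3)
})

test_that("PAI is the mean over observed reference peptides", {
  tab <- data.frame(
    sample_id = c(rep("s1", 3), rep("s2", 2)),
    protein = "P1",
    peptide_id = c("p1", "p2", "p3", "p1", "p2"),
    xic_area = c(100, 200, 300, 50, 150),
    is_standard = FALSE)
  pai <- compute_pai(tab)
  expect_equal(unname(pai$values["P1", "s1"]), 200)
  expect_equal(unname(pai$values["P1", "s2"]), 100)
  pai0 <- compute_pai(tab, missing_ref = "zero")
  expect_equal(unname(pai0$values["P1", "s2"]), 200 / 3)
})

test_that("PAI matches the brute-force oracle on random tables", {
  set.seed(71)
  for (i in 1:50) {
    df <- random_peptide_table(n_prot = sample(2:5, 1),
                               n_pep = sample(1:6, 1),
                               n_samp = sample(3:6, 1))
    if (nrow(df) == 0) next
    got <- compute_pai(df)$values
    want <- oracle_pai(df)
    want <- want[rownames(got), colnames(got), drop = FALSE]
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("calibration absorbs a global per-sample rescaling", {
  set.seed(5)
  df <- random_peptide_table(n_prot = 4, n_pep = 4, n_samp = 4, missing = 0)
  df$sn_ratio <- NULL
  df <- rbind(df, std_rows(unique(df$sample_id)))
  base <- quantify(df)$values
  k <- c(s01 = 3, s02 = 0.5, s03 = 1, s04 = 10)
  df2 <- df
  df2$xic_area <- df2$xic_area * k[df2$sample_id]
  scaled <- quantify(df2)$values
  # per-sample scale factors are absorbed up to one global constant (the
  # calibration reference is the cross-sample mean), so all PAI ratios are
  # restored exactly
  ratio <- scaled / base
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-10)
  expect_equal(scaled / mean(ratio), base, tolerance = 1e-10)
})

test_that("PAI is monotone in any reference peptide intensity", {
  df <- data.frame(sample_id = "s1", protein = "P1",
                   peptide_id = c("p1", "p2", "p3"),
                   xic_area = c(10, 20, 30), is_standard = FALSE)
  base <- compute_pai(df)$values["P1", "s1"]
  df$xic_area[1] <- 25
  up <- compute_pai(df)$values["P1", "s1"]
  expect_gte(up, base)
})
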