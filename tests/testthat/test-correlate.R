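toy_pai <- function(values, n_peptides = NULL, median_sn = NULL) {
  ps <- data.frame(protein = rownames(values),
                   n_peptides = n_peptides %||% rep(3L, nrow(values)),
                   median_sn = median_sn %||% rep(100, nrow(values)),
                   stringsAsFactors = FALSE)
  structure(list(values = values, peptide_support = ps, refs = NULL),
            class = "pai_matrix")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("reference abundances follow the aggregation rules", {
  cat6 <- default_catalog()
  accs <- subunit_accessions(c("PA28α", "PA28β", "β5"), cat6$catalog)
  values <- rbind(c(1, 10), c(3, 30), c(7, 70))
  rownames(values) <- accs
  colnames(values) <- c("s1", "s2")
  defs <- list(cat6$complexes[["PA28αβ"]], cat6$complexes$sP20S)
  refs <- build_reference_abundances(toy_pai(values), defs, cat6$catalog)
  expect_equal(unname(refs$values["PA28αβ", ]), c(2, 20))    # median of 2
  expect_equal(unname(refs$values["sP20S", ]), c(7, 70))     # single member
  # no member detected -> error naming the reference
  expect_error(
    build_reference_abundances(toy_pai(values), list(cat6$complexes$iP20S),
                               cat6$catalog), "iP20S")
})

test_that("correlate: proportionality, anticorrelation, oracle agreement", {
  expect_equal(correlate(c(1, 2, 3), c(2, 4, 6))$r, 1)
  rec <- correlate(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_equal(rec$r, -1)
  expect_equal(rec$r2, 1)
  rec2 <- correlate(c(1, 2, 3), c(1, 2, 4))
  expect_equal(rec2$r2, oracle_pearson(c(1, 2, 3), c(1, 2, 4))^2,
               tolerance = 1e-12)
  expect_equal(rec2$r2, rec2$r^2, tolerance = 1e-12)
  # zero variance flags the record undefined
  expect_true(correlate(c(1, 1, 1), c(1, 2, 3))$undefined)
  expect_error(correlate(c(1, 2), c(1, 2)), "3 samples")
  # missing treated as 0 in both vectors
  expect_equal(correlate(c(1, NA, 3), c(1, 0, 3))$r,
               correlate(c(1, 0, 3), c(1, 0, 3))$r)
})

test_that("r is invariant under affine transforms up to the slope sign", {
  set.seed(19)
  for (i in 1:20) {
    x <- rnorm(8)
    y <- rnorm(8)
    a <- runif(1, -3, 3)
    if (a == 0) a <- 1
    b <- rnorm(1)
    r0 <- correlate(x, y)$r
    r1 <- correlate(a * x + b, y)$r
    expect_equal(r1, sign(a) * r0, tolerance = 1e-12)
  }
})

test_that("correlation matrix has the contracted shape and diagonal", {
  cat6 <- default_catalog()
  sim <- simulate_apms(default_apms_model(seed = 2))
  pai <- quantify(sim$peptide_table)
  refs <- build_reference_abundances(pai, cat6$complexes, cat6$catalog)
  targets <- rownames(pai$values)
  cm <- correlation_matrix(pai, refs, targets)
  expect_equal(dim(cm$r2), c(length(targets), 8))
  expect_equal(cm$r2, cm$r^2, tolerance = 1e-12)
  # a single-member reference against its own member: r2 = 1
  b5 <- subunit_accessions("β5", cat6$catalog)
  expect_equal(unname(cm$r2[b5, "sP20S"]), 1, tolerance = 1e-12)
  expect_error(correlation_matrix(pai, refs, c(targets[1], "nope")), "nope")
})

test_that("contaminants correlate with no reference", {
  cat6 <- default_catalog()
  frac_low <- vapply(1:5, function(s) {
    sim <- simulate_apms(default_apms_model(seed = s))
    pai <- quantify(sim$peptide_table)
    refs <- build_reference_abundances(pai, cat6$complexes, cat6$catalog)
    cont <- grep("^CONT", rownames(pai$values), value = TRUE)
    cm <- correlation_matrix(pai, refs, cont)
    mean(cm$r2 < 0.2, na.rm = TRUE)
  }, 0)
  expect_gt(mean(frac_low), 0.95)
})

test_that("the PIP filter keeps exactly the proteins satisfying all clauses", {
  values <- matrix(rep(1, 12), 6, 2)  # values unused by the filter itself
  rownames(values) <- paste0("T", 1:6)
  colnames(values) <- c("s1", "s2")
  pai <- toy_pai(values,
                 n_peptides = c(3L, 1L, 2L, 3L, 2L, 3L),
                 median_sn = c(15, 15, 15, 5, 50, 12))
  r <- rbind(
    T1 = c(0.9, 0.1, 0.1),    # passes everything, best = ncP20S
    T2 = c(0.9, 0.9, 0.9),    # fails: 1 peptide
    T3 = c(0.1, 0.95, 0.2),   # passes, best = sP20S
    T4 = c(0.9, 0.9, 0.9),    # fails: median S/N 5
    T5 = c(-0.95, 0.2, 0.85), # passes via iP20S (anticorrelation ignored)
    T6 = c(0.5, 0.6, 0.7))    # fails: no r above 0.8
  colnames(r) <- c("ncP20S", "sP20S", "iP20S")
  kept <- filter_pips(pai, r)
  expect_setequal(kept$protein, c("T1", "T3", "T5"))
  lab <- setNames(kept$best_reference, kept$protein)
  expect_equal(unname(lab[c("T1", "T3", "T5")]),
               c("ncP20S", "sP20S", "iP20S"))
  # empty result is allowed
  none <- filter_pips(pai, r, r_threshold = 0.99)
  expect_equal(nrow(none), 0)
})

test_that("planted subtype partners never cross to the other subtype", {
  cat6 <- default_catalog()
  for (s in 1:5) {
    sim <- simulate_apms(default_apms_model(seed = 100 + s))
    pai <- quantify(sim$peptide_table)
    refs <- build_reference_abundances(pai, cat6$complexes, cat6$catalog)
    cm <- correlation_matrix(pai, refs)
    pa28 <- subunit_accessions(c("PA28α", "PA28β"), cat6$catalog)
    spart <- subunit_accessions(c("PI31", "PA200"), cat6$catalog)
    expect_true(all(cm$r[pa28, "sP20S"] < 0.5))
    expect_true(all(cm$r[spart, "iP20S"] < 0.5))
  }
})
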