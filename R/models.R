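# Default study-condition models ------------------------------------------

default_propensities <- function() {
  ap <- rbind(
    `19S` = c(sP20S = 0.50, iP20S = 0.50),
    c(sP20S = 0.05, iP20S = 0.90),   # PA28alpha/beta
    c(sP20S = 0.15, iP20S = 0.60),   # PA28gamma
    PA200 = c(sP20S = 0.70, iP20S = 0.05),
    PI31 = c(sP20S = 0.80, iP20S = 0.05))
  rownames(ap)[2] <- paste0("PA28", .alpha, .beta)
  rownames(ap)[3] <- paste0("PA28", .gamma)
  ap
}

#' Default nine-cell-line AP-MS study model
#'
#' The default model behind the 24-sample affinity-purification series: nine
#' human cell lines (three immune-lineage lines with 30-55% immunoproteasome,
#' six epithelial/fibroblast lines with 2-15%), subtype fractions and total
#' 20S amounts fixed once (see the methods vignette for the rationale), regulator
#' association propensities planted so that PA28 alpha/beta tracks the
#' immunoproteasome, PI31 and PA200 the standard proteasome, and the 19S
#' both, with peptide-level noise CV 0.2 and 87% capture yield. The default
#' replicate pattern (3,3,3,3,3,3,2,2,2) yields 24 samples.
#'
#' @param seed integer seed.
#' @param noise_cv measurement / replicate coefficient of variation.
#' @param ... further arguments passed to [ground_truth_model()]
#'   (e.g. `peptide_model`, `background`).
#' @return A `ground_truth_model` with a `default_replicates` attribute.
#' @export
default_apms_model <- function(seed = 1L, noise_cv = 0.2, ...) {
  cl <- data.frame(
    name = c("lymphoma_1", "leukemia_1", "leukemia_2", "epithelial_1",
             "epithelial_2", "epithelial_3", "epithelial_4", "osteo_1",
             "fibroblast_1"),
    f_sP20S = c(0.41, 0.55, 0.67, 0.83, 0.85, 0.89, 0.92, 0.92, 0.95),
    f_iP20S = c(0.55, 0.40, 0.30, 0.15, 0.10, 0.08, 0.06, 0.04, 0.02),
    f_b5i_P20S = c(0.04, 0.05, 0.03, 0.02, 0.05, 0.03, 0.02, 0.04, 0.03),
    f_b1ib5i_P20S = 0,
    total_20S = c(1.73, 0.94, 0.84, 0.69, 1.45, 0.98, 0.63, 1.27, 1.25),
    stringsAsFactors = FALSE)
  args <- utils::modifyList(
    list(cell_lines = cl,
         association_propensity = default_propensities(),
         peptide_model = list(noise_cv = noise_cv),
         seed = seed),
    list(...))
  m <- do.call(ground_truth_model, args)
  attr(m, "default_replicates") <- c(3L, 3L, 3L, 3L, 3L, 3L, 2L, 2L, 2L)
  m
}

#' Two-cell-line differential model (pure sP20S vs pure iP20S)
#'
#' Emulates the engineered HEK-EBNA pair: one line assembling only standard
#' proteasome, one only immunoproteasome. The planted propensity contrasts
#' are arguments so differential-recovery and null (type-I error) studies
#' use the same machinery.
#'
#' @param pa28ab propensity of PA28 alpha/beta for (sP20S, iP20S); the
#'   default plants a fourfold contrast.
#' @param pi31 propensity of PI31 for (sP20S, iP20S); default an eightfold
#'   contrast.
#' @param pa200,pa28g,s19 propensities for PA200, PA28 gamma and the 19S
#'   (equal by default: no planted difference).
#' @inheritParams default_apms_model
#' @return A `ground_truth_model` with cell lines `HEK_s` and `HEK_i`.
#' @export
hek_ebna_model <- function(pa28ab = c(0.1, 0.4), pi31 = c(0.4, 0.05),
                           pa200 = c(0.3, 0.3), pa28g = c(0.3, 0.3),
                           s19 = c(0.5, 0.5), seed = 1L, noise_cv = 0.2, ...) {
  cl <- data.frame(name = c("HEK_s", "HEK_i"),
                   f_sP20S = c(1, 0), f_iP20S = c(0, 1),
                   total_20S = c(1.0, 1.0), stringsAsFactors = FALSE)
  ap <- rbind(`19S` = s19, pa28ab, pa28g, PA200 = pa200, PI31 = pi31)
  colnames(ap) <- c("sP20S", "iP20S")
  rownames(ap)[2] <- paste0("PA28", .alpha, .beta)
  rownames(ap)[3] <- paste0("PA28", .gamma)
  args <- utils::modifyList(
    list(cell_lines = cl, association_propensity = ap,
         peptide_model = list(noise_cv = noise_cv),
         background = list(n_contaminants = 10L), seed = seed),
    list(...))
  do.call(ground_truth_model, args)
}

#' Default glycerol-gradient (PCP) model
#'
#' A U937-like lysate resolved over 19 fractions. Species (deepest first):
#' doubly capped 30S, 26S (standard and a beta1i/beta5i-intermediate core),
#' free 19S, PA200- and PA28 gamma-capped standard 20S, the
#' immunoproteasome-PA28 alpha/beta species (the planted co-sedimentation the
#' gradient screen is meant to recover), and free 20S (standard and
#' beta5i-intermediate). beta2i occurs only in the PA28 alpha/beta-capped
#' immunoproteasome; beta1i and beta5i also sediment with intermediate-core
#' species elsewhere in the gradient.
#'
#' @inheritParams default_apms_model
#' @return A `ground_truth_model` with `gradient_model$species` populated.
#' @export
default_gradient_model <- function(seed = 1L, noise_cv = 0.2, ...) {
  nc <- noncatalytic_subunits()
  ct <- subtype_catalytic()
  s19 <- paste0("Rpt", 1:6)
  s19 <- c(s19, paste0("Rpn", c(1:3, 5:14)))
  pa28ab <- paste0("PA28", c(.alpha, .beta))
  species <- list(
    list(name = "30S_std", members = c(nc, ct$sP20S, s19),
         amount = 0.30, center = 5.5, width = 1.8),
    list(name = "26S_std", members = c(nc, ct$sP20S, s19),
         amount = 0.90, center = 8, width = 1.8),
    list(name = "26S_b1ib5i", members = c(nc, ct$b1ib5i_P20S, s19),
         amount = 0.25, center = 8, width = 1.8),
    list(name = "free_19S", members = s19,
         amount = 0.30, center = 10, width = 1.8),
    list(name = "sP20S_PA200", members = c(nc, ct$sP20S, "PA200"),
         amount = 0.15, center = 11, width = 1.5),
    list(name = "iP20S_PA28ab", members = c(nc, ct$iP20S, pa28ab),
         amount = 0.50, center = 12, width = 1.5),
    list(name = "sP20S_PA28g", members = c(nc, ct$sP20S, paste0("PA28", .gamma)),
         amount = 0.20, center = 12.5, width = 1.5),
    list(name = "sP20S_PI31", members = c(nc, ct$sP20S, "PI31"),
         amount = 0.15, center = 13, width = 1.5),
    list(name = "free_20S_std", members = c(nc, ct$sP20S),
         amount = 1.00, center = 14, width = 1.6),
    list(name = "free_20S_b5i", members = c(nc, ct$b5i_P20S),
         amount = 0.35, center = 14, width = 1.6))
  cl <- data.frame(name = "U937", f_sP20S = 1, f_iP20S = 0, total_20S = 1,
                   stringsAsFactors = FALSE)
  args <- utils::modifyList(
    list(cell_lines = cl,
         association_propensity = default_propensities(),
         peptide_model = list(noise_cv = noise_cv),
         gradient_model = list(n_fractions = 19L, species = species),
         seed = seed),
    list(...))
  do.call(ground_truth_model, args)
}

#' Single-cell-line model for the interferon-gamma time course
#'
#' A HeLa-like line with low basal immunoproteasome content, for use with
#' [simulate_ifng_timecourse()] and the default induction schedule (iP20S up
#' eightfold, sP20S halved over 72 h).
#'
#' @inheritParams default_apms_model
#' @return A single-line `ground_truth_model`.
#' @export
ifng_model <- function(seed = 1L, noise_cv = 0.2, ...) {
  # basal composition chosen so the default induction schedule (immuno x8,
  # standard x0.5) leaves total 20S essentially unchanged at 72 h
  cl <- data.frame(name = "HeLa", f_sP20S = 0.935, f_iP20S = 0.04,
                   f_b5i_P20S = 0.025, f_b1ib5i_P20S = 0,
                   total_20S = 1.0, stringsAsFactors = FALSE)
  args <- utils::modifyList(
    list(cell_lines = cl,
         association_propensity = default_propensities(),
         peptide_model = list(noise_cv = noise_cv),
         background = list(n_contaminants = 10L), seed = seed),
    list(...))
  do.call(ground_truth_model, args)
}

#' The default interferon-gamma fold schedule
#'
#' Eightfold immunoproteasome induction and twofold standard-proteasome
#' decrease at 72 h, interpolated (geometrically) at 24 h and 48 h.
#'
#' @return Named list of per-timepoint multipliers for `iP20S` and `sP20S`.
#' @export
ifng_schedule <- function() {
  tp <- c("0h", "24h", "48h", "72h")
  list(iP20S = stats::setNames(8^(c(0, 1, 2, 3) / 3), tp),
       sP20S = stats::setNames(0.5^(c(0, 1, 2, 3) / 3), tp))
}
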