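# Synthetic peptide-level MS data with recorded ground truth --------------

#' Construct a ground-truth model for the simulator
#'
#' The model describes, per cell line, how total 20S core particle splits
#' into subtypes (standard sP20S, immuno iP20S and the two intermediate
#' subtypes carrying beta5i or beta1i+beta5i), how strongly each regulator
#' associates with each subtype, and how protein amounts turn into observed
#' peptide ion intensities (fixed per-peptide ionization efficiencies,
#' multiplicative lognormal measurement noise, dropout, per-run drift and
#' spiked internal-standard peptides).
#'
#' @param cell_lines data.frame with columns `name`, `f_sP20S`, `f_iP20S`,
#'   `f_b5i_P20S`, `f_b1ib5i_P20S` (subtype fractions summing to 1 per line)
#'   and `total_20S` (arbitrary units).
#' @param association_propensity numeric matrix, regulators x subtypes
#'   (columns `sP20S`, `iP20S`, `b5i_P20S`, `b1ib5i_P20S`), values in
#'   \[0, 1\]: expected bound regulator per 20S particle of that subtype.
#'   Missing intermediate columns default to the iP20S column (intermediates
#'   associate with the same regulators as the immunoproteasome).
#' @param regulator_pools named numeric vector of cellular regulator
#'   abundances (arbitrary units); recorded in the truth for expression-level
#'   contrasts, not used in the capture formula.
#' @param capture_yield fraction of assembled complexes recovered by the
#'   immunopurification, in (0, 1]. Default 0.87.
#' @param peptide_model list: `peptides_per_protein` (>= 1),
#'   `efficiency_sigma` (lognormal sigma of fixed per-peptide ionization
#'   factors), `noise_cv` (multiplicative CV of each measurement and of the
#'   per-replicate biological perturbation), `missing_rate` (dropout
#'   probability per peptide ion per sample), `sn_floor` (intensity divisor
#'   that yields the reported signal-to-noise ratio).
#' @param gradient_model list: `n_fractions` (default 19) and `species`, a
#'   list of sedimenting species, each `list(name, members, amount, center,
#'   width)` with `members` canonical subunit names.
#' @param background list: `n_contaminants`, `contaminant_level` (relative
#'   abundance of background proteins).
#' @param loading_cv coefficient of variation of the per-sample loading /
#'   capture factor shared by every complex-derived protein in an
#'   affinity-purified sample (amount of purified complex injected varies
#'   between IPs; background contaminants do not scale with it). Not applied
#'   in gradient mode, where all fractions come from one lysate.
#' @param run_drift_sigma lognormal sigma of the per-run intensity scale
#'   factor (inter-run drift removed later by internal-standard calibration).
#' @param n_standards number of spiked isotopically labeled standard
#'   peptides per run (default 8).
#' @param intensity_scale global factor mapping abundance units to XIC areas.
#' @param seed integer seed; with a fixed seed outputs are byte-identical.
#' @return Object of class `ground_truth_model`.
#' @export
ground_truth_model <- function(cell_lines,
                               association_propensity,
                               regulator_pools = NULL,
                               capture_yield = 0.87,
                               peptide_model = list(),
                               gradient_model = list(),
                               background = list(),
                               loading_cv = 0.1,
                               run_drift_sigma = 0.2,
                               n_standards = 8,
                               intensity_scale = 1e6,
                               seed = 1L) {
  subtypes <- c("sP20S", "iP20S", "b5i_P20S", "b1ib5i_P20S")
  cl <- as.data.frame(cell_lines, stringsAsFactors = FALSE)
  for (col in c("f_b5i_P20S", "f_b1ib5i_P20S"))
    if (is.null(cl[[col]])) cl[[col]] <- 0
  stopifnot(all(c("name", "f_sP20S", "f_iP20S", "total_20S") %in% names(cl)))
  fr <- as.matrix(cl[, paste0("f_", subtypes)])
  if (any(abs(rowSums(fr) - 1) > 1e-9))
    stop("subtype fractions must sum to 1 per cell line")
  if (any(fr < 0)) stop("subtype fractions must be non-negative")
  if (!(capture_yield > 0 && capture_yield <= 1))
    stop("capture_yield must be in (0, 1]")

  ap <- as.matrix(association_propensity)
  if (is.null(colnames(ap)) || !all(c("sP20S", "iP20S") %in% colnames(ap)))
    stop("association_propensity needs 'sP20S' and 'iP20S' columns")
  for (col in c("b5i_P20S", "b1ib5i_P20S"))
    if (!col %in% colnames(ap))
      ap <- cbind(ap, stats::setNames(data.frame(ap[, "iP20S"]), col))
  ap <- as.matrix(ap[, subtypes, drop = FALSE])
  if (any(ap < 0 | ap > 1)) stop("association propensities must lie in [0, 1]")

  pm <- utils::modifyList(list(peptides_per_protein = 5L,
                               efficiency_sigma = 0.4,
                               noise_cv = 0.2,
                               missing_rate = 0.01,
                               sn_floor = 2000), peptide_model)
  if (pm$peptides_per_protein < 1) stop("peptides_per_protein must be >= 1")
  gm <- utils::modifyList(list(n_fractions = 19L, species = NULL),
                          gradient_model)
  if (gm$n_fractions < 2) stop("n_fractions must be >= 2")
  bg <- utils::modifyList(list(n_contaminants = 30L, contaminant_level = 0.1),
                          background)

  cat6 <- default_catalog()
  structure(list(cell_lines = cl,
                 association_propensity = ap,
                 regulator_pools = regulator_pools,
                 capture_yield = capture_yield,
                 peptide_model = pm,
                 gradient_model = gm,
                 background = bg,
                 loading_cv = loading_cv,
                 run_drift_sigma = run_drift_sigma,
                 n_standards = as.integer(n_standards),
                 intensity_scale = intensity_scale,
                 seed = as.integer(seed),
                 catalog = cat6$catalog,
                 complexes = cat6$complexes),
            class = "ground_truth_model")
}

#' @export
print.ground_truth_model <- function(x, ...) {
  cat(sprintf("ground_truth_model: %d cell line(s), %d regulator(s), seed %d\n",
              nrow(x$cell_lines), nrow(x$association_propensity), x$seed))
  invisible(x)
}

# lognormal multiplicative factor with a given CV (mean 1)
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# regulator -> member subunit names, from the default complex definitions
regulator_members <- function(model) {
  regs <- rownames(model$association_propensity)
  defs <- model$complexes[regs]
  if (any(vapply(defs, is.null, TRUE)))
    stop("unknown regulator(s): ",
         paste(regs[vapply(defs, is.null, TRUE)], collapse = ", "))
  lapply(defs, `[[`, "members")
}

# deterministic per-peptide efficiency factors, one per (protein, peptide),
# shared across samples within a simulated dataset
peptide_layout <- function(proteins, model) {
  k <- model$peptide_model$peptides_per_protein
  data.frame(
    protein = rep(proteins, each = k),
    peptide_id = paste0(rep(proteins, each = k), "_pep",
                        sprintf("%02d", rep(seq_len(k), length(proteins)))),
    efficiency = stats::rlnorm(length(proteins) * k,
                               sdlog = model$peptide_model$efficiency_sigma),
    stringsAsFactors = FALSE)
}

# expand a proteins x samples true-abundance matrix into a peptide table
expand_to_peptides <- function(truth_mat, layout, run_scale, model) {
  pm <- model$peptide_model
  samples <- colnames(truth_mat)
  n_pep <- nrow(layout)
  n_s <- length(samples)
  abund <- truth_mat[layout$protein, , drop = FALSE]           # peptides x samples
  base <- abund * layout$efficiency * model$intensity_scale
  base <- sweep(base, 2L, run_scale[samples], `*`)
  noise <- matrix(rlnorm_cv(n_pep * n_s, pm$noise_cv), n_pep, n_s)
  xic <- base * noise
  keep <- matrix(stats::runif(n_pep * n_s) >= pm$missing_rate, n_pep, n_s)
  keep <- keep & xic > 0
  idx <- which(keep, arr.ind = TRUE)
  dt <- data.table::data.table(
    sample_id = samples[idx[, 2L]],
    protein = layout$protein[idx[, 1L]],
    peptide_id = layout$peptide_id[idx[, 1L]],
    xic_area = xic[keep],
    is_standard = FALSE)
  dt[, sn_ratio := xic_area / pm$sn_floor]
  # spiked internal standards: constant amount, perturbed only by run drift
  std_amount <- 10^seq(4, 6, length.out = model$n_standards)
  std <- data.table::CJ(sample_id = samples, j = seq_len(model$n_standards))
  std[, `:=`(protein = "ISTD",
             peptide_id = paste0("ISTD_pep", sprintf("%02d", j)),
             xic_area = std_amount[j] * run_scale[sample_id],
             is_standard = TRUE,
             sn_ratio = std_amount[j] * run_scale[sample_id] / pm$sn_floor)]
  std[, j := NULL]
  out <- data.table::rbindlist(list(dt, std), use.names = TRUE)
  data.table::setkey(out, sample_id, protein, peptide_id)
  out[]
}

# per-sample true protein abundances for an AP-MS style capture, given a
# matrix of per-sample subtype abundances (subtypes x samples)
apms_protein_truth <- function(subtype_ab, model) {
  cat6 <- model$catalog
  yield <- model$capture_yield
  nc <- noncatalytic_subunits()
  catal <- subtype_catalytic()
  regs <- regulator_members(model)
  ap <- model$association_propensity

  rows <- list()
  total <- colSums(subtype_ab)
  for (s in nc) rows[[s]] <- yield * total
  all_cat <- unique(unlist(catal))
  for (s in all_cat) {
    in_sub <- names(catal)[vapply(catal, function(m) s %in% m, TRUE)]
    rows[[s]] <- yield * colSums(subtype_ab[in_sub, , drop = FALSE])
  }
  for (g in names(regs)) {
    bound <- yield * colSums(subtype_ab * ap[g, rownames(subtype_ab)])
    for (s in regs[[g]]) rows[[s]] <- bound
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- subunit_accessions(names(rows), cat6)
  colnames(mat) <- colnames(subtype_ab)
  mat
}

contaminant_truth <- function(n_samples, sample_ids, model, flat = FALSE) {
  bg <- model$background
  if (bg$n_contaminants < 1)
    return(matrix(0, 0, n_samples, dimnames = list(NULL, sample_ids)))
  mat <- matrix(
    bg$contaminant_level * stats::rlnorm(bg$n_contaminants * n_samples, sdlog = 1),
    bg$n_contaminants, n_samples)
  rownames(mat) <- sprintf("CONT%03d", seq_len(bg$n_contaminants))
  colnames(mat) <- sample_ids
  mat
}

#' Simulate an AP-MS purification series
#'
#' For each cell line and replicate, one immunopurified sample: per-protein
#' true abundance is `capture_yield` times the (replicate-perturbed) subtype
#' abundances summed over the subtypes containing the protein, and, for
#' regulator subunits, weighted by the association propensity. Proteins are
#' expanded into peptide ions with fixed per-peptide efficiencies, lognormal
#' measurement noise, dropout, per-run drift and spiked standards.
#'
#' @param model a [ground_truth_model()].
#' @param replicates_per_line integer scalar or vector (one per cell line).
#' @param condition_by optional function(name) mapping cell-line name to a
#'   condition label stored in the metadata (default: the cell-line name).
#' @return Object of class `sim_dataset`: list with `peptide_table`
#'   (data.table: sample_id, protein, peptide_id, xic_area, sn_ratio,
#'   is_standard), `metadata` (sample_id, cell_line, replicate, condition,
#'   fraction = NA) and `truth` (model, per-sample subtype abundances,
#'   per-sample per-protein true abundances, per-run scale factors).
#' @examples
#' m <- default_apms_model(seed = 7)
#' sim <- simulate_apms(m)
#' nrow(sim$metadata)  # 24 samples
#' @export
simulate_apms <- function(model, replicates_per_line = NULL,
                          condition_by = NULL) {
  stopifnot(inherits(model, "ground_truth_model"))
  cl <- model$cell_lines
  if (is.null(replicates_per_line))
    replicates_per_line <- attr(model, "default_replicates") %||%
      rep(2L, nrow(cl))
  if (length(replicates_per_line) == 1L)
    replicates_per_line <- rep(replicates_per_line, nrow(cl))
  if (length(replicates_per_line) != nrow(cl))
    stop("replicates_per_line must be scalar or one per cell line")
  if (any(replicates_per_line < 1)) stop("replicate count must be >= 1")

  set.seed(model$seed)
  subtypes <- c("sP20S", "iP20S", "b5i_P20S", "b1ib5i_P20S")
  meta <- do.call(rbind, lapply(seq_len(nrow(cl)), function(i) {
    data.frame(cell_line = cl$name[i], replicate = seq_len(replicates_per_line[i]),
               stringsAsFactors = FALSE)
  }))
  meta$sample_id <- sprintf("%s_r%d", meta$cell_line, meta$replicate)
  meta$condition <- if (is.null(condition_by)) meta$cell_line else
    vapply(meta$cell_line, condition_by, "")
  meta$fraction <- NA_integer_
  n_s <- nrow(meta)

  base <- t(as.matrix(cl[, paste0("f_", subtypes)])) * rep(cl$total_20S,
                                                           each = 4)
  rownames(base) <- subtypes
  colnames(base) <- cl$name
  # replicate-level biological perturbation of the subtype abundances
  cv <- model$peptide_model$noise_cv
  subtype_ab <- base[, meta$cell_line, drop = FALSE] *
    matrix(rlnorm_cv(4L * n_s, cv), 4L, n_s)
  # shared per-sample loading / capture variability (recorded in the truth)
  subtype_ab <- sweep(subtype_ab, 2L, rlnorm_cv(n_s, model$loading_cv), `*`)
  colnames(subtype_ab) <- meta$sample_id

  truth_mat <- apms_protein_truth(subtype_ab, model)
  cont <- contaminant_truth(n_s, meta$sample_id, model)
  truth_mat <- rbind(truth_mat, cont)

  layout <- peptide_layout(rownames(truth_mat), model)
  run_scale <- stats::setNames(rlnorm_cv(n_s, sqrt(exp(model$run_drift_sigma^2) - 1)),
                               meta$sample_id)
  tab <- expand_to_peptides(truth_mat, layout, run_scale, model)

  new_sim_dataset(tab, meta[, c("sample_id", "cell_line", "replicate",
                                "condition", "fraction")],
                  model, subtype_ab, truth_mat, run_scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_sim_dataset <- function(tab, meta, model, subtype_ab, truth_mat, run_scale) {
  structure(list(
    peptide_table = tab,
    metadata = meta,
    truth = list(model = model,
                 subtype_abundance = subtype_ab,
                 protein_truth = truth_mat,
                 run_scale = run_scale)),
    class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: %d samples, %d peptide rows, %d proteins\n",
              nrow(x$metadata), nrow(x$peptide_table),
              nrow(x$truth$protein_truth)))
  invisible(x)
}

#' Simulate a density-gradient fractionation (PCP) experiment
#'
#' Each sedimenting species of the model's `gradient_model$species` list is a
#' Gaussian over fraction indexes (declared center and width, in fractions).
#' A protein's per-fraction true abundance is the sum over all species
#' containing it. Each fraction of each replicate is one LC-MS run with its
#' own drift factor and spiked standards.
#'
#' @inheritParams simulate_apms
#' @param replicates number of gradient replicates (default 2).
#' @return A `sim_dataset`; `metadata$fraction` holds the fraction index and
#'   `metadata$replicate` the gradient replicate.
#' @export
simulate_gradient <- function(model, replicates = 2L) {
  stopifnot(inherits(model, "ground_truth_model"))
  species <- model$gradient_model$species
  if (is.null(species)) stop("model$gradient_model$species is not set")
  nf <- model$gradient_model$n_fractions
  cat6 <- model$catalog
  known <- cat6$entries$subunit_name
  for (sp in species) {
    bad <- setdiff(sp$members, known)
    if (length(bad))
      stop("species '", sp$name, "' references unknown subunit(s): ",
           paste(bad, collapse = ", "))
  }

  set.seed(model$seed)
  meta <- expand.grid(fraction = seq_len(nf), replicate = seq_len(replicates))
  meta$sample_id <- sprintf("r%d_f%02d", meta$replicate, meta$fraction)
  meta$cell_line <- model$cell_lines$name[1]
  meta$condition <- "gradient"
  n_s <- nrow(meta)
  cv <- model$peptide_model$noise_cv

  # species x sample true amounts: Gaussian peak, replicate-perturbed amount
  prot_acc <- unique(subunit_accessions(unlist(lapply(species, `[[`, "members")),
                                        cat6))
  truth_mat <- matrix(0, length(prot_acc), n_s,
                      dimnames = list(prot_acc, meta$sample_id))
  for (sp in species) {
    amt_rep <- sp$amount * rlnorm_cv(replicates, cv)
    peak <- exp(-(meta$fraction - sp$center)^2 / (2 * sp$width^2))
    amounts <- amt_rep[meta$replicate] * peak
    accs <- subunit_accessions(sp$members, cat6)
    truth_mat[accs, ] <- truth_mat[accs, , drop = FALSE] +
      matrix(amounts, length(accs), n_s, byrow = TRUE)
  }
  # contaminants: own random peak (or flat) per protein, shared across reps
  bg <- model$background
  if (bg$n_contaminants > 0) {
    centers <- stats::runif(bg$n_contaminants, 1, nf)
    widths <- stats::runif(bg$n_contaminants, 1, 4)
    flat <- stats::runif(bg$n_contaminants) < 0.3
    amt <- bg$contaminant_level * stats::rlnorm(bg$n_contaminants, sdlog = 1)
    cont <- t(vapply(seq_len(bg$n_contaminants), function(i) {
      if (flat[i]) rep(amt[i], n_s) else
        amt[i] * exp(-(meta$fraction - centers[i])^2 / (2 * widths[i]^2))
    }, numeric(n_s)))
    rownames(cont) <- sprintf("CONT%03d", seq_len(bg$n_contaminants))
    colnames(cont) <- meta$sample_id
    truth_mat <- rbind(truth_mat, cont)
  }

  layout <- peptide_layout(rownames(truth_mat), model)
  run_scale <- stats::setNames(rlnorm_cv(n_s, sqrt(exp(model$run_drift_sigma^2) - 1)),
                               meta$sample_id)
  tab <- expand_to_peptides(truth_mat, layout, run_scale, model)
  new_sim_dataset(tab, meta[, c("sample_id", "cell_line", "replicate",
                                "condition", "fraction")],
                  model, NULL, truth_mat, run_scale)
}

#' Simulate an interferon-gamma induction time course
#'
#' AP-MS samples at each time point, with the subtype abundances of the
#' model's (single) cell line multiplied by a per-timepoint fold schedule
#' (e.g. immunoproteasome up eightfold, standard proteasome halved at 72 h).
#' Regulator amounts follow from the association propensities.
#'
#' @inheritParams simulate_apms
#' @param timepoints character vector of time point labels, e.g.
#'   `c("0h", "24h", "48h", "72h")`.
#' @param fold_schedule named list of numeric vectors (names `sP20S`,
#'   `iP20S`, optionally intermediates), each the per-timepoint multiplier;
#'   every vector must cover every time point (names or positions).
#' @param replicates biological replicates per time point (default 3).
#' @return A `sim_dataset`; `metadata$condition` is the time point.
#' @export
simulate_ifng_timecourse <- function(model, timepoints, fold_schedule,
                                     replicates = 3L) {
  stopifnot(inherits(model, "ground_truth_model"))
  if (nrow(model$cell_lines) != 1L)
    stop("time-course simulation expects a single-cell-line model")
  subtypes <- c("sP20S", "iP20S", "b5i_P20S", "b1ib5i_P20S")
  sched <- matrix(1, length(subtypes), length(timepoints),
                  dimnames = list(subtypes, timepoints))
  for (st in names(fold_schedule)) {
    v <- fold_schedule[[st]]
    if (!is.null(names(v))) {
      if (!all(timepoints %in% names(v)))
        stop("fold_schedule for '", st, "' is missing time point(s): ",
             paste(setdiff(timepoints, names(v)), collapse = ", "))
      v <- v[timepoints]
    } else if (length(v) != length(timepoints)) {
      stop("fold_schedule for '", st, "' must cover every time point")
    }
    sched[st, ] <- v
  }
  # intermediates follow the immuno schedule unless given explicitly
  for (st in c("b5i_P20S", "b1ib5i_P20S"))
    if (!st %in% names(fold_schedule)) sched[st, ] <- sched["iP20S", ]

  set.seed(model$seed)
  cl <- model$cell_lines
  base <- cl$total_20S[1] * as.numeric(cl[1, paste0("f_", subtypes)])
  names(base) <- subtypes

  meta <- expand.grid(replicate = seq_len(replicates), condition = timepoints,
                      stringsAsFactors = FALSE)
  meta$cell_line <- cl$name[1]
  meta$sample_id <- sprintf("%s_%s_r%d", meta$cell_line, meta$condition,
                            meta$replicate)
  meta$fraction <- NA_integer_
  n_s <- nrow(meta)
  cv <- model$peptide_model$noise_cv

  subtype_ab <- (base * sched[, meta$condition, drop = FALSE]) *
    matrix(rlnorm_cv(4L * n_s, cv), 4L, n_s)
  subtype_ab <- sweep(subtype_ab, 2L, rlnorm_cv(n_s, model$loading_cv), `*`)
  colnames(subtype_ab) <- meta$sample_id

  truth_mat <- apms_protein_truth(subtype_ab, model)
  cont <- contaminant_truth(n_s, meta$sample_id, model)
  truth_mat <- rbind(truth_mat, cont)
  layout <- peptide_layout(rownames(truth_mat), model)
  run_scale <- stats::setNames(rlnorm_cv(n_s, sqrt(exp(model$run_drift_sigma^2) - 1)),
                               meta$sample_id)
  tab <- expand_to_peptides(truth_mat, layout, run_scale, model)
  attr(sched, "timepoints") <- timepoints
  out <- new_sim_dataset(tab, meta[, c("sample_id", "cell_line", "replicate",
                                       "condition", "fraction")],
                         model, subtype_ab, truth_mat, run_scale)
  out$truth$fold_schedule <- sched
  out
}
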