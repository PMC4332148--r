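# End-to-end orchestration --------------------------------------------------

#' Build a run configuration
#'
#' One structure drives an end-to-end run: simulation mode, thresholds (all
#' defaulting to the analysis defaults), toggles for the documented design
#' choices, and the master seed from which every stage's randomness flows.
#' Configurations round-trip losslessly through YAML.
#'
#' @param mode `"apms"`, `"gradient"` or `"timecourse"`.
#' @param out_dir output directory for stage artifacts.
#' @param seed master seed.
#' @param r_threshold,min_peptides,min_median_sn PIP filter thresholds.
#' @param epsilon chi-squared denominator floor.
#' @param pcp_reference reference complex for the gradient screen.
#' @param reference_condition reference condition for the differential
#'   stage (default: first condition encountered).
#' @param missing_ref PAI missing-reference-peptide rule ("mean" or "zero").
#' @param calibrate apply internal-standard calibration.
#' @param var_equal equal-variance t-test (FALSE = Welch).
#' @param noise_cv simulator noise level.
#' @return List of class `run_config`.
#' @export
pipeline_config <- function(mode = c("apms", "gradient", "timecourse"),
                            out_dir = "pipeline_out", seed = 1L,
                            r_threshold = 0.8, min_peptides = 2,
                            min_median_sn = 10, epsilon = 1e-4,
                            pcp_reference = paste0("PA28", .alpha, .beta),
                            reference_condition = NULL,
                            missing_ref = "mean", calibrate = TRUE,
                            var_equal = TRUE, noise_cv = 0.2) {
  mode <- match.arg(mode)
  pcp_reference <- enc2utf8(pcp_reference)
  structure(list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
                 r_threshold = r_threshold, min_peptides = min_peptides,
                 min_median_sn = min_median_sn, epsilon = epsilon,
                 pcp_reference = pcp_reference,
                 reference_condition = reference_condition,
                 missing_ref = missing_ref, calibrate = calibrate,
                 var_equal = var_equal, noise_cv = noise_cv),
            class = "run_config")
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML file path.
#' @param config a `run_config`.
#' @return [read_run_config()]: a `run_config`; the writer returns `path`.
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lst <- lapply(lst, function(x) if (is.character(x)) enc2utf8(x) else x)
  do.call(pipeline_config, lst)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  yaml::write_yaml(unclass(config), con)
  invisible(path)
}

# deterministic per-stage seeds derived from the master seed
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, quantify = 211L, pcp = 307L,
               correlate = 401L, cluster = 503L, differential = 601L)
  (as.integer(seed) * 1009L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full pipeline
#'
#' Simulates the requested experiment, quantifies it, runs the mode's
#' analysis stages (gradient: profile chi-squared screen; apms: reference
#' correlation, PIP filter, supervised / PCA / UPGMA clustering;
#' timecourse: differential regulator association) and writes every stage
#' artifact plus a reproducibility manifest into `config$out_dir`. Running
#' the same configuration and seed twice yields byte-identical outputs.
#'
#' @param config a `run_config` (or path to a YAML config).
#' @return The manifest list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  cat6 <- default_catalog()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  sim_seed <- stage_seed(config$seed, "simulate")
  sim <- switch(config$mode,
    apms = simulate_apms(default_apms_model(seed = sim_seed,
                                            noise_cv = config$noise_cv)),
    gradient = simulate_gradient(default_gradient_model(
      seed = sim_seed, noise_cv = config$noise_cv)),
    timecourse = simulate_ifng_timecourse(
      ifng_model(seed = sim_seed, noise_cv = config$noise_cv),
      timepoints = names(ifng_schedule()$iP20S),
      fold_schedule = ifng_schedule()))
  write_sim_dataset(sim, file.path(config$out_dir, "simulated"))
  counts$samples <- nrow(sim$metadata)
  counts$peptide_rows <- nrow(sim$peptide_table)

  if (config$mode == "gradient") {
    reps <- split(sim$metadata, sim$metadata$replicate)
    pai_list <- lapply(reps, function(md) {
      md <- md[order(md$fraction), ]
      tab <- sim$peptide_table[sim$peptide_table$sample_id %in% md$sample_id]
      subset_samples(quantify(tab, calibrate = config$calibrate,
                              missing_ref = config$missing_ref),
                     md$sample_id)
    })
    if (!config$pcp_reference %in% names(cat6$complexes))
      stop("stage pcp: unknown reference complex '", config$pcp_reference, "'")
    screen <- pcp_screen(pai_list, config$pcp_reference,
                         defs = cat6$complexes, catalog = cat6$catalog,
                         epsilon = config$epsilon)
    write_tsv(screen, file.path(config$out_dir, "chi2_screen.tsv"))
    counts$proteins_screened <- nrow(screen)
  } else {
    pai <- quantify(sim$peptide_table, calibrate = config$calibrate,
                    missing_ref = config$missing_ref)
    write_pai_matrix(pai, file.path(config$out_dir, "pai.tsv"))
    counts$proteins_quantified <- nrow(pai$values)

    refs <- build_reference_abundances(pai, cat6$complexes, cat6$catalog)
    cm <- correlation_matrix(pai, refs)
    write_tsv(data.frame(protein = rownames(cm$r2), cm$r2,
                         check.names = FALSE),
              file.path(config$out_dir, "r2_matrix.tsv"))
    write_tsv(data.frame(protein = rownames(cm$r), cm$r, check.names = FALSE),
              file.path(config$out_dir, "r_matrix.tsv"))
    pips <- filter_pips(pai, cm$r, r_threshold = config$r_threshold,
                        min_peptides = config$min_peptides,
                        min_median_sn = config$min_median_sn)
    write_tsv(pips, file.path(config$out_dir, "pips.tsv"))
    counts$confident_pips <- nrow(pips)

    ok <- rowSums(is.na(cm$r2)) == 0
    if (sum(ok) >= 2) {
      sup <- supervised_cluster(cm$r2[ok, , drop = FALSE])
      write_tsv(data.frame(protein = sup$order,
                           cluster3 = cut_clusters(sup, 3)[sup$order]),
                file.path(config$out_dir, "supervised_order.tsv"))
      norm <- max_normalize(pai)
      pca <- pca_pearson(norm)
      write_tsv(data.frame(protein = rownames(pca$scores),
                           pca$scores[, 1:min(3, ncol(pca$scores))],
                           check.names = FALSE),
                file.path(config$out_dir, "pca_scores.tsv"))
      dend <- ahc_upgma(norm)
      writeLines(as_newick(dend),
                 file.path(config$out_dir, "upgma.nwk"))
    }

    if (config$mode == "timecourse") {
      ref_cond <- config$reference_condition %||% sim$metadata$condition[1]
      diff <- differential_association(sim$peptide_table, sim$metadata,
                                       reference_condition = ref_cond,
                                       defs = cat6$complexes,
                                       catalog = cat6$catalog,
                                       var_equal = config$var_equal)
      write_tsv(diff, file.path(config$out_dir, "differential.tsv"))
      counts$regulators_tested <- length(unique(diff$regulator))
    }
  }

  manifest <- list(
    mode = config$mode,
    seed = config$seed,
    config = unclass(config),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    package_version = as.character(utils::packageVersion("proteoPCP")),
    counts = counts)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
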