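## pipeline_cli: end-to-end orchestration --------------------------------

#' Run the full QC pipeline on a matrix + metadata pair
#'
#' Validates the inputs, normalizes iBAQ to FOT when needed, and
#' computes per experiment: the four-dimensional QC summary, the global
#' SNR (plus SNR per intensity tertile when requested), intensity-group
#' assignments, identification frequencies, and DEP records; across all
#' experiments it adds occurrence bins, the DEP reproducibility
#' frequency table, and (when several months are present) the stability
#' series. The report is fully determined by inputs + config and
#' carries a provenance block (input hashes, thresholds, package
#' version).
#'
#' @param x a [quant_matrix] (iBAQ or FOT) or a path readable by
#'   [read_quant_matrix].
#' @param metadata a [run_metadata] or a path readable by
#'   [read_metadata].
#' @param fc_threshold DEP fold-change threshold (default 2).
#' @param snr_by_intensity also compute SNR within each intensity
#'   tertile of every experiment (slower).
#' @param output_dir if non-`NULL`, report tables are written there as
#'   TSV files (only after every stage succeeded).
#' @return list of class `qc_report` with elements `four_dim`, `snr`,
#'   `intensity_groups`, `dep_records`, `dep_frequency`,
#'   `occurrence_bins`, `stability` (or `NULL`), `provenance`.
#' @export
run_full_qc <- function(x, metadata, fc_threshold = 2,
                        snr_by_intensity = FALSE, output_dir = NULL) {
  if (is.character(x)) x <- read_quant_matrix(x)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  if (!inherits(metadata, "run_metadata")) metadata <- run_metadata(metadata)
  check_pairing(x, metadata)
  fot <- if (quant_unit(x) == "iBAQ") ibaq_to_fot(x) else x

  experiments <- unique(metadata$experiment_id)
  four_dim <- list(); snr_rows <- list(); assignments <- list()
  dep_records <- list()
  for (eid in experiments) {
    runs <- experiment_runs(metadata, eid)
    four_dim[[eid]] <- four_dim_summary(fot, metadata, eid)
    assignments[[eid]] <- assign_intensity_groups(fot, metadata, eid)
    snr_rows[[eid]] <- pipeline_snr_row(fot, metadata, eid, "global",
                                        proteins = NULL)
    if (snr_by_intensity) {
      a <- assignments[[eid]]
      for (g in c("low", "medium", "high")) {
        snr_rows[[paste(eid, g)]] <- pipeline_snr_row(
          fot, metadata, eid, g,
          proteins = a$protein_id[a$group == g])
      }
    }
    dep_records[[eid]] <- detect_deps(fot, metadata, eid,
                                      fc_threshold = fc_threshold)
  }
  all_deps <- do.call(rbind, dep_records)
  dep_freq <- if (nrow(all_deps))
    dep_reproducibility(all_deps, length(experiments)) else NULL
  stability <- if (length(unique(metadata$month)) > 1L)
    stability_series(fot, metadata) else NULL

  report <- list(
    four_dim = do.call(rbind, four_dim),
    snr = do.call(rbind, snr_rows),
    intensity_groups = assignments,
    dep_records = all_deps,
    dep_frequency = dep_freq,
    occurrence_bins = occurrence_bins(fot),
    stability = stability,
    provenance = list(
      package_version = as.character(utils::packageVersion("proteoqc")),
      n_proteins = nrow(x), n_runs = ncol(x),
      n_experiments = length(experiments),
      fc_threshold = fc_threshold,
      input_unit = quant_unit(x),
      matrix_hash = matrix_hash(x),
      timestamp_free = TRUE))
  class(report) <- "qc_report"
  if (!is.null(output_dir)) write_qc_report(report, output_dir)
  report
}

pipeline_snr_row <- function(fot, metadata, eid, scope, proteins) {
  runs <- experiment_runs(metadata, eid)
  res <- tryCatch(
    snr_from_matrix(fot, metadata, runs = runs, proteins = proteins),
    proteoqc_degenerate_error = function(e) NULL,
    proteoqc_error = function(e) NA)
  if (is.null(res))
    return(data.frame(experiment_id = eid, scope = scope,
                      snr_db = Inf, category = "degenerate",
                      stringsAsFactors = FALSE))
  if (!inherits(res, "snr_result"))
    return(data.frame(experiment_id = eid, scope = scope,
                      snr_db = NA_real_, category = NA_character_,
                      stringsAsFactors = FALSE))
  data.frame(experiment_id = eid, scope = scope, snr_db = res$snr_db,
             category = res$category, stringsAsFactors = FALSE)
}

# content hash of the numeric payload, used for provenance
matrix_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(list(dimnames(x), as.vector(unclass(x))), con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:",
      x$provenance$n_proteins, "proteins,",
      x$provenance$n_runs, "runs,",
      x$provenance$n_experiments, "experiment(s)\n")
  print(x$four_dim)
  print(x$snr)
  invisible(x)
}

#' Write the report tables of a QC run as TSV files
#'
#' @param report a `qc_report` from [run_full_qc].
#' @param output_dir directory (created if absent).
#' @return `output_dir`, invisibly.
#' @export
write_qc_report <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    if (is.null(df) || !NROW(df)) return()
    utils::write.table(df, file.path(output_dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(report$four_dim, "four_dim_summary")
  wt(report$snr, "snr")
  wt(report$dep_records, "dep_records")
  wt(report$dep_frequency, "dep_frequency")
  wt(report$occurrence_bins, "occurrence_bins")
  if (!is.null(report$stability))
    wt(report$stability$reproducibility, "stability")
  prov <- report$provenance
  writeLines(paste(names(prov), vapply(prov, as.character, ""),
                   sep = "\t"),
             file.path(output_dir, "provenance.tsv"))
  invisible(output_dir)
}

#' Benchmark suite over simulated scenarios
#'
#' Runs a grid of simulation scenarios (by default: the three injection
#' modes under drift, a clean reference, and a noise sweep), computes
#' the SNR, median within-group CV, and DEP recall/precision against the
#' planted truth for each, and returns one summary row per scenario.
#' Scenario failures are recorded, not fatal.
#'
#' @param scenarios named list of [simulation_config] objects; a default
#'   grid is built from `base_seed` when omitted.
#' @param base_seed root seed for the default grid.
#' @param fc_threshold DEP threshold used for recall/precision.
#' @return data.frame: `scenario`, `snr_db`, `snr_category`,
#'   `median_cv`, `dep_recall`, `dep_precision`, `seed`, `error`.
#' @export
run_benchmark_suite <- function(scenarios = NULL, base_seed = 1L,
                                fc_threshold = 2) {
  if (is.null(scenarios)) {
    scenarios <- list(
      clean = simulation_config(n_proteins = 1000L, seed = base_seed,
                                cv_profile = c(low = 0.3, medium = 0.2,
                                               high = 0.1)),
      noisy = simulation_config(n_proteins = 1000L, seed = base_seed + 1L),
      drift_RI = simulation_config(n_proteins = 1000L, seed = base_seed + 2L,
                                   injection_mode = "RI",
                                   drift_per_injection = 1.05),
      drift_CI1 = simulation_config(n_proteins = 1000L, seed = base_seed + 2L,
                                    injection_mode = "CI1",
                                    drift_per_injection = 1.05),
      drift_CI2 = simulation_config(n_proteins = 1000L, seed = base_seed + 2L,
                                    injection_mode = "CI2",
                                    drift_per_injection = 1.05))
  }
  rows <- lapply(names(scenarios), function(nm) {
    cfg <- scenarios[[nm]]
    tryCatch({
      sim <- simulate_experiment(cfg)
      fot <- ibaq_to_fot(sim$matrix)
      snr <- tryCatch(snr_from_matrix(fot, sim$metadata),
                      proteoqc_degenerate_error = function(e) e)
      degenerate <- inherits(snr, "condition")
      deps <- detect_deps(fot, sim$metadata, "E1",
                          fc_threshold = fc_threshold)
      perf <- dep_performance(deps, sim$truth)
      cvs <- c()
      for (g in cfg$group_labels) {
        runs <- sim$metadata$run_id[sim$metadata$group_label == g]
        cvs <- c(cvs, matrix_cvs(fot, runs))
      }
      data.frame(scenario = nm,
                 snr_db = if (degenerate) Inf else snr$snr_db,
                 snr_category = if (degenerate) "degenerate"
                                else snr$category,
                 median_cv = stats::median(cvs, na.rm = TRUE),
                 dep_recall = perf["recall"],
                 dep_precision = perf["precision"],
                 seed = cfg$seed, error = NA_character_,
                 stringsAsFactors = FALSE, row.names = NULL)
    }, error = function(e) {
      data.frame(scenario = nm, snr_db = NA_real_,
                 snr_category = NA_character_, median_cv = NA_real_,
                 dep_recall = NA_real_, dep_precision = NA_real_,
                 seed = cfg$seed, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}

#' Recall and precision of DEP calls against planted truth
#'
#' A planted DEP is "recalled" when at least one emitted record (any
#' pair, any direction) names its protein; precision is the fraction of
#' called proteins that are planted DEPs or group-specific proteins
#' (both are truly differential).
#'
#' @param deps `dep_records` from [detect_deps].
#' @param truth a `ground_truth`.
#' @return named vector `c(recall, precision)`.
#' @export
dep_performance <- function(deps, truth) {
  true_ids <- unique(c(truth$dep_flags$protein_id,
                       unlist(truth$specific_proteins, use.names = FALSE)))
  called <- unique(deps$protein_id)
  recall <- if (length(true_ids))
    length(intersect(called, true_ids)) / length(true_ids) else NA_real_
  precision <- if (length(called))
    length(intersect(called, true_ids)) / length(called) else NA_real_
  c(recall = recall, precision = precision)
}
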