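## synthetic_data: ground-truthed simulator of DDA quantification -------

#' Simulation configuration
#'
#' Bundles every knob of the label-free quantification simulator. The
#' defaults emulate a reference-material design: 4 biological groups
#' (four family members D5/D6/F7/M8) times 3 technical replicates, base
#' abundances spanning 7 orders of magnitude, ~4% group-specific
#' proteins, intensity-dependent technical CV (80% in the low-intensity
#' tertile down to 20% in the high tertile) and intensity-dependent
#' stochastic detection, as observed in data-dependent acquisition.
#'
#' @param n_proteins number of simulated proteins.
#' @param m_groups number of biological groups (>= 2 for SNR designs).
#' @param n_replicates technical replicates per group (>= 2).
#' @param group_labels optional character vector of group names; defaults
#'   to D5/D6/F7/M8 when `m_groups == 4`, else `G1..Gm`.
#' @param dynamic_range_log10 decades spanned by base abundances.
#' @param group_effect_sd standard deviation (in log10 decades) of
#'   per-protein per-group biological effects: samples from different
#'   individuals differ modestly across the whole proteome, not only in
#'   the planted differential proteins. Set to 0 for groups that are
#'   biologically identical up to the planted differences.
#' @param dep_fraction fraction of proteins planted as differentially
#'   expressed in exactly one group.
#' @param dep_fc_range range (low, high) from which true fold changes of
#'   planted DEPs are drawn, log-uniformly; both must exceed
#'   `dep_threshold`.
#' @param dep_threshold fold-change threshold the planted DEPs must
#'   exceed (the downstream caller's detection threshold is separate).
#' @param specific_fraction fraction of proteins, per group, expressed in
#'   that group only.
#' @param cv_profile named numeric vector `c(low=, medium=, high=)` of
#'   target technical CVs per base-intensity tertile.
#' @param detection_midpoint log10-abundance at which detection
#'   probability is 0.5. `NULL` (default) places it at the 30th
#'   percentile of simulated log10 base abundances, which yields
#'   realistic DDA-like missingness concentrated in low-intensity
#'   proteins.
#' @param detection_slope logistic slope per log10 decade; `Inf` gives
#'   deterministic detection above the midpoint.
#' @param always_detect if `TRUE`, detection probability is forced to 1
#'   (no missingness).
#' @param injection_mode `"RI"` (random injection over an extended
#'   window), `"CI1"` (continuous, groups interleaved per replicate
#'   cycle) or `"CI2"` (continuous, each group's replicates in one
#'   block).
#' @param drift_per_injection multiplicative intensity drift per
#'   injection slot (1 = none).
#' @param ri_window_factor in RI mode, injection slots are drawn from a
#'   window this many times larger than the run count, reflecting runs
#'   scattered over days rather than queued back-to-back.
#' @param months number of monthly time points (1 = no longitudinal arm).
#' @param degradation_fraction fraction of proteins subject to
#'   time-dependent decay.
#' @param degradation_rate exponential decay rate per month past onset.
#' @param degradation_onset_month last stable month; decay applies to
#'   months beyond it.
#' @param twin_similarity probability that a planted DEP assigned to one
#'   of the first two groups is shared by both (monozygotic-twin
#'   structure); 0 disables it.
#' @param seed integer seed; together with the config it fully determines
#'   all outputs.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_proteins = 3000L,
                              m_groups = 4L,
                              n_replicates = 3L,
                              group_labels = NULL,
                              dynamic_range_log10 = 7,
                              group_effect_sd = 0.1,
                              dep_fraction = 0.1,
                              dep_fc_range = c(4, 16),
                              dep_threshold = 2,
                              specific_fraction = 0.04,
                              cv_profile = c(low = 0.8, medium = 0.4,
                                             high = 0.2),
                              detection_midpoint = NULL,
                              detection_slope = 2,
                              always_detect = FALSE,
                              injection_mode = c("CI2", "CI1", "RI"),
                              drift_per_injection = 1,
                              ri_window_factor = 7,
                              months = 1L,
                              degradation_fraction = 0,
                              degradation_rate = 0.4,
                              degradation_onset_month = 12L,
                              twin_similarity = 0,
                              seed = 1L) {
  injection_mode <- match.arg(injection_mode)
  cfg <- list(
    n_proteins = as.integer(n_proteins), m_groups = as.integer(m_groups),
    n_replicates = as.integer(n_replicates), group_labels = group_labels,
    dynamic_range_log10 = dynamic_range_log10,
    group_effect_sd = group_effect_sd,
    dep_fraction = dep_fraction, dep_fc_range = dep_fc_range,
    dep_threshold = dep_threshold, specific_fraction = specific_fraction,
    cv_profile = cv_profile, detection_midpoint = detection_midpoint,
    detection_slope = detection_slope, always_detect = always_detect,
    injection_mode = injection_mode,
    drift_per_injection = drift_per_injection,
    ri_window_factor = ri_window_factor, months = as.integer(months),
    degradation_fraction = degradation_fraction,
    degradation_rate = degradation_rate,
    degradation_onset_month = as.integer(degradation_onset_month),
    twin_similarity = twin_similarity, seed = as.integer(seed))
  validate_config(cfg)
  if (is.null(cfg$group_labels)) {
    cfg$group_labels <- if (cfg$m_groups == 4L) c("D5", "D6", "F7", "M8")
                        else paste0("G", seq_len(cfg$m_groups))
  }
  class(cfg) <- "simulation_config"
  cfg
}

validate_config <- function(cfg) {
  fracs <- c(dep_fraction = cfg$dep_fraction,
             specific_fraction = cfg$specific_fraction,
             degradation_fraction = cfg$degradation_fraction,
             twin_similarity = cfg$twin_similarity)
  bad <- names(fracs)[fracs < 0 | fracs > 1]
  if (length(bad))
    pqc_stop(sprintf("fraction(s) outside [0,1]: %s",
                     paste(bad, collapse = ", ")),
             "proteoqc_config_error")
  if (cfg$m_groups < 2L)
    pqc_stop("m_groups must be >= 2", "proteoqc_config_error")
  if (cfg$n_replicates < 2L)
    pqc_stop("n_replicates must be >= 2", "proteoqc_config_error")
  if (cfg$n_proteins < 1L)
    pqc_stop("n_proteins must be >= 1", "proteoqc_config_error")
  if (any(cfg$dep_fc_range <= cfg$dep_threshold))
    pqc_stop("dep_fc_range must lie above dep_threshold",
             "proteoqc_config_error")
  if (any(cfg$cv_profile < 0) ||
      !all(c("low", "medium", "high") %in% names(cfg$cv_profile)))
    pqc_stop("cv_profile needs non-negative entries named low/medium/high",
             "proteoqc_config_error")
  if (cfg$drift_per_injection <= 0)
    pqc_stop("drift_per_injection must be > 0", "proteoqc_config_error")
  if (cfg$group_effect_sd < 0)
    pqc_stop("group_effect_sd must be >= 0", "proteoqc_config_error")
  invisible(TRUE)
}

# CV of a lognormal with log-sd sigma is sqrt(exp(sigma^2) - 1); invert
cv_to_sigma <- function(cv) sqrt(log(1 + cv^2))

#' Generate the ground truth of a simulated study
#'
#' Draws per-protein base abundances (lognormal, linearly rescaled in
#' log10 space so the realized span equals `dynamic_range_log10`
#' decades), plants group-specific proteins and differentially expressed
#' proteins with fold changes above the configured threshold, stratifies
#' proteins into base-intensity tertiles carrying the CV targets, and
#' fixes the detection-probability curve.
#'
#' @param config a [simulation_config].
#' @return list of class `ground_truth` with elements `protein_ids`,
#'   `base_abundance` (proteins x groups; 0 where a protein does not
#'   belong to a group), `dep_flags` (data.frame: protein_id, group,
#'   fold_change plus one row per affected group pair), `specific_proteins`
#'   (named list per group), `stratum` (low/medium/high per protein),
#'   `degraded` (logical per protein), `detection_midpoint`,
#'   `detection_slope`, `cv_profile`.
#' @export
generate_ground_truth <- function(config) {
  validate_config(config)
  cfg <- config
  set.seed(cfg$seed)

  p <- cfg$n_proteins
  m <- cfg$m_groups
  ids <- sprintf("P%05d", seq_len(p))
  groups <- cfg$group_labels

  # lognormal base abundance; rescale log10 values so the empirical span
  # equals the configured dynamic range exactly
  z <- stats::rnorm(p)
  if (p > 1L && diff(range(z)) > 0) {
    z <- (z - min(z)) / diff(range(z)) * cfg$dynamic_range_log10
  } else {
    z <- rep(cfg$dynamic_range_log10 / 2, p)
  }
  log10_base <- z  # decades above the floor (floor = 1 in arbitrary units)
  # proteome-wide inter-individual variation: every protein differs a
  # little between groups, on top of which DEPs are planted
  effects <- matrix(stats::rnorm(p * m, sd = cfg$group_effect_sd), p, m)
  base <- matrix(10^(log10_base + effects), nrow = p, ncol = m,
                 dimnames = list(ids, groups))

  # group-specific proteins: disjoint sets, expressed only in their group
  specific <- stats::setNames(vector("list", m), groups)
  n_spec <- floor(cfg$specific_fraction * p)
  if (n_spec * m > p)
    pqc_stop("specific_fraction too large for n_proteins",
             "proteoqc_config_error")
  pool <- sample(ids, n_spec * m)
  for (g in seq_len(m)) {
    sel <- pool[seq.int((g - 1L) * n_spec + 1L, length.out = n_spec)]
    specific[[g]] <- sel
    base[sel, -g] <- 0
  }

  # planted DEPs: elevate one group by a fold change drawn above threshold
  candidates <- setdiff(ids, pool)
  n_dep <- floor(cfg$dep_fraction * p)
  n_dep <- min(n_dep, length(candidates))
  dep_ids <- if (n_dep) sample(candidates, n_dep) else character(0)
  dep_rows <- list()
  if (n_dep) {
    tgt <- sample.int(m, n_dep, replace = TRUE)
    fc <- exp(stats::runif(n_dep, log(cfg$dep_fc_range[1]),
                           log(cfg$dep_fc_range[2])))
    twin <- cfg$twin_similarity > 0 & m >= 2L & tgt <= 2L &
      stats::runif(n_dep) < cfg$twin_similarity
    for (k in seq_len(n_dep)) {
      gset <- if (twin[k]) 1:2 else tgt[k]
      base[dep_ids[k], gset] <- base[dep_ids[k], gset] * fc[k]
      dep_rows[[k]] <- data.frame(protein_id = dep_ids[k],
                                  group = groups[tgt[k]],
                                  shared_twin = twin[k],
                                  fold_change = fc[k],
                                  stringsAsFactors = FALSE)
    }
  }
  dep_flags <- if (length(dep_rows)) do.call(rbind, dep_rows) else
    data.frame(protein_id = character(0), group = character(0),
               shared_twin = logical(0), fold_change = numeric(0))

  # base-intensity tertile strata (on the shared log10 base abundance)
  q <- stats::quantile(log10_base, c(0.3333, 0.6667), names = FALSE)
  stratum <- cut(log10_base, c(-Inf, q, Inf),
                 labels = c("low", "medium", "high"), right = TRUE)
  stratum <- as.character(stratum)

  midpoint <- cfg$detection_midpoint
  if (is.null(midpoint)) midpoint <- stats::quantile(log10_base, 0.30,
                                                     names = FALSE)
  degraded <- rep(FALSE, p)
  n_deg <- floor(cfg$degradation_fraction * p)
  if (n_deg) degraded[sample.int(p, n_deg)] <- TRUE

  truth <- list(protein_ids = ids, base_abundance = base,
                dep_flags = dep_flags, specific_proteins = specific,
                stratum = stats::setNames(stratum, ids),
                degraded = stats::setNames(degraded, ids),
                detection_midpoint = midpoint,
                detection_slope = cfg$detection_slope,
                cv_profile = cfg$cv_profile)
  class(truth) <- "ground_truth"
  truth
}

# month-dependent decay factor for degraded proteins
degradation_factor <- function(truth, month, config) {
  onset <- config$degradation_onset_month
  f <- rep(1, length(truth$protein_ids))
  if (month > onset) {
    f[truth$degraded] <- exp(-config$degradation_rate * (month - onset))
  }
  f
}

#' Simulate a single MS run
#'
#' Observed abundance = base x lognormal technical noise (stratum CV
#' target, mean-1 parameterization) x drift^(injection slot - 1) x
#' degradation factor. Each protein is then detected independently with
#' probability given by a logistic curve in its noiseless log10
#' abundance; undetected entries are `NA`.
#'
#' @param truth a [generate_ground_truth] result.
#' @param group group label present in the truth.
#' @param replicate replicate index (bookkeeping only).
#' @param injection_index injection slot, >= 1; drift exponent is
#'   `injection_index - 1`.
#' @param month month index, >= 1.
#' @param config the [simulation_config].
#' @param seed run-level seed.
#' @return named numeric vector (length `n_proteins`) with `NA` for
#'   undetected proteins.
#' @export
simulate_run <- function(truth, group, replicate, injection_index = 1L,
                         month = 1L, config, seed) {
  if (!group %in% colnames(truth$base_abundance))
    pqc_stop(sprintf("unknown group '%s'", group), "proteoqc_lookup_error")
  set.seed(as.integer(seed))
  base <- truth$base_abundance[, group]
  sigma <- cv_to_sigma(truth$cv_profile[truth$stratum])
  noise <- exp(stats::rnorm(length(base)) * sigma - sigma^2 / 2)
  drift <- config$drift_per_injection^(injection_index - 1L)
  degr <- degradation_factor(truth, month, config)
  observed <- base * noise * drift * degr

  # detection driven by the noiseless (pre-noise) abundance
  noiseless <- base * drift * degr
  expressed <- base > 0
  if (config$always_detect) {
    prob <- as.numeric(expressed)
  } else {
    lg <- ifelse(expressed, log10(noiseless), -Inf)
    if (is.infinite(config$detection_slope)) {
      prob <- as.numeric(lg >= truth$detection_midpoint)
    } else {
      prob <- stats::plogis(config$detection_slope *
                              (lg - truth$detection_midpoint))
    }
    prob[!expressed] <- 0
  }
  detected <- stats::runif(length(base)) < prob
  observed[!detected] <- NA_real_
  stats::setNames(observed, truth$protein_ids)
}

# injection slots per run for one experiment (m*n runs).
# Runs are ordered group-major (all replicates of group 1, then group 2 ...).
injection_slots <- function(config, seed) {
  m <- config$m_groups; n <- config$n_replicates
  total <- m * n
  switch(config$injection_mode,
    # CI2: 555-666-777-888 — each group's replicates form a block
    CI2 = as.integer(outer(seq_len(n), (seq_len(m) - 1L) * n, `+`)),
    # CI1: 5678-5678-5678 — groups cycle within each replicate round
    CI1 = as.integer(outer((seq_len(n) - 1L) * m, seq_len(m), `+`)),
    # RI: runs scattered over a window ri_window_factor times wider,
    # emulating random scheduling over days rather than one queue
    RI = {
      set.seed(as.integer(seed))
      window <- max(total, ceiling(config$ri_window_factor * total))
      sample(sample.int(window, total))  # random slots, random assignment
    })
}

#' Simulate a complete experiment (or monthly series of experiments)
#'
#' Produces the full m-groups x n-replicates design: ground truth, one
#' simulated run per (group, replicate) with injection slots assigned by
#' the configured injection mode, and tidy run metadata. With
#' `months > 1` the design is repeated at each monthly time point
#' (experiment ids `E1_m<month>`), sharing one ground truth.
#'
#' @param config a [simulation_config].
#' @param truth optional pre-generated [generate_ground_truth] output
#'   (shared truth across experiments of a campaign).
#' @param experiment_id id stem for metadata rows.
#' @return list with `matrix` (a [quant_matrix], unit iBAQ),
#'   `metadata` (a [run_metadata]) and `truth`.
#' @export
simulate_experiment <- function(config, truth = NULL,
                                experiment_id = "E1") {
  validate_config(config)
  if (is.null(truth)) truth <- generate_ground_truth(config)
  m <- config$m_groups; n <- config$n_replicates
  groups <- config$group_labels
  months <- seq_len(config$months)

  cols <- list(); meta <- list()
  for (mo in months) {
    slots <- injection_slots(config, seed = config$seed + 7919L * mo)
    k <- 0L
    for (g in seq_len(m)) {
      for (r in seq_len(n)) {
        k <- k + 1L
        run_seed <- (config$seed + 104729L * mo + 613L * k) %% .Machine$integer.max
        v <- simulate_run(truth, groups[g], r,
                          injection_index = slots[k], month = mo,
                          config = config, seed = run_seed)
        eid <- if (config$months > 1L)
          sprintf("%s_m%02d", experiment_id, mo) else experiment_id
        rid <- sprintf("%s_%s_r%d", eid, groups[g], r)
        cols[[rid]] <- v
        meta[[rid]] <- data.frame(
          run_id = rid, group_label = groups[g], replicate_index = r,
          experiment_id = eid, site_id = "S1", instrument_id = "sim",
          injection_index = slots[k], month = mo,
          material_form = "peptide", stringsAsFactors = FALSE)
      }
    }
  }
  mat <- do.call(cbind, cols)
  colnames(mat) <- names(cols)
  list(matrix = quant_matrix(mat, unit = "iBAQ"),
       metadata = run_metadata(do.call(rbind, meta)),
       truth = truth)
}

#' Simulate a multi-experiment campaign sharing one ground truth
#'
#' Emulates the same reference samples being measured in `n_experiments`
#' independent experiments (different sites/instruments): each
#' experiment re-runs the design with its own derived seed while the
#' underlying biology (ground truth) stays fixed.
#'
#' @param config a [simulation_config] (with `months = 1`).
#' @param n_experiments number of experiments.
#' @return list with combined `matrix`, `metadata` (experiment ids
#'   `E01..`), and the shared `truth`.
#' @export
simulate_campaign <- function(config, n_experiments) {
  stopifnot(n_experiments >= 1L)
  truth <- generate_ground_truth(config)
  mats <- list(); metas <- list()
  for (e in seq_len(n_experiments)) {
    cfg_e <- config
    cfg_e$seed <- (config$seed + 15485863L * e) %% .Machine$integer.max
    class(cfg_e) <- "simulation_config"
    sim <- simulate_experiment(cfg_e, truth = truth,
                               experiment_id = sprintf("E%02d", e))
    mats[[e]] <- unclass(sim$matrix)
    metas[[e]] <- as.data.frame(sim$metadata)
  }
  mat <- do.call(cbind, mats)
  list(matrix = quant_matrix(mat, unit = "iBAQ"),
       metadata = run_metadata(do.call(rbind, metas)),
       truth = truth)
}

#' Simulate a dilution series for internal-standard peptides
#'
#' Signal = dilution factor x per-peptide response x lognormal noise
#' (mean-1, CV `noise_cv`). Deterministic given the seed.
#'
#' @param anchor_peptides character vector of peptide ids.
#' @param dilution_factors strictly positive dilution factors, >= 3
#'   points.
#' @param noise_cv technical CV of the measured signal.
#' @param seed integer seed.
#' @param response optional named vector of per-peptide responses
#'   (signal per unit amount); drawn log-uniformly in `[1e5, 1e7]` when
#'   omitted.
#' @return data.frame with columns `peptide_id`, `dilution_factor`,
#'   `signal`.
#' @export
simulate_dilution_series <- function(anchor_peptides, dilution_factors,
                                     noise_cv = 0, seed = 1L,
                                     response = NULL) {
  if (length(dilution_factors) < 3L)
    pqc_stop("a dilution series needs >= 3 points",
             "proteoqc_config_error")
  if (any(dilution_factors <= 0))
    pqc_stop("dilution factors must be strictly positive",
             "proteoqc_config_error")
  set.seed(as.integer(seed))
  if (is.null(response)) {
    response <- stats::setNames(
      10^stats::runif(length(anchor_peptides), 5, 7), anchor_peptides)
  }
  sigma <- cv_to_sigma(noise_cv)
  out <- expand.grid(peptide_id = anchor_peptides,
                     dilution_factor = dilution_factors,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  noise <- if (noise_cv > 0)
    exp(stats::rnorm(nrow(out)) * sigma - sigma^2 / 2) else 1
  out$signal <- out$dilution_factor * response[out$peptide_id] * noise
  rownames(out) <- NULL
  out
}
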