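## differential: fold-change DEP calls and reproducibility frequency ----

#' Detect differentially expressed proteins within one experiment
#'
#' For each unordered group pair (canonical orientation: test = the
#' group that sorts first, reference = the other, unless `pairs` is
#' supplied) the fold change is the ratio of mean sentinel-filled FOT
#' across replicates. A protein is called up when the ratio strictly
#' exceeds `fc_threshold` and down when it is strictly below
#' `1/fc_threshold`. The sentinel-inclusive mean keeps proteins absent
#' from one group in the analysis, where they show a large but finite
#' ratio.
#'
#' @param x a [quant_matrix] in FOT units (sentinel-filled).
#' @param metadata a [run_metadata].
#' @param experiment_id experiment whose runs are compared.
#' @param fc_threshold fold-change threshold, strictly > 1 (default 2).
#' @param pairs optional data.frame with columns `test`, `reference`
#'   giving the orientations to evaluate; defaults to all unordered
#'   pairs in sorted-label orientation.
#' @return data.frame of class `dep_records`: `protein_id`, `test`,
#'   `reference`, `direction` (`up`/`down`), `fold_change`,
#'   `experiment_id`.
#' @export
detect_deps <- function(x, metadata, experiment_id, fc_threshold = 2,
                        pairs = NULL) {
  if (fc_threshold <= 1)
    pqc_stop("fc_threshold must be > 1", "proteoqc_config_error")
  runs <- experiment_runs(metadata, experiment_id)
  groups <- metadata$group_label[match(runs, metadata$run_id)]
  glev <- sort(unique(groups))
  if (length(glev) < 2L)
    pqc_stop("DEP detection needs >= 2 groups", "proteoqc_design_error")
  if (is.null(pairs)) {
    cmb <- utils::combn(glev, 2)
    pairs <- data.frame(test = cmb[1, ], reference = cmb[2, ],
                        stringsAsFactors = FALSE)
  }
  unknown <- setdiff(unique(c(pairs$test, pairs$reference)), glev)
  if (length(unknown))
    pqc_stop(sprintf("unknown group(s): %s",
                     paste(unknown, collapse = ", ")),
             "proteoqc_lookup_error")
  v <- unclass(x)[, runs, drop = FALSE]
  v[is.na(v)] <- FOT_SENTINEL
  gmeans <- sapply(glev, function(g)
    rowMeans(v[, groups == g, drop = FALSE]))

  recs <- list()
  for (k in seq_len(nrow(pairs))) {
    fc <- gmeans[, pairs$test[k]] / gmeans[, pairs$reference[k]]
    up <- fc > fc_threshold
    dn <- fc < 1 / fc_threshold
    hit <- up | dn
    if (!any(hit)) next
    recs[[k]] <- data.frame(
      protein_id = rownames(gmeans)[hit],
      test = pairs$test[k], reference = pairs$reference[k],
      direction = ifelse(up[hit], "up", "down"),
      fold_change = fc[hit], experiment_id = experiment_id,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(protein_id = character(0), test = character(0),
               reference = character(0), direction = character(0),
               fold_change = numeric(0), experiment_id = character(0))
  class(out) <- c("dep_records", "data.frame")
  out
}

# bin edges for reproducibility frequency over E experiments.
# The reference campaign of E = 24 uses the published 1-9/10-18/19-24
# partition; other E use equal integer thirds, remainders to lower bins.
dep_frequency_breaks <- function(n_experiments) {
  e <- as.integer(n_experiments)
  if (e == 24L) return(c(9L, 18L, 24L))
  base <- e %/% 3L; rem <- e %% 3L
  sizes <- base + c(rem >= 1L, rem >= 2L, 0L)
  cumsum(sizes)
}

#' Reproducibility frequency of DEP calls across experiments
#'
#' Counts, for each (protein, group pair, direction) triple, the number
#' of experiments whose DEP list contains it, and bins the count into
#' low/medium/high reproducibility. For a 24-experiment campaign the
#' bins are 1-9 (low), 10-18 (medium), 19-24 (high); otherwise the range
#' `[1, E]` is split into three equal integer parts with remainders
#' assigned to the lower bins.
#'
#' @param records row-bound `dep_records` from several experiments.
#' @param n_experiments total number of experiments E in the campaign.
#' @return data.frame of class `dep_frequency_table`: `protein_id`,
#'   `test`, `reference`, `direction`, `frequency`, `bin`
#'   (`low`/`medium`/`high`); attribute `breaks` holds the bin edges.
#' @export
dep_reproducibility <- function(records, n_experiments) {
  stopifnot(n_experiments >= 1L)
  key_full <- paste(records$protein_id, records$test, records$reference,
                    records$direction, records$experiment_id, sep = "\r")
  if (anyDuplicated(key_full)) {
    pqc_warn("duplicate DEP record(s) within one experiment; deduplicating")
    records <- records[!duplicated(key_full), , drop = FALSE]
  }
  key <- paste(records$protein_id, records$test, records$reference,
               records$direction, sep = "\r")
  freq <- table(key)
  parts <- do.call(rbind, strsplit(names(freq), "\r", fixed = TRUE))
  br <- dep_frequency_breaks(n_experiments)
  f <- as.integer(freq)
  if (any(f > n_experiments))
    pqc_stop("observed frequency exceeds n_experiments",
             "proteoqc_validation_error")
  bin <- factor(ifelse(f <= br[1], "low",
                       ifelse(f <= br[2], "medium", "high")),
                levels = c("low", "medium", "high"))
  out <- data.frame(protein_id = parts[, 1], test = parts[, 2],
                    reference = parts[, 3], direction = parts[, 4],
                    frequency = f, bin = bin, stringsAsFactors = FALSE,
                    row.names = NULL)
  out <- out[order(out$protein_id, out$test, out$reference,
                   out$direction), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "breaks") <- br
  class(out) <- c("dep_frequency_table", "data.frame")
  out
}

#' DEPs with a consistent trend across every experiment
#'
#' Filters the frequency table to triples whose frequency equals the
#' number of experiments, i.e. the protein was called in the same
#' direction for the same pair in every single experiment. A protein
#' ever called in both directions for the same pair is excluded.
#'
#' @param freq_table a `dep_frequency_table`.
#' @param n_experiments total experiments E.
#' @return subset of `freq_table` rows.
#' @export
consistent_trend_deps <- function(freq_table, n_experiments) {
  both_key <- paste(freq_table$protein_id, freq_table$test,
                    freq_table$reference, sep = "\r")
  dir_count <- tapply(freq_table$direction, both_key,
                      function(d) length(unique(d)))
  ambiguous <- names(dir_count)[dir_count > 1]
  keep <- freq_table$frequency == n_experiments &
    !(both_key %in% ambiguous)
  out <- freq_table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
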