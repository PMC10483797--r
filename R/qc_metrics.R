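## qc_metrics: reproducibility, variability, stability -------------------

#' Coefficient of variation of replicate measurements
#'
#' `100 * sd / mean` (sample SD), in percent. Returns `NA` when fewer
#' than 2 present values are supplied (such proteins are skipped, not
#' errors, by callers).
#'
#' @param values numeric vector of present replicate measurements.
#' @return CV in percent, or `NA_real_`.
#' @examples
#' protein_cv(c(1, 2, 3))  # 50
#' @export
protein_cv <- function(values) {
  values <- values[is_present(values)]
  if (length(values) < 2L) return(NA_real_)
  100 * stats::sd(values) / mean(values)
}

# per-protein CVs over a set of runs (rows with < 2 present values -> NA)
matrix_cvs <- function(x, runs) {
  sub <- unclass(x)[, runs, drop = FALSE]
  apply(sub, 1L, protein_cv)
}

#' Median CV per intensity group
#'
#' Per-protein CVs are computed across the given runs (present values
#' only) and summarized as the median within each intensity tertile and
#' globally.
#'
#' @param x a [quant_matrix] (FOT).
#' @param metadata a [run_metadata]; optional when `runs` given.
#' @param assignment output of [assign_intensity_groups].
#' @param experiment_id,runs run selection, as in
#'   [assign_intensity_groups].
#' @return data.frame `group` (`low`, `medium`, `high`, `global`),
#'   `median_cv`, `n_proteins`. Empty groups yield `NA` with a warning.
#' @export
median_cv_by_group <- function(x, metadata = NULL, assignment,
                               experiment_id = NULL, runs = NULL) {
  if (is.null(runs)) runs <- experiment_runs(metadata, experiment_id)
  cvs <- matrix_cvs(x, runs)
  cvs <- cvs[!is.na(cvs)]
  lvl <- c("low", "medium", "high")
  rows <- lapply(c(lvl, "global"), function(g) {
    ids <- if (g == "global") assignment$protein_id
           else assignment$protein_id[assignment$group == g]
    vals <- cvs[intersect(names(cvs), ids)]
    if (!length(vals)) {
      pqc_warn(sprintf("no proteins with computable CV in group '%s'", g))
      data.frame(group = g, median_cv = NA_real_, n_proteins = 0L)
    } else {
      data.frame(group = g, median_cv = stats::median(vals),
                 n_proteins = length(vals))
    }
  })
  do.call(rbind, rows)
}

#' Identification frequency within an experiment
#'
#' For each protein observed at least once in the experiment's runs,
#' counts in how many of the n replicate runs it is present.
#'
#' @inheritParams median_cv_by_group
#' @return data.frame `protein_id`, `idf` (1..n), plus attribute
#'   `n_runs`.
#' @export
identification_frequency <- function(x, metadata = NULL,
                                     experiment_id = NULL, runs = NULL) {
  if (is.null(runs)) runs <- experiment_runs(metadata, experiment_id)
  present <- is_present(unclass(x)[, runs, drop = FALSE])
  counts <- rowSums(present)
  counts <- counts[counts > 0]
  structure(data.frame(protein_id = names(counts), idf = as.integer(counts),
                       stringsAsFactors = FALSE),
            n_runs = length(runs))
}

#' Occurrence-frequency confidence bins over all runs
#'
#' Occurrence frequency = number of runs where the protein is present
#' divided by total runs. Proteins are placed into 11 bins: ten
#' equal-width 10%-bins on `[0, 1)` plus a distinct exact-100% bin
#' holding proteins observed in every run.
#'
#' @param x a [quant_matrix] over all runs of the study.
#' @return data.frame `protein_id`, `occurrence_frequency`, `bin` (an
#'   ordered factor with 11 levels). Proteins never observed are
#'   excluded.
#' @export
occurrence_bins <- function(x) {
  present <- is_present(unclass(x))
  total <- ncol(x)
  counts <- rowSums(present)
  keep <- counts > 0
  freq <- counts[keep] / total
  labels <- c(sprintf("[%d,%d%%)", seq(0, 90, 10), seq(10, 100, 10)),
              "100%")
  bin <- ifelse(freq == 1, 11L, pmin(10L, floor(freq * 10) + 1L))
  data.frame(protein_id = rownames(x)[keep],
             occurrence_frequency = unname(freq),
             bin = factor(labels[bin], levels = labels, ordered = TRUE),
             stringsAsFactors = FALSE)
}

#' Pairwise Pearson correlation between runs
#'
#' Computed on log10 of sentinel-filled FOT values over the union of
#' proteins present in at least one run of each pair (default), or over
#' proteins present in both (`mode = "intersect"`). Constant columns
#' give `NA` with a warning.
#'
#' @param x a [quant_matrix] (FOT).
#' @param runs run ids (>= 2); defaults to all columns.
#' @param mode `"union"` or `"intersect"` protein universe per pair.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pairwise_correlation <- function(x, runs = colnames(x),
                                 mode = c("union", "intersect")) {
  mode <- match.arg(mode)
  if (length(runs) < 2L)
    pqc_stop("need >= 2 runs for a correlation matrix",
             "proteoqc_validation_error")
  v <- unclass(x)[, runs, drop = FALSE]
  present <- is_present(v)
  v[is.na(v)] <- FOT_SENTINEL
  lv <- log10(v)
  k <- length(runs)
  r <- diag(1, k)
  dimnames(r) <- list(runs, runs)
  warned <- FALSE
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      sel <- if (mode == "union") present[, i] | present[, j]
             else present[, i] & present[, j]
      a <- lv[sel, i]; b <- lv[sel, j]
      if (sum(sel) < 2L || stats::sd(a) == 0 || stats::sd(b) == 0) {
        if (!warned) {
          pqc_warn("constant or empty profile: correlation undefined for some pair(s)")
          warned <- TRUE
        }
        r[i, j] <- r[j, i] <- NA_real_
      } else {
        r[i, j] <- r[j, i] <- stats::cor(a, b)
      }
    }
  }
  r
}

#' Overlap statistics among protein sets
#'
#' Exact set algebra over >= 2 named sets: the common intersection, the
#' union, per-set totals and per-set specific counts (elements in no
#' other set), plus overlap percentages relative to a declared
#' reference set.
#'
#' @param sets named list of character vectors.
#' @param reference name of the reference set for percentages (default:
#'   first set).
#' @return list with `intersection`, `union`, `per_set` (data.frame:
#'   set, size, specific, overlap_with_reference_pct).
#' @export
overlap_sets <- function(sets, reference = names(sets)[1]) {
  if (length(sets) < 2L)
    pqc_stop("need >= 2 sets", "proteoqc_validation_error")
  sets <- lapply(sets, unique)
  if (!reference %in% names(sets) || !length(sets[[reference]]))
    pqc_stop("reference set missing or empty", "proteoqc_validation_error")
  inter <- Reduce(intersect, sets)
  uni <- Reduce(union, sets)
  ref <- sets[[reference]]
  per_set <- do.call(rbind, lapply(names(sets), function(nm) {
    others <- unlist(sets[setdiff(names(sets), nm)], use.names = FALSE)
    data.frame(set = nm, size = length(sets[[nm]]),
               specific = length(setdiff(sets[[nm]], others)),
               overlap_with_reference_pct =
                 100 * length(intersect(sets[[nm]], ref)) / length(ref),
               stringsAsFactors = FALSE)
  }))
  list(intersection = inter, union = uni, per_set = per_set)
}

#' Intensity-group transition matrix between two experiments
#'
#' For each intensity tertile of experiment A, the percentage of its
#' proteins that land in each tertile of experiment B or are not
#' detected there — the table behind a Sankey flow diagram. Each source
#' row sums to 100.
#'
#' @param assignment_a,assignment_b outputs of
#'   [assign_intensity_groups] for the two experiments.
#' @return 3 x 4 matrix (rows `low`/`medium`/`high` of A; columns
#'   `low`/`medium`/`high`/`not_detected` of B), in percent. Empty
#'   source groups give rows of `NA`.
#' @export
intensity_flow <- function(assignment_a, assignment_b) {
  lvl <- c("low", "medium", "high")
  dest <- stats::setNames(assignment_b$group, assignment_b$protein_id)
  out <- matrix(NA_real_, 3L, 4L,
                dimnames = list(lvl, c(lvl, "not_detected")))
  for (g in lvl) {
    ids <- assignment_a$protein_id[assignment_a$group == g]
    if (!length(ids)) next
    to <- dest[ids]
    to[is.na(to)] <- "not_detected"
    tab <- table(factor(to, levels = colnames(out)))
    out[g, ] <- 100 * as.numeric(tab) / length(ids)
  }
  out
}

#' Longitudinal stability of protein identification
#'
#' Reproducibility of month t versus a reference month: the fraction of
#' proteins identified in the reference month that are also identified
#' (in >= 1 run) in month t — globally and within the reference month's
#' intensity tertiles. Per-protein monthly mean FOT profiles are
#' returned for trend inspection.
#'
#' @param x a [quant_matrix] (FOT) covering all months.
#' @param metadata a [run_metadata] with a `month` column.
#' @param reference_month month used as baseline (default: earliest).
#' @return list with `reproducibility` (data.frame month x group),
#'   `trends` (proteins x months matrix of mean present FOT),
#'   `reference_month`.
#' @export
stability_series <- function(x, metadata, reference_month = NULL) {
  months <- sort(unique(metadata$month))
  if (length(months) < 2L)
    pqc_stop("stability analysis needs >= 2 months",
             "proteoqc_validation_error")
  if (is.null(reference_month)) reference_month <- months[1]
  if (!reference_month %in% months)
    pqc_stop(sprintf("reference month %s absent from metadata",
                     reference_month), "proteoqc_validation_error")
  runs_of <- function(mo) metadata$run_id[metadata$month == mo]
  identified <- lapply(months, function(mo) {
    present <- is_present(unclass(x)[, runs_of(mo), drop = FALSE])
    rownames(x)[rowSums(present) > 0]
  })
  names(identified) <- as.character(months)
  ref_ids <- identified[[as.character(reference_month)]]
  ref_assign <- assign_intensity_groups(x, runs = runs_of(reference_month))
  lvl <- c("low", "medium", "high")
  rows <- list()
  for (mo in months) {
    now <- identified[[as.character(mo)]]
    for (g in c(lvl, "global")) {
      ids <- if (g == "global") ref_ids
             else intersect(ref_ids,
                            ref_assign$protein_id[ref_assign$group == g])
      rows[[length(rows) + 1L]] <- data.frame(
        month = mo, group = g,
        reproducibility = if (length(ids))
          length(intersect(ids, now)) / length(ids) else NA_real_,
        n_reference = length(ids))
    }
  }
  trends <- sapply(months, function(mo) {
    sub <- unclass(x)[, runs_of(mo), drop = FALSE]
    sub[!is_present(sub)] <- NA_real_
    rowMeans(sub, na.rm = TRUE)
  })
  colnames(trends) <- as.character(months)
  list(reproducibility = do.call(rbind, rows), trends = trends,
       reference_month = reference_month)
}

#' Four-dimensional QC summary of an experiment
#'
#' The four coordinates of the quality map: mean number of proteins
#' identified per run; reproducibility (fraction of observed proteins
#' identified in all runs); mean pairwise Pearson correlation among
#' technical-replicate runs of the same group; and median per-protein
#' within-group CV. When no group structure is supplied the runs are
#' treated as one flat replicate set.
#'
#' @inheritParams median_cv_by_group
#' @return one-row data.frame of class `four_dim_summary` with columns
#'   `experiment_id`, `n_proteins_identified`, `reproducibility`,
#'   `mean_pearson_r`, `median_cv`.
#' @export
four_dim_summary <- function(x, metadata = NULL, experiment_id = NULL,
                             runs = NULL) {
  if (is.null(runs)) runs <- experiment_runs(metadata, experiment_id)
  if (length(runs) < 2L)
    pqc_stop("four-dimensional summary needs >= 2 runs",
             "proteoqc_design_error")
  groups <- if (!is.null(metadata))
    metadata$group_label[match(runs, metadata$run_id)]
  else rep("all", length(runs))
  present <- is_present(unclass(x)[, runs, drop = FALSE])
  idf <- rowSums(present)
  observed <- idf > 0

  # correlations and CVs within replicate sets of the same group
  rvals <- c(); cvs <- c()
  for (g in unique(groups)) {
    gruns <- runs[groups == g]
    if (length(gruns) < 2L) next
    r <- pairwise_correlation(x, gruns)
    rvals <- c(rvals, r[upper.tri(r)])
    cvs <- c(cvs, matrix_cvs(x, gruns))
  }
  out <- data.frame(
    experiment_id = experiment_id %||% "experiment",
    n_proteins_identified = mean(colSums(present)),
    reproducibility = sum(idf == length(runs)) / sum(observed),
    mean_pearson_r = mean(rvals, na.rm = TRUE),
    median_cv = stats::median(cvs, na.rm = TRUE),
    stringsAsFactors = FALSE)
  class(out) <- c("four_dim_summary", "data.frame")
  out
}
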