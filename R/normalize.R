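## normalization: iBAQ -> FOT and intensity tertiles ---------------------

#' Normalize iBAQ values to fraction of total (FOT)
#'
#' Per run, each protein's iBAQ is divided by the run's total iBAQ over
#' identified proteins and scaled by `1e5`, so present values in a run
#' sum to `1e5`. Entries missing in the input are assigned the `1e-5`
#' sentinel (the convention used downstream for log transforms and
#' fold-change means); set `fill_missing = FALSE` to keep them `NA`.
#'
#' @param x a [quant_matrix] with unit `"iBAQ"`.
#' @param fill_missing assign `1e-5` to missing entries (default) or
#'   keep `NA`.
#' @return a [quant_matrix] with unit `"FOT"`.
#' @examples
#' m <- matrix(c(2, 3, 5), 3, 1, dimnames = list(paste0("P", 1:3), "r1"))
#' ibaq_to_fot(quant_matrix(m, "iBAQ"))   # 20000, 30000, 50000
#' @export
ibaq_to_fot <- function(x, fill_missing = TRUE) {
  stopifnot(inherits(x, "quant_matrix"))
  if (quant_unit(x) != "iBAQ")
    pqc_stop(sprintf("expected unit 'iBAQ', got '%s'", quant_unit(x)),
             "proteoqc_validation_error")
  totals <- colSums(x, na.rm = TRUE)
  empty <- colSums(!is.na(x)) == 0L
  if (any(empty))
    pqc_stop(sprintf("run(s) with no identified proteins: %s",
                     paste(colnames(x)[empty], collapse = ", ")),
             "proteoqc_normalization_error")
  fot <- sweep(unclass(x), 2L, totals, `/`) * FOT_SCALE
  if (fill_missing) fot[is.na(fot)] <- FOT_SENTINEL
  quant_matrix(fot, unit = "FOT")
}

#' Assign proteins of an experiment to intensity tertiles
#'
#' Ranks each protein by its basis intensity — the mean of its present
#' FOT values across the experiment's runs (sentinel-filled entries
#' excluded) — and cuts at the 33.33rd and 66.67th percentiles (linear
#' interpolation): below the first cut is `low`, above the second is
#' `high`, the rest `medium`. Only proteins detected at least once in
#' the experiment are assigned.
#'
#' @param x a [quant_matrix] (FOT units).
#' @param metadata a [run_metadata]; optional when `runs` is given.
#' @param experiment_id which experiment's runs to use.
#' @param runs explicit run ids, overriding metadata lookup.
#' @return data.frame `protein_id`, `group` (`low`/`medium`/`high`),
#'   `basis_value`, ordered by protein id.
#' @export
assign_intensity_groups <- function(x, metadata = NULL,
                                    experiment_id = NULL, runs = NULL) {
  stopifnot(inherits(x, "quant_matrix"))
  if (is.null(runs)) {
    if (is.null(metadata) || is.null(experiment_id))
      pqc_stop("supply either 'runs' or metadata + experiment_id",
               "proteoqc_validation_error")
    runs <- experiment_runs(metadata, experiment_id)
  }
  sub <- unclass(x)[, runs, drop = FALSE]
  present <- is_present(sub)
  keep <- rowSums(present) >= 1L
  if (!any(keep))
    pqc_stop("no protein detected in the experiment",
             "proteoqc_validation_error")
  sub <- sub[keep, , drop = FALSE]
  present <- present[keep, , drop = FALSE]
  vals <- sub
  vals[!present] <- NA_real_
  basis <- rowMeans(vals, na.rm = TRUE)
  # stable protein-id order before ranking so ties break deterministically
  basis <- basis[order(names(basis))]
  q <- stats::quantile(basis, c(0.3333, 0.6667), names = FALSE, type = 7)
  if (q[1] == q[2] && stats::var(basis) == 0) {
    pqc_warn("all basis intensities equal; assigning every protein to 'medium'")
    grp <- rep("medium", length(basis))
  } else {
    grp <- ifelse(basis < q[1], "low",
                  ifelse(basis > q[2], "high", "medium"))
  }
  data.frame(protein_id = names(basis), group = grp,
             basis_value = unname(basis), stringsAsFactors = FALSE)
}
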