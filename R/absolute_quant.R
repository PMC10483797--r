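## absolute_quant: internal-standard anchoring and copies/cell ----------

AVOGADRO <- 6.02214076e23

# coefficient of determination without summary.lm's perfect-fit warning
r_squared_of <- function(fit, y) {
  1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
}

#' Molar amount of a stable-isotope internal-standard protein
#'
#' The concatenated internal-standard protein carries a heavy-labeled
#' copy of a reference peptide whose light-labeled counterpart is added
#' in a known molar amount. The protein's molar amount follows from the
#' heavy/light signal ratio:
#' `amount = gold_amount_mol * heavy_signal / light_signal`.
#'
#' @param heavy_signal MS signal of the heavy (standard-protein)
#'   peptide.
#' @param light_signal MS signal of the light (spiked reference)
#'   peptide.
#' @param gold_amount_mol molar amount of the spiked reference peptide.
#' @return molar amount of the internal-standard protein.
#' @examples
#' qconcat_molar_amount(1, 2, 10e-12)  # 5 pmol
#' @export
qconcat_molar_amount <- function(heavy_signal, light_signal,
                                 gold_amount_mol) {
  if (any(c(heavy_signal, light_signal, gold_amount_mol) <= 0))
    pqc_stop("signals and reference amount must be > 0",
             "proteoqc_validation_error")
  gold_amount_mol * heavy_signal / light_signal
}

#' Linearity of a dilution series in log-log space
#'
#' Ordinary least squares of `log10(signal)` on `log10(dilution
#' factor)`. Zero signals are excluded with a warning; a constant signal
#' (zero variance) returns slope 0 with R-squared reported as 0 and a
#' warning.
#'
#' @param series data.frame with columns `dilution_factor` and `signal`
#'   (one peptide), e.g. one peptide's rows from
#'   [simulate_dilution_series].
#' @return list `slope`, `intercept`, `r_squared`, `n_points`.
#' @export
dilution_linearity <- function(series) {
  stopifnot(all(c("dilution_factor", "signal") %in% names(series)))
  if (any(series$dilution_factor <= 0))
    pqc_stop("dilution factors must be strictly positive",
             "proteoqc_validation_error")
  drop <- series$signal <= 0 | is.na(series$signal)
  if (any(drop)) {
    pqc_warn(sprintf("excluding %d non-positive signal point(s)",
                     sum(drop)))
    series <- series[!drop, , drop = FALSE]
  }
  if (nrow(series) < 3L)
    pqc_stop("fewer than 3 usable dilution points",
             "proteoqc_validation_error")
  lx <- log10(series$dilution_factor)
  ly <- log10(series$signal)
  if (stats::var(ly) == 0) {
    pqc_warn("constant signal across dilutions; R-squared undefined, reported as 0")
    return(list(slope = 0, intercept = mean(ly), r_squared = 0,
                n_points = nrow(series)))
  }
  fit <- stats::lm(ly ~ lx)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r_squared_of(fit, ly),
       n_points = nrow(series))
}

#' Calibrate relative abundance against anchor-protein copy numbers
#'
#' Fits `log10(ABQ) = slope * log10(iBAQ) + intercept` by ordinary least
#' squares over anchor proteins with known absolute copy numbers
#' (copies/cell). Two anchors give the exact interpolating line.
#'
#' @param anchor_abq absolute abundances (copies/cell), all positive.
#' @param anchor_ibaq matched relative abundances (iBAQ), all positive.
#' @param cells_per_sample cell count of the preparation the copy
#'   numbers refer to (stored for provenance).
#' @param anchor_ids optional anchor names used in error messages.
#' @return object of class `calibration_model`: `slope`, `intercept`,
#'   `r_squared`, `n_anchors`, `cells_per_sample`.
#' @export
fit_anchor_calibration <- function(anchor_abq, anchor_ibaq,
                                   cells_per_sample = NA_real_,
                                   anchor_ids = NULL) {
  if (length(anchor_abq) != length(anchor_ibaq) || length(anchor_abq) < 2L)
    pqc_stop("need matched anchor lists of length >= 2",
             "proteoqc_validation_error")
  if (is.null(anchor_ids))
    anchor_ids <- paste0("anchor", seq_along(anchor_abq))
  bad <- which(anchor_abq <= 0 | anchor_ibaq <= 0)
  if (length(bad))
    pqc_stop(sprintf("non-positive abundance for anchor '%s'",
                     anchor_ids[bad[1]]), "proteoqc_validation_error")
  lx <- log10(anchor_ibaq); ly <- log10(anchor_abq)
  fit <- stats::lm(ly ~ lx)
  r2 <- if (length(lx) == 2L) 1 else r_squared_of(fit, ly)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n_anchors = length(lx),
                 cells_per_sample = cells_per_sample),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "calibration: log10(copies/cell) = %.4f * log10(iBAQ) + %.4f (R2 = %.4f, %d anchors)\n",
    x$slope, x$intercept, x$r_squared, x$n_anchors))
  invisible(x)
}

#' Predict absolute copy numbers from relative abundance
#'
#' `copies = 10^(slope * log10(iBAQ) + intercept)`; strictly increasing
#' in iBAQ when the calibration slope is positive. Sentinel-filled or
#' non-positive entries must be removed by the caller.
#'
#' @param model a [fit_anchor_calibration] result.
#' @param ibaq positive numeric vector of iBAQ values.
#' @return copies/cell vector, named like `ibaq`.
#' @export
predict_copy_numbers <- function(model, ibaq) {
  if (!inherits(model, "calibration_model"))
    pqc_stop("model must come from fit_anchor_calibration",
             "proteoqc_validation_error")
  if (any(ibaq <= 0 | is.na(ibaq)))
    pqc_stop("iBAQ values must be positive and non-missing",
             "proteoqc_validation_error")
  out <- 10^(model$slope * log10(ibaq) + model$intercept)
  names(out) <- names(ibaq)
  out
}

#' Copies per cell from a molar amount
#'
#' `copies/cell = moles * Avogadro / cells`. Exposed because the full
#' anchoring chain (reference peptide -> standard-protein molar amount
#' -> endogenous molar amount -> copies/cell) is assembled from it.
#'
#' @param amount_mol molar amount of protein in the preparation.
#' @param cells number of cells the preparation derives from.
#' @return copies per cell.
#' @export
copies_per_cell <- function(amount_mol, cells) {
  if (any(cells <= 0))
    pqc_stop("cell count must be > 0", "proteoqc_validation_error")
  amount_mol * AVOGADRO / cells
}
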