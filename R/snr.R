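## snr_metric: PCA-weighted signal-to-noise ratio ------------------------

#' Pair counts of a balanced m-groups x n-replicates design
#'
#' Number of between-group run pairs, `C(m,2) * n^2`, and within-group
#' replicate pairs, `m * C(n,2)`. These are the denominators that turn
#' the raw inter/intra squared-distance sums into averages; for the
#' 4 x 3 reference design they are 54 and 12.
#'
#' @param m number of biological groups (>= 2).
#' @param n replicates per group (>= 2).
#' @return named numeric vector `c(inter_pairs, intra_pairs)`.
#' @examples
#' pair_counts(4, 3)  # 54, 12
#' @export
pair_counts <- function(m, n) {
  if (m < 2 || n < 2)
    pqc_stop("SNR undefined: need m >= 2 groups and n >= 2 replicates",
             "proteoqc_design_error")
  c(inter_pairs = choose(m, 2) * n * n, intra_pairs = m * choose(n, 2))
}

#' Embed runs on the first two principal components
#'
#' Preprocessing before PCA: missing entries are filled with the `1e-5`
#' sentinel, values are log10-transformed, and each protein is centered
#' and scaled to unit variance across runs (making the embedding
#' scale-free); each step can be switched off. PCA is computed over runs
#' (runs = observations, proteins = variables); proteins with zero
#' variance across runs are dropped beforehand, since they carry no
#' geometry and break unit scaling.
#'
#' @param x a [quant_matrix] (FOT units expected under default options).
#' @param metadata a [run_metadata] covering the runs of `x`; optional
#'   when `group` is given.
#' @param group per-run group labels (in column order), overriding
#'   metadata.
#' @param log10_transform,center,scale. preprocessing switches.
#' @param renormalize_weights if `TRUE`, the two component weights are
#'   rescaled to sum to 1; by default they are the variance-explained
#'   fractions of the full decomposition.
#' @return object of class `snr_embedding`: `coordinates` (runs x 2),
#'   `weights` (length 2), `group_labels`, `replicate_indices`,
#'   `variance_explained` (all components).
#' @export
embed_pca <- function(x, metadata = NULL, group = NULL,
                      log10_transform = TRUE, center = TRUE,
                      scale. = TRUE, renormalize_weights = FALSE) {
  stopifnot(inherits(x, "quant_matrix"))
  if (ncol(x) < 3L)
    pqc_stop("PCA embedding needs >= 3 runs", "proteoqc_design_error")
  if (is.null(group)) {
    if (is.null(metadata))
      pqc_stop("supply metadata or per-run group labels",
               "proteoqc_validation_error")
    idx <- match(colnames(x), metadata$run_id)
    if (anyNA(idx)) check_pairing(x, metadata)  # raises detailed error
    group <- metadata$group_label[idx]
    repl <- metadata$replicate_index[idx]
  } else {
    repl <- stats::ave(seq_along(group), group, FUN = seq_along)
  }
  v <- unclass(x)
  v[is.na(v)] <- FOT_SENTINEL
  if (log10_transform) {
    if (any(v <= 0))
      pqc_stop("non-positive values; log10 preprocessing needs positive data",
               "proteoqc_validation_error")
    v <- log10(v)
  }
  keep <- apply(v, 1L, stats::var) > 0
  if (sum(keep) < 2L)
    pqc_stop("fewer than 2 proteins with non-zero variance across runs",
             "proteoqc_validation_error")
  v <- v[keep, , drop = FALSE]
  pc <- stats::prcomp(t(v), center = center, scale. = scale.)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  w <- ve[1:2]
  if (renormalize_weights) w <- w / sum(w)
  structure(list(coordinates = pc$x[, 1:2, drop = FALSE],
                 weights = w,
                 group_labels = as.character(group),
                 replicate_indices = repl,
                 variance_explained = ve),
            class = "snr_embedding")
}

#' Construct an embedding from explicit coordinates
#'
#' Mainly for worked examples and tests: wraps given two-component
#' coordinates, weights and group labels into an `snr_embedding`.
#'
#' @param coordinates numeric matrix (runs x 2) or vector (1-D designs).
#' @param weights length-2 non-negative component weights.
#' @param group per-run group labels.
#' @return an `snr_embedding`.
#' @export
snr_embedding <- function(coordinates, weights, group) {
  if (is.vector(coordinates)) coordinates <- cbind(coordinates, 0)
  coordinates <- as.matrix(coordinates)[, 1:2, drop = FALSE]
  stopifnot(length(weights) == 2L, all(weights >= 0),
            nrow(coordinates) == length(group), all(is.finite(coordinates)))
  structure(list(coordinates = coordinates, weights = as.numeric(weights),
                 group_labels = as.character(group),
                 replicate_indices =
                   stats::ave(seq_along(group), group, FUN = seq_along),
                 variance_explained = as.numeric(weights)),
            class = "snr_embedding")
}

#' Signal-to-noise ratio of a replicated multi-group embedding
#'
#' SNR (in decibels) is 10*log10 of the ratio between the average
#' weighted squared distance over all between-group run pairs (signal)
#' and the average weighted squared distance over all within-group
#' replicate pairs (noise), computed on the two retained principal
#' components. Requires a balanced design (equal replicates per group).
#' Identical replicates within every group give zero noise — reported as
#' a distinct degenerate-replicates error rather than `Inf`.
#'
#' @param embedding an `snr_embedding` (see [embed_pca]).
#' @return object of class `snr_result`: `snr_db`, `signal`, `noise`,
#'   `m`, `n`, `category` (see [classify_snr]).
#' @examples
#' e <- snr_embedding(c(0, 1, 10, 11), weights = c(1, 0),
#'                    group = c("A", "A", "B", "B"))
#' compute_snr(e)$snr_db  # 10*log10(100.5)
#' @export
compute_snr <- function(embedding) {
  stopifnot(inherits(embedding, "snr_embedding"))
  g <- embedding$group_labels
  sizes <- table(g)
  m <- length(sizes)
  if (m < 2L)
    pqc_stop("SNR needs >= 2 groups", "proteoqc_design_error")
  if (length(unique(as.integer(sizes))) != 1L)
    pqc_stop("unbalanced design: SNR requires equal replicates per group",
             "proteoqc_design_error")
  n <- as.integer(sizes[1])
  if (n < 2L)
    pqc_stop("SNR needs >= 2 replicates per group", "proteoqc_design_error")
  pc <- pair_counts(m, n)
  co <- embedding$coordinates
  w <- embedding$weights

  # weighted squared Euclidean distances between all run pairs
  sw <- sweep(co, 2L, sqrt(w), `*`)
  d2 <- as.matrix(stats::dist(sw))^2
  same <- outer(g, g, `==`)
  ut <- upper.tri(d2)
  signal_sum <- sum(d2[ut & !same])
  noise_sum <- sum(d2[ut & same])
  signal <- signal_sum / pc[["inter_pairs"]]
  noise <- noise_sum / pc[["intra_pairs"]]
  # zero up to floating fuzz: replicates coincide, SNR diverges
  if (noise == 0 || (signal > 0 && noise < signal * 1e-12))
    pqc_stop("degenerate replicates: zero intra-group distance (infinite SNR)",
             "proteoqc_degenerate_error")
  snr_db <- 10 * log10(signal / noise)
  structure(list(snr_db = snr_db, signal = unname(signal),
                 noise = unname(noise), m = m, n = n,
                 category = classify_snr(snr_db)),
            class = "snr_result")
}

#' @export
print.snr_result <- function(x, ...) {
  cat(sprintf("SNR: %.2f dB (%s) [m = %d groups, n = %d replicates]\n",
              x$snr_db, x$category, x$m, x$n))
  invisible(x)
}

#' Classify an SNR value into a performance category
#'
#' Bins are left-closed/right-open: `[0, 2)` ineligible, `[2, 10)`
#' average, `[10, 20)` good, `[20, Inf)` excellent; negative values are
#' ineligible.
#'
#' @param snr_db finite SNR in decibels (vectorized).
#' @return character vector of categories.
#' @examples
#' classify_snr(c(0.59, 17.74, 25.18))
#' @export
classify_snr <- function(snr_db) {
  if (any(!is.finite(snr_db)))
    pqc_stop("SNR must be finite for classification",
             "proteoqc_validation_error")
  as.character(cut(snr_db, c(-Inf, 2, 10, 20, Inf),
                   labels = c("ineligible", "average", "good", "excellent"),
                   right = FALSE))
}

#' Mean-minus-SD threshold over a collection of SNR values
#'
#' Summarizes a distribution of SNR scores (e.g., from many experiments)
#' as `mean - sd` (sample standard deviation), the convention used to
#' flag high discriminating power.
#'
#' @param snr_values numeric vector, length >= 2.
#' @return `mean(snr_values) - sd(snr_values)`.
#' @export
derive_snr_threshold <- function(snr_values) {
  if (length(snr_values) < 2L)
    pqc_stop("need >= 2 SNR values to derive a threshold",
             "proteoqc_validation_error")
  mean(snr_values) - stats::sd(snr_values)
}

#' SNR of a quantification matrix in one call
#'
#' Convenience wrapper: [embed_pca] then [compute_snr], optionally on a
#' subset of runs and/or proteins (e.g., one intensity tertile).
#'
#' @inheritParams embed_pca
#' @param runs optional run ids to subset.
#' @param proteins optional protein ids to subset.
#' @param ... passed to [embed_pca].
#' @return an `snr_result`.
#' @export
snr_from_matrix <- function(x, metadata, runs = NULL, proteins = NULL,
                            ...) {
  v <- unclass(x)
  if (!is.null(runs)) v <- v[, runs, drop = FALSE]
  if (!is.null(proteins))
    v <- v[intersect(rownames(v), proteins), , drop = FALSE]
  compute_snr(embed_pca(quant_matrix(v, quant_unit(x)), metadata, ...))
}
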