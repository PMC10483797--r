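# shared fixtures and independent oracles

# tiny quant matrix with named dims
qm <- function(values, nrow, unit = "FOT", proteins = NULL, runs = NULL) {
  m <- matrix(values, nrow = nrow)
  rownames(m) <- proteins %||% sprintf("P%d", seq_len(nrow(m)))
  colnames(m) <- runs %||% sprintf("r%d", seq_len(ncol(m)))
  quant_matrix(m, unit = unit)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# metadata for a balanced m x n single-experiment design whose run ids
# follow <exp>_<group>_r<rep>
balanced_meta <- function(groups, n, experiment_id = "E1") {
  df <- expand.grid(replicate_index = seq_len(n), group_label = groups,
                    stringsAsFactors = FALSE)
  df$experiment_id <- experiment_id
  df$run_id <- sprintf("%s_%s_r%d", experiment_id, df$group_label,
                       df$replicate_index)
  df$month <- 1L
  run_metadata(df)
}

# independent SNR oracle: explicit double loops over all pairs, no
# prefactor algebra; mirrors the metric's definition term by term
snr_bruteforce <- function(coords, weights, groups) {
  if (is.vector(coords)) coords <- cbind(coords, 0)
  glev <- unique(groups)
  m <- length(glev)
  idx <- lapply(glev, function(g) which(groups == g))
  inter <- c()
  for (x in seq_len(m - 1)) for (y in seq.int(x + 1, m)) {
    for (i in idx[[x]]) for (j in idx[[y]]) {
      inter <- c(inter, sum(weights * (coords[i, ] - coords[j, ])^2))
    }
  }
  intra <- c()
  for (x in seq_len(m)) {
    ii <- idx[[x]]
    for (a in seq_len(length(ii) - 1)) for (b in seq.int(a + 1, length(ii))) {
      intra <- c(intra, sum(weights * (coords[ii[a], ] - coords[ii[b], ])^2))
    }
  }
  10 * log10(mean(inter) / mean(intra))
}

# random balanced embedding for property tests
random_embedding <- function(m, n, spread = 5) {
  groups <- rep(LETTERS[seq_len(m)], each = n)
  centers <- matrix(runif(2 * m, -spread, spread), m, 2)
  coords <- centers[rep(seq_len(m), each = n), ] + matrix(rnorm(2 * m * n), m * n, 2)
  w <- runif(2); w <- w / sum(w)
  list(coords = coords, weights = w, groups = groups)
}

# closed-form OLS via normal equations (oracle for linearity fits)
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}
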