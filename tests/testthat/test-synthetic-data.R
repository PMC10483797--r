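test_that("invalid configurations are rejected", {
  expect_error(simulation_config(m_groups = 1), class = "proteoqc_config_error")
  expect_error(simulation_config(dep_fraction = 1.2),
               class = "proteoqc_config_error")
  expect_error(simulation_config(n_replicates = 1),
               class = "proteoqc_config_error")
  expect_error(simulation_config(dep_fc_range = c(1.5, 3)),
               class = "proteoqc_config_error")
})

test_that("zero-rate config plants no DEPs and no specific proteins", {
  cfg <- simulation_config(n_proteins = 200, dep_fraction = 0,
                           specific_fraction = 0, seed = 3)
  tr <- generate_ground_truth(cfg)
  expect_equal(nrow(tr$dep_flags), 0L)
  expect_true(all(lengths(tr$specific_proteins) == 0L))
  expect_true(all(tr$base_abundance > 0))
})

test_that("ground truth is deterministic given the seed", {
  cfg <- simulation_config(n_proteins = 300, seed = 7)
  expect_identical(generate_ground_truth(cfg), generate_ground_truth(cfg))
  sim1 <- simulate_experiment(cfg)
  sim2 <- simulate_experiment(cfg)
  expect_identical(unclass(sim1$matrix), unclass(sim2$matrix))
})

test_that("base abundances are lognormal over the configured span", {
  cfg <- simulation_config(n_proteins = 10000, dynamic_range_log10 = 7,
                           specific_fraction = 0, dep_fraction = 0,
                           seed = 21)
  tr <- generate_ground_truth(cfg)
  span <- log10(max(tr$base_abundance) / min(tr$base_abundance))
  expect_gte(span, 6.5)
  expect_lte(span, 7.5)
})

test_that("planted fold changes exceed the threshold and specific sets are disjoint", {
  cfg <- simulation_config(n_proteins = 1000, seed = 9)
  tr <- generate_ground_truth(cfg)
  expect_true(all(tr$dep_flags$fold_change > cfg$dep_threshold))
  all_spec <- unlist(tr$specific_proteins, use.names = FALSE)
  expect_equal(anyDuplicated(all_spec), 0L)
  # a specific protein is absent (zero abundance) outside its group
  for (g in names(tr$specific_proteins)) {
    ids <- tr$specific_proteins[[g]]
    other <- setdiff(colnames(tr$base_abundance), g)
    expect_true(all(tr$base_abundance[ids, other] == 0))
  }
})

test_that("noise-free fully-detected runs reproduce base abundance exactly", {
  cfg <- simulation_config(n_proteins = 100, specific_fraction = 0,
                           cv_profile = c(low = 0, medium = 0, high = 0),
                           drift_per_injection = 1, always_detect = TRUE,
                           seed = 4)
  tr <- generate_ground_truth(cfg)
  v <- simulate_run(tr, "D5", 1, config = cfg, seed = 99)
  expect_equal(unname(v), unname(tr$base_abundance[, "D5"]))
})

test_that("detection probability zero yields an all-missing run", {
  cfg <- simulation_config(n_proteins = 50, detection_midpoint = 1e9,
                           detection_slope = Inf, seed = 4)
  tr <- generate_ground_truth(cfg)
  v <- simulate_run(tr, "D5", 1, config = cfg, seed = 1)
  expect_true(all(is.na(v)))
})

test_that("unknown group raises a lookup error", {
  cfg <- simulation_config(n_proteins = 20, seed = 1)
  tr <- generate_ground_truth(cfg)
  expect_error(simulate_run(tr, "nope", 1, config = cfg, seed = 1),
               class = "proteoqc_lookup_error")
})

test_that("realized per-stratum CV matches the configured target", {
  cfg <- simulation_config(n_proteins = 5000, specific_fraction = 0,
                           dep_fraction = 0, always_detect = TRUE,
                           cv_profile = c(low = 0.8, medium = 0.4,
                                          high = 0.2), seed = 5)
  tr <- generate_ground_truth(cfg)
  draws <- sapply(1:100, function(i)
    simulate_run(tr, "D5", 1, config = cfg, seed = 1000 + i))
  for (s in c("low", "medium", "high")) {
    ids <- names(tr$stratum)[tr$stratum == s]
    cvs <- apply(draws[ids, ], 1, function(v) sd(v) / mean(v))
    target <- cfg$cv_profile[[s]]
    expect_gt(median(cvs), target * 0.9)
    expect_lt(median(cvs), target * 1.1)
  }
})

test_that("detection probability is monotone in base abundance", {
  cfg <- simulation_config(n_proteins = 100, seed = 2)
  tr <- generate_ground_truth(cfg)
  lg <- seq(0, 7, length.out = 50)
  p <- plogis(tr$detection_slope * (lg - tr$detection_midpoint))
  expect_true(all(diff(p) >= 0))
})

test_that("experiment assembly matches the design arithmetic", {
  cfg <- simulation_config(n_proteins = 60, seed = 13)
  sim <- simulate_experiment(cfg)
  expect_equal(ncol(sim$matrix), 12L)
  expect_identical(colnames(sim$matrix), sim$metadata$run_id)
  expect_setequal(sim$metadata$injection_index, 1:12)
})

test_that("CI2 mode places each group's replicates in consecutive slots", {
  cfg <- simulation_config(n_proteins = 40, injection_mode = "CI2",
                           seed = 8)
  sim <- simulate_experiment(cfg)
  md <- sim$metadata
  for (g in unique(md$group_label)) {
    slots <- sort(md$injection_index[md$group_label == g])
    expect_equal(diff(slots), rep(1L, length(slots) - 1L))
  }
})

test_that("CI1 mode cycles the groups within each replicate round", {
  cfg <- simulation_config(n_proteins = 40, injection_mode = "CI1",
                           seed = 8)
  md <- simulate_experiment(cfg)$metadata
  ord <- md$group_label[order(md$injection_index)]
  expect_equal(ord, rep(cfg$group_labels, times = cfg$n_replicates))
})

test_that("mean SNR over seeds orders injection modes CI2 >= CI1 > RI under drift", {
  snr <- sapply(1:10, function(s) {
    sapply(c("RI", "CI1", "CI2"), function(mode) {
      cfg <- simulation_config(n_proteins = 600, seed = 100 + s,
                               injection_mode = mode,
                               drift_per_injection = 1.05)
      sim <- simulate_experiment(cfg)
      snr_from_matrix(ibaq_to_fot(sim$matrix), sim$metadata)$snr_db
    })
  })
  means <- rowMeans(snr)
  expect_gte(means[["CI2"]], means[["CI1"]])
  expect_gt(means[["CI1"]], means[["RI"]])
})

test_that("dilution series: noiseless signals are exactly proportional", {
  s <- simulate_dilution_series("pep1", c(1, 1/2, 1/4), noise_cv = 0,
                                seed = 1)
  expect_equal(s$signal / s$signal[1], c(1, 1/2, 1/4))
  fit <- dilution_linearity(s)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("dilution series rejects designs with fewer than 3 points", {
  expect_error(simulate_dilution_series("p", c(1, 0.5), 0, 1),
               class = "proteoqc_config_error")
  expect_error(simulate_dilution_series("p", c(1, -1, 0.5), 0, 1),
               class = "proteoqc_config_error")
})

test_that("noisy dilution series recovers unit log-log slope across seeds", {
  factors <- 2^-(0:7)
  slopes <- sapply(1:100, function(s) {
    ser <- simulate_dilution_series("p", factors, noise_cv = 0.05,
                                    seed = s)
    dilution_linearity(ser)$slope
  })
  expect_true(all(slopes > 0.9 & slopes < 1.1))
})
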