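test_that("protein CV matches hand computation and scale invariance", {
  expect_equal(protein_cv(c(100, 100, 100)), 0)
  expect_equal(protein_cv(c(1, 2, 3)), 50)  # mean 2, sample SD 1
  v <- c(3.2, 5.8, 4.4, 9.1)
  expect_equal(protein_cv(v * 137), protein_cv(v))
  expect_true(is.na(protein_cv(c(5))))          # < 2 present values
  expect_true(is.na(protein_cv(c(5, NA, 1e-5))))  # sentinel not present
})

test_that("median CV per intensity group recovers the simulated ordering", {
  cfg <- simulation_config(n_proteins = 5000, specific_fraction = 0,
                           dep_fraction = 0, always_detect = TRUE,
                           cv_profile = c(low = 0.8, medium = 0.3,
                                          high = 0.15), seed = 31)
  sim <- simulate_experiment(cfg)
  fot <- ibaq_to_fot(sim$matrix)
  a <- assign_intensity_groups(fot, sim$metadata, "E1")
  runs <- sim$metadata$run_id[sim$metadata$group_label == "D5"]
  med <- median_cv_by_group(fot, assignment = a, runs = runs)
  m <- setNames(med$median_cv, med$group)
  expect_gt(m[["low"]], m[["medium"]])
  expect_gt(m[["medium"]], m[["high"]])
})

test_that("noise-free replicates give zero CV everywhere", {
  cfg <- simulation_config(n_proteins = 200, specific_fraction = 0,
                           cv_profile = c(low = 0, medium = 0, high = 0),
                           always_detect = TRUE, seed = 32)
  sim <- simulate_experiment(cfg)
  fot <- ibaq_to_fot(sim$matrix)
  a <- assign_intensity_groups(fot, sim$metadata, "E1")
  runs <- sim$metadata$run_id[sim$metadata$group_label == "F7"]
  med <- median_cv_by_group(fot, assignment = a, runs = runs)
  expect_true(all(abs(med$median_cv) < 1e-9))
})

test_that("identification frequency counts presence across replicates", {
  # P1 present in a,b; P2 in a only; P3 in all three
  x <- qm(c(1, 2, 3,  1, 1e-5, 4,  1e-5, 1e-5, 5), nrow = 3,
          unit = "FOT", runs = c("a", "b", "c"))
  idf <- identification_frequency(x, runs = c("a", "b", "c"))
  expect_equal(setNames(idf$idf, idf$protein_id),
               c(P1 = 2L, P2 = 1L, P3 = 3L))
})

test_that("occurrence bins partition observed proteins with an exact 100% bin", {
  set.seed(33)
  n_runs <- 110
  counts <- c(110, 55, 109, 3, 0, 71, 110, 11)
  v <- t(sapply(counts, function(k)
    c(rep(1, k), rep(NA, n_runs - k))[sample(n_runs)]))
  dimnames(v) <- list(sprintf("P%d", seq_along(counts)),
                      sprintf("r%d", 1:n_runs))
  ob <- occurrence_bins(quant_matrix(v, "FOT"))
  expect_equal(nrow(ob), sum(counts > 0))
  by_id <- setNames(as.character(ob$bin), ob$protein_id)
  expect_equal(by_id[["P1"]], "100%")
  expect_equal(by_id[["P7"]], "100%")
  expect_equal(by_id[["P2"]], "[50,60%)")   # 55/110 = 0.5
  expect_equal(by_id[["P3"]], "[90,100%)")  # 109/110
  expect_equal(by_id[["P4"]], "[0,10%)")
  expect_equal(by_id[["P8"]], "[10,20%)")   # 11/110 = 0.1
})

test_that("pairwise correlation has unit diagonal and affine invariance", {
  set.seed(34)
  v <- matrix(rlnorm(40, 2, 1), 20, 2,
              dimnames = list(sprintf("P%d", 1:20), c("a", "b")))
  v[, 2] <- v[, 1] * 2  # log-shift
  r <- pairwise_correlation(quant_matrix(v, "FOT"))
  expect_equal(diag(r), c(a = 1, b = 1))
  expect_equal(r["a", "b"], 1)
})

test_that("pairwise correlation matches a hand-computed Pearson r", {
  lv <- cbind(a = c(0, 1, 2, 3, 4), b = c(0.5, 0.8, 2.2, 2.9, 4.4))
  v <- 10^lv
  rownames(v) <- sprintf("P%d", 1:5)
  r <- pairwise_correlation(quant_matrix(v, "FOT"))
  a <- lv[, 1]; b <- lv[, 2]
  hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(r["a", "b"], hand, tolerance = 1e-12)
})

test_that("constant profiles yield NA correlation with a warning", {
  v <- matrix(c(1, 1, 1, 5, 6, 7), 3, 2,
              dimnames = list(sprintf("P%d", 1:3), c("a", "b")))
  expect_warning(r <- pairwise_correlation(quant_matrix(v, "FOT")),
                 "constant")
  expect_true(is.na(r["a", "b"]))
})

test_that("set overlap follows inclusion-exclusion on a 3-set fixture", {
  sets <- list(A = c("p1", "p2", "p3", "p4"),
               B = c("p3", "p4", "p5"),
               C = c("p4", "p6"))
  ov <- overlap_sets(sets, reference = "A")
  expect_equal(ov$intersection, "p4")
  expect_setequal(ov$union, paste0("p", 1:6))
  ps <- ov$per_set
  expect_equal(ps$specific[ps$set == "A"], 2L)  # p1, p2
  expect_equal(ps$overlap_with_reference_pct[ps$set == "B"], 50)
  # subset relation: overlap of a subset with its superset is 100%
  ov2 <- overlap_sets(list(big = c("x", "y", "z"), small = c("x", "y")),
                      reference = "small")
  expect_equal(
    ov2$per_set$overlap_with_reference_pct[ov2$per_set$set == "big"], 100)
  expect_equal(length(overlap_sets(list(A = "a", B = "b"))$intersection), 0L)
  expect_error(overlap_sets(list(A = "a")),
               class = "proteoqc_validation_error")
})

test_that("intensity flow rows sum to 100 and self-flow is the identity", {
  a <- data.frame(protein_id = sprintf("p%d", 1:9),
                  group = rep(c("low", "medium", "high"), each = 3),
                  basis_value = 1:9)
  flow <- intensity_flow(a, a)
  expect_equal(rowSums(flow), c(low = 100, medium = 100, high = 100))
  expect_equal(diag(flow[, 1:3]), c(low = 100, medium = 100, high = 100))

  # constructed 9-protein flow vs hand tally
  b <- a
  b$group <- c("low", "medium", "medium", "high", "high", "high",
               "high", "high", "high")
  b <- b[-9, ]  # p9 not detected in B
  flow2 <- intensity_flow(a, b)
  expect_equal(unname(flow2["low", ]), c(100/3, 200/3, 0, 0))
  expect_equal(unname(flow2["medium", ]), c(0, 0, 100, 0))
  expect_equal(unname(flow2["high", ]), c(0, 0, 200/3, 100/3))

  # degenerate: nothing detected downstream
  empty_b <- data.frame(protein_id = character(0), group = character(0),
                        basis_value = numeric(0))
  flow3 <- intensity_flow(a, empty_b)
  expect_true(all(flow3[, "not_detected"] == 100))
})

test_that("stability is exactly 1 at the reference month in every group", {
  cfg <- simulation_config(n_proteins = 400, months = 3, seed = 35)
  sim <- simulate_experiment(cfg)
  fot <- ibaq_to_fot(sim$matrix)
  st <- stability_series(fot, sim$metadata)
  ref <- st$reproducibility[st$reproducibility$month == st$reference_month, ]
  expect_true(all(ref$reproducibility == 1))
})

test_that("degradation starting at month 12 depresses later reproducibility", {
  cfg <- simulation_config(n_proteins = 800, months = 15, seed = 11,
                           degradation_fraction = 0.3,
                           degradation_rate = 1.0,
                           degradation_onset_month = 12L)
  sim <- simulate_experiment(cfg)
  fot <- ibaq_to_fot(sim$matrix)
  st <- stability_series(fot, sim$metadata)
  g <- st$reproducibility[st$reproducibility$group == "global", ]
  pre <- mean(g$reproducibility[g$month <= 12])
  post <- g$reproducibility[g$month > 12]
  expect_true(all(post < pre))
})

test_that("without degradation reproducibility only fluctuates by detection noise", {
  reps <- sapply(1:20, function(s) {
    cfg <- simulation_config(n_proteins = 300, months = 3, seed = 400 + s,
                             degradation_fraction = 0)
    sim <- simulate_experiment(cfg)
    fot <- ibaq_to_fot(sim$matrix)
    st <- stability_series(fot, sim$metadata)
    g <- st$reproducibility[st$reproducibility$group == "global", ]
    mean(g$reproducibility[g$month > 1])
  })
  expect_lt(abs(mean(reps) - 1), 0.05)
})

test_that("four-dimensional summary is ideal for a clean experiment", {
  cfg <- simulation_config(n_proteins = 150, specific_fraction = 0,
                           cv_profile = c(low = 0, medium = 0, high = 0),
                           always_detect = TRUE, seed = 36)
  sim <- simulate_experiment(cfg)
  fot <- ibaq_to_fot(sim$matrix)
  fd <- four_dim_summary(fot, sim$metadata, "E1")
  expect_equal(fd$reproducibility, 1)
  expect_equal(fd$mean_pearson_r, 1, tolerance = 1e-9)
  expect_equal(fd$median_cv, 0, tolerance = 1e-9)
  expect_equal(fd$n_proteins_identified, 150)
})

test_that("noisier experiments score lower r and higher CV", {
  mk <- function(cv) {
    cfg <- simulation_config(n_proteins = 400, specific_fraction = 0,
                             cv_profile = c(low = cv, medium = cv,
                                            high = cv),
                             always_detect = TRUE, seed = 37)
    sim <- simulate_experiment(cfg)
    four_dim_summary(ibaq_to_fot(sim$matrix), sim$metadata, "E1")
  }
  quiet <- mk(0.1); loud <- mk(0.6)
  expect_gt(quiet$mean_pearson_r, loud$mean_pearson_r)
  expect_lt(quiet$median_cv, loud$median_cv)
})

test_that("four-dim components match independently computed pieces", {
  v <- matrix(c(10, 12, 1e-5,
                200, 180, 190,
                1e-5, 1e-5, 5), 3, 3, byrow = TRUE,
              dimnames = list(sprintf("P%d", 1:3), c("a", "b", "c")))
  x <- quant_matrix(v, "FOT")
  fd <- four_dim_summary(x, runs = c("a", "b", "c"))
  expect_equal(fd$n_proteins_identified, mean(c(2, 2, 2)))
  expect_equal(fd$reproducibility, 1 / 3)  # only P2 in all runs
  cvs <- c(protein_cv(c(10, 12)), protein_cv(c(200, 180, 190)))
  expect_equal(fd$median_cv, median(cvs))
})
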