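test_that("local density reproduces the collinear worked example", {
  x <- matrix(c(0, 1, 2), ncol = 1)
  dens <- local_density(x, omega = 2)
  # middle: 2/(1+1) = 1; ends: 2/(1+4) = 0.4
  expect_equal(dens$rho, c(0.4, 1, 0.4))
  expect_equal(dens$omega, 2L)
})

test_that("omega follows round(r * P) and rho scales as 1/c^2", {
  set.seed(41)
  x <- matrix(rnorm(200), 100, 2)
  dens <- local_density(x, r = 0.15)
  expect_equal(dens$omega, 15L)
  expect_equal(local_density(x, r = 0.10)$omega, 10L)

  scaled <- local_density(3 * x, r = 0.15)
  expect_equal(scaled$rho, dens$rho / 9, tolerance = 1e-12)
  expect_true(all(dens$rho > 0))
  expect_error(local_density(x, r = 1.2), "in \\(0, 1\\)")
  expect_error(local_density(x[1:2, , drop = FALSE]), "3 subjects")
})

test_that("duplicate subjects receive the sentinel density", {
  x <- matrix(c(0, 0, 0, 5, 9), ncol = 1)
  dens <- local_density(x, omega = 2)
  # subjects 1-3 coincide: zero neighbor distances -> 10x the max finite rho
  expect_equal(dens$rho[4], 2 / 41)     # distances 4 and 5
  expect_equal(dens$rho[5], 2 / 97)     # distances 4 and 9
  expect_equal(dens$rho[1:3], rep(10 * 2 / 41, 3))
})

test_that("delta reproduces the worked example and the rarity default", {
  x <- matrix(c(0, 1, 2), ncol = 1)
  rho <- c(0.4, 1, 0.4)
  dd <- delta_distance(x, rho, gamma = 1)
  # middle point is the global density peak: delta = max distance = 1;
  # ends: nearest denser point is the middle, distance 1
  expect_equal(dd$delta, c(1, 1, 1))
  expect_equal(dd$psi_sets[[2]], integer(0))

  set.seed(6)
  big <- matrix(rnorm(718), 359, 2)
  expect_equal(delta_distance(big, runif(359))$gamma, 3L)
})

test_that("gamma = 1 reduces to the classical density-peak delta", {
  set.seed(19)
  x <- matrix(rnorm(120), 60, 2)
  rho <- local_density(x, r = 0.15)$rho
  dd <- delta_distance(x, rho, gamma = 1)
  expect_equal(dd$delta, classical_delta(x, rho), tolerance = 1e-12)
})

test_that("psi sets only contain strictly denser subjects", {
  set.seed(29)
  x <- matrix(rnorm(100), 50, 2)
  rho <- local_density(x)$rho
  dd <- delta_distance(x, rho, gamma = 3)
  for (i in seq_along(rho)) {
    expect_lte(length(dd$psi_sets[[i]]), 3L)
    if (length(dd$psi_sets[[i]]) > 0) {
      expect_true(all(rho[dd$psi_sets[[i]]] > rho[i]))
    }
  }
})

test_that("outlier flagging matches hand arithmetic and symmetry", {
  # the ESD convention flags the single huge value among five
  expect_equal(detect_anomalies(rep(1, 5), c(1, 1, 1, 1, 100),
                                critical = "esd"), 5L)
  # all ratios equal: nothing to flag under any convention
  for (crit in c("chebyshev", "esd", "chisq")) {
    expect_length(detect_anomalies(rep(2, 6), rep(3, 6), critical = crit), 0L)
  }
  # permutation symmetry of the flagged set
  set.seed(55)
  rho <- runif(40, 0.5, 1.5)
  delta <- c(runif(39, 0.5, 1.5), 60)
  fl <- detect_anomalies(rho, delta)
  perm <- sample.int(40)
  fl_p <- detect_anomalies(rho[perm], delta[perm])
  expect_equal(sort(perm[fl_p]), fl)
  expect_error(detect_anomalies(1:3, 1:2), "differ")
})

test_that("the distribution-free convention flags gross outliers only", {
  set.seed(61)
  ratios <- exp(rnorm(150, 0, 0.4))
  rho <- rep(1, 150)
  expect_length(detect_anomalies(rho, ratios), 0L)
  ratios[c(17, 90)] <- ratios[c(17, 90)] * 1e4
  expect_equal(detect_anomalies(rho, ratios), c(17L, 90L))
})

test_that("cohort features hold per-subject MFIs and percentages", {
  # hand-built pooled result: 2 subjects, 2 populations, 1 marker
  vals <- matrix(c(1, 2, 9, 5, 7, 4, 6, 8, 10, 12), ncol = 1)
  pooled <- list(
    pooled = flow_sample(vals, "CD3"),
    subject = c(rep("s1", 5), rep("s2", 5)),
    subject_ids = c("s1", "s2"),
    result = list(assignment = structure(
      list(final_labels = c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L, 2L),
           n_populations = 2L),
      class = "population_assignment"))
  )
  feats <- build_gdataset(pooled)
  expect_equal(dim(feats$features), c(2L, 4L))
  # s1 cluster 1: values {1,2,9} -> MFI 2; 3 of 5 cells -> 60 %
  expect_equal(unname(feats$features["s1", "pop1_CD3_mfi"]), 2)
  expect_equal(unname(feats$features["s1", "pop1_pct"]), 60)
  # s2 absent from cluster 1: pct 0, MFI imputed with pooled median {1,2,9}
  expect_equal(unname(feats$features["s2", "pop1_pct"]), 0)
  expect_equal(unname(feats$features["s2", "pop1_CD3_mfi"]), 2)
  # percentages sum to 100 per subject
  pct <- feats$features[, c("pop1_pct", "pop2_pct")]
  expect_equal(unname(rowSums(pct)), c(100, 100))
})

test_that("feature standardization is column-wise and safe on constants", {
  f <- structure(list(subject_ids = c("a", "b"),
                      features = cbind(c(0, 10), c(3, 3)),
                      n_populations = 1L, marker_names = "M1",
                      standardized = FALSE),
                 class = "cohort_features")
  z <- standardize_features(f)
  expect_true(z$standardized)
  expect_equal(z$features[, 1], -z$features[2:1, 1])
  expect_equal(unname(z$features[, 2]), c(0, 0))
  expect_lt(max(abs(colMeans(z$features))), 1e-9)
})

test_that("pooling concatenates, caps and validates panels", {
  coh <- gen_cohort(cohort_spec(n_subjects = 4L, n_anomalous = 0L,
                                cells_per_subject = 100L), seed = 2)
  pooled <- pool_and_cluster(coh$samples, seed = 2)
  expect_equal(n_cells(pooled$pooled), 400L)
  expect_equal(unname(table(pooled$subject)), rep(100L, 4L),
               ignore_attr = TRUE)

  capped <- pool_and_cluster(coh$samples[1:2], per_subject_cap = 50L, seed = 2)
  expect_equal(n_cells(capped$pooled), 100L)

  bad <- coh$samples
  bad[[2]] <- flow_sample(bad[[2]]$values, paste0("X", 1:5),
                          subject_id = "S002")
  expect_error(pool_and_cluster(bad, seed = 1), "S002")
  expect_error(pool_and_cluster(coh$samples[1]), "2 subjects")
})

test_that("the anomaly pipeline is deterministic given its seed", {
  coh <- gen_cohort(cohort_spec(n_subjects = 12L, n_anomalous = 1L,
                                cells_per_subject = 80L), seed = 5)
  r1 <- run_anomaly_pipeline(coh$samples, seed = 5, critical = "esd")
  r2 <- run_anomaly_pipeline(coh$samples, seed = 5, critical = "esd")
  expect_identical(r1$rho, r2$rho)
  expect_identical(r1$delta, r2$delta)
  expect_identical(r1$flagged, r2$flagged)
  expect_equal(r1$omega, max(1L, round(0.15 * 12)))
  expect_equal(r1$gamma, 1L)
})
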