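# Heterogeneity discovery: standardization moments, Ward linkage against a
# brute-force oracle, Beale's-index k selection, z-score importance,
# cluster CATEs and profiles, threshold sensitivity.

test_that("jitter-standardization yields exact moments and is seeded", {
  withr::with_seed(1, ites <- list(rnorm(500, -0.05, 0.1),
                                   runif(200), rep(c(-1, 1), 50)))
  for (x in ites) {
    z <- jitter_standardize(x, seed = 42)
    expect_lt(abs(mean(z$z_ite)), 1e-9)
    expect_lt(abs(gformulaHTE:::pop_sd(z$z_ite) - 0.1), 1e-9)
  }
  z1 <- jitter_standardize(ites[[1]], seed = 7)
  z2 <- jitter_standardize(ites[[1]], seed = 7)
  expect_identical(z1$z_ite, z2$z_ite)
  expect_false(identical(z1$z_ite,
                         jitter_standardize(ites[[1]], seed = 8)$z_ite))
})

test_that("standardization with zero noise matches the hand-computed
          population-SD scaling", {
  z <- jitter_standardize(c(-0.2, 0, 0.2), noise_sd = 0, seed = 1)
  expect_equal(z$z_ite, c(-0.1224744871, 0, 0.1224744871),
               tolerance = 1e-9)
  expect_error(jitter_standardize(rep(0.3, 10), noise_sd = 0, seed = 1),
               "constant")
})

test_that("Ward clustering recovers well-separated groups with
          non-decreasing merge heights", {
  withr::with_seed(2, x <- c(rnorm(50, -0.1, 0.005), rnorm(50, 0.1, 0.005)))
  sol <- ward_cluster(x)
  expect_true(all(diff(sol$heights) >= -1e-12))
  lab <- cut_labels(sol, 2)
  expect_equal(lab, rep(c(1L, 2L), each = 50))
  expect_error(ward_cluster(rnorm(5)), "n >= 10")
})

test_that("hclust Ward.D2 agrees with the brute-force centroid oracle", {
  for (s in 1:5) {
    withr::with_seed(s, x <- rnorm(12))
    sol <- ward_cluster(x)
    oracle <- naive_ward(x)
    expect_equal(sol$heights, oracle$heights, tolerance = 1e-10)
    for (k in 1:11) {
      # oracle partition after merge (12 - k) has k clusters
      got <- labels_to_partition(stats::cutree(sol$hclust, k = k))
      want <- canonical_partition(oracle$partitions[[12 - k]])
      expect_identical(got, want)
    }
  }
})

test_that("Beale's index finds the planted number of clusters", {
  withr::with_seed(3, {
    two <- c(rnorm(150, -1, 0.1), rnorm(150, 1, 0.1))
    three <- c(rnorm(100, -2, 0.1), rnorm(100, 0, 0.1), rnorm(100, 2, 0.1))
    one <- rnorm(300)
  })
  b2 <- beale_select_k(ward_cluster(two))
  expect_equal(b2$k, 2)
  expect_false(b2$no_significant_structure)
  b3 <- beale_select_k(ward_cluster(three))
  expect_equal(b3$k, 3)
  b1 <- beale_select_k(ward_cluster(one))
  expect_equal(b1$k, 2)
  expect_true(b1$no_significant_structure)
  # the path reports every evaluated split with finite F where defined
  expect_equal(b2$beale_path$from_k, 1:9)
  expect_true(all(b2$beale_path$significant %in% c(TRUE, FALSE)))
})

test_that("covariate importance matches the z-score arithmetic and flags
          zero-variance variables", {
  sch <- covariate_schema(c("v", "flat"), c("continuous", "continuous"))
  d <- data.frame(v = c(1, 1, 1, 2, 2, 2), flat = rep(5, 6))
  labels <- c(1, 1, 1, 2, 2, 2)
  imp <- covariate_importance(d, labels, sch, thresholds = c(0.25))
  row_v <- imp[imp$variable == "v", ]
  expect_equal(row_v$z_cluster1, -1)
  expect_equal(row_v$z_cluster2, 1)
  expect_equal(row_v$importance, 2)
  expect_equal(imp$importance[imp$variable == "flat"], 0)
})

test_that("importance selection is monotone across thresholds", {
  cfg <- recovery_config(n_total = 600, seed = 5)
  sim <- generate_cohort(cfg)
  labels <- as.integer(sim$oracle$true_ite <
                         median(sim$oracle$true_ite)) + 1L
  imp <- covariate_importance(sim$cohort, labels)
  sel <- sensitivity_thresholds(imp)
  expect_true(all(sel[["0.30"]] %in% sel[["0.25"]]))
  expect_true(all(sel[["0.25"]] %in% sel[["0.20"]]))
  expect_true(all(imp$importance >= 0))
  # selection flags in the table agree with the sets
  expect_setequal(imp$variable[imp$`selected_0.25`], sel[["0.25"]])
})

test_that("cluster CATEs respect their algebraic identities", {
  withr::with_seed(6, {
    p0 <- runif(400, 0.1, 0.6)
    p1 <- pmin(pmax(p0 + rnorm(400, -0.1, 0.1), 0.01), 0.99)
  })
  cf <- structure(list(p1 = p1, p0 = p0, outcome_kind = "binary"),
                  class = "counterfactual_predictions")
  ite <- compute_ite(cf)
  # all persons in one cluster: CATE = ATE
  one <- cluster_cate(ite, cf, rep(1L, 400), n_boot = 50, seed = 1)
  expect_equal(one$CATE, mean(ite$ite))
  # split on the sign of the ITE
  lab <- ifelse(ite$ite < 0, 1L, 2L)
  two <- cluster_cate(ite, cf, lab, n_boot = 50, seed = 1)
  expect_lt(two$CATE[1], 0)
  expect_gt(two$CATE[2], 0)
  # size-weighted CATE mean equals the ATE to machine precision
  expect_equal(sum(two$CATE * two$n) / sum(two$n), mean(ite$ite))
  # small clusters are flagged unstable
  lab_small <- c(rep(1L, 395), rep(2L, 5))
  small <- cluster_cate(ite, cf, lab_small, n_boot = 20, seed = 1)
  expect_true(small$unstable[small$cluster == 2])
  expect_false(small$unstable[small$cluster == 1])
})

test_that("cluster profiles order columns by importance and tag the
          high-benefit cluster", {
  cfg <- recovery_config(n_total = 800, seed = 8)
  sim <- generate_cohort(cfg)
  ite_true <- sim$oracle$true_ite
  cf <- structure(list(p1 = sim$oracle$risk1, p0 = sim$oracle$risk0,
                       outcome_kind = "binary"),
                  class = "counterfactual_predictions")
  ite <- compute_ite(cf)
  z <- jitter_standardize(ite, seed = 8)
  sol <- ward_cluster(z)
  lab <- cut_labels(sol, 2)
  imp <- covariate_importance(sim$cohort, lab)
  cate <- cluster_cate(ite, cf, lab, n_boot = 50, seed = 8)
  prof <- cluster_profile(sim$cohort, lab, imp, cate)
  sel <- imp$variable[imp$importance > 0.25]
  expect_equal(setdiff(names(prof),
                       c("cluster", "n", "CATE", "high_benefit")), sel)
  expect_equal(prof$high_benefit, prof$CATE == min(prof$CATE))
  # the planted modifier differs between clusters in the planted direction:
  # intenders concentrate in the high-benefit cluster
  hb <- which(prof$high_benefit)
  expect_gt(prof[hb, "intention"], prof[-hb, "intention"])
})

test_that("secondary continuous outcomes run through the same stages", {
  cfg <- recovery_config(n_total = 500, seed = 9)
  sim <- generate_cohort(cfg)
  X <- build_design(sim$cohort, default_schema())
  eff <- estimate_effects(X, sim$cohort$delta_sbp, library = glm_library(),
                          V = 4, n_boot = 20, seed = 9, fast_boot = TRUE,
                          loss = "gaussian")
  expect_equal(eff$ATE$scale, "mean difference")
  expect_null(eff$RR)
  expect_lt(eff$ATE$point, 0)        # program lowers follow-up SBP on average
  z <- jitter_standardize(eff$ite, seed = 9)
  sol <- ward_cluster(z)
  lab <- cut_labels(sol, 2)
  cate <- cluster_cate(eff$ite, eff$cf, lab, n_boot = 20, seed = 9)
  expect_equal(sum(cate$CATE * cate$n) / sum(cate$n), eff$ATE$point)
  expect_true(all(is.na(cate$RR)))
})
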