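# G-formula: counterfactual predictions, ITE algebra, bootstrap effect
# estimates, NNT / E-value transforms, positivity diagnostic, baseline table.

test_that("counterfactual predictions ignore the observed treatment value
          and respect a treatment-blind model", {
  withr::with_seed(1, {
    x <- rnorm(200)
    a <- rbinom(200, 1, 0.5)
    y <- rbinom(200, 1, plogis(x))      # treatment has no effect
  })
  X <- cbind(x = x, treatment = a)
  m <- cv_stack(X, y, list(learner_spec("glm", "glm", interactions = FALSE)),
                V = 5, seed = 1)
  # zero out the fitted treatment coefficient by hand-constructed model:
  # a model that ignores A entirely must give p1 == p0
  cf <- counterfactual_predict(m, X)
  fit0 <- glm(y ~ x, family = binomial)
  expect_equal(cor(cf$p1, fitted(fit0)), 1, tolerance = 0.05)
  # constant learner: p1 = p0 = c
  m$weights <- c(const = 1)
  m$cv_risks <- c(const = 0.2)
  m$fits <- list(const = list(predict = function(X) rep(0.3, nrow(X))))
  cf2 <- counterfactual_predict(m, X)
  expect_equal(cf2$p1, rep(0.3, 200))
  expect_equal(cf2$p0, rep(0.3, 200))
})

test_that("a saturated logistic model reproduces 2x2 cell proportions", {
  # printed toy table: treated 30/100 events, control 10/100 events
  a <- rep(c(1, 0), each = 100)
  y <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  X <- cbind(treatment = a)
  m <- cv_stack(X, y, list(learner_spec("glm", "glm", interactions = FALSE)),
                V = 5, seed = 2)
  cf <- counterfactual_predict(m, X)
  expect_equal(unique(round(cf$p1, 10)), 0.30, tolerance = 1e-6)
  expect_equal(unique(round(cf$p0, 10)), 0.10, tolerance = 1e-6)
})

test_that("ITE is the elementwise difference of counterfactual predictions", {
  cf <- structure(list(p1 = c(0.2, 0.5, 0.4), p0 = c(0.3, 0.5, 0.1),
                       outcome_kind = "binary"),
                  class = "counterfactual_predictions")
  ite <- compute_ite(cf)
  expect_equal(ite$ite, c(-0.1, 0, 0.3))
  expect_equal(mean(ite$ite), mean(cf$p1) - mean(cf$p0))
})

test_that("plug-in ATE recovers the oracle effect on a large cohort", {
  cfg <- generation_config(n_total = 20000, seed = 31,
                           treatment_main_effect = -0.3,
                           interaction_coefs = numeric(0))
  sim <- generate_cohort(cfg)
  X <- build_design(sim$cohort, default_schema())
  eff <- estimate_effects(X, sim$cohort$y_uncontrolled,
                          library = glm_library(), V = 2, n_boot = 1,
                          seed = 31, fast_boot = TRUE)
  expect_lt(abs(eff$ATE$point - attr(sim$oracle, "true_ate")), 0.015)
  # algebraic identities: mean(ITE) = ATE, RR = mean(p1)/mean(p0)
  expect_equal(eff$ATE$point, mean(eff$ite$ite))
  expect_equal(eff$RR$point, mean(eff$cf$p1) / mean(eff$cf$p0))
})

test_that("ATE confidence intervals cover zero under a null effect", {
  covered <- vapply(1:50, function(s) {
    cfg <- generation_config(n_total = 2000, seed = 1000 + s,
                             treatment_main_effect = 0,
                             interaction_coefs = numeric(0),
                             treated_fraction = 0.3)
    sim <- generate_cohort(cfg)
    X <- build_design(sim$cohort, default_schema())
    eff <- estimate_effects(
      X, sim$cohort$y_uncontrolled,
      library = list(learner_spec("glm_main", "glm", interactions = FALSE)),
      V = 2, n_boot = 200, seed = s)
    eff$ATE$ci_low <= 0 && 0 <= eff$ATE$ci_high
  }, TRUE)
  expect_gte(mean(covered), 0.90)
})

test_that("degenerate effect inputs behave: equal predictions, zero RD", {
  # p1 == p0 exactly -> ATE 0, RR 1
  cf <- structure(list(p1 = rep(0.25, 50), p0 = rep(0.25, 50),
                       outcome_kind = "binary"),
                  class = "counterfactual_predictions")
  ite <- compute_ite(cf)
  expect_equal(mean(ite$ite), 0)
  expect_equal(mean(cf$p1) / mean(cf$p0), 1)
})

test_that("NNT is the reciprocal absolute risk difference", {
  expect_equal(round(nnt_from_rd(0.052), 1), 19.2)
  expect_equal(round(nnt_from_rd(0.044), 1), 22.7)
  expect_equal(round(nnt_from_rd(-0.17), 1), 5.9)
  expect_equal(round(nnt_from_rd(0.15), 1), 6.7)
  expect_equal(nnt_from_rd(1.0), 1.0)
  expect_error(nnt_from_rd(0), "undefined")
  # exact reciprocal identity
  for (rd in c(-0.3, -0.052, 0.01, 0.8)) {
    expect_equal(nnt_from_rd(rd) * abs(rd), 1)
  }
})

test_that("E-values match the published transforms and are symmetric", {
  expect_equal(round(evalue_rr(0.81), 2), 1.77)
  expect_equal(round(evalue_rr(0.41), 2), 4.31)
  expect_equal(round(evalue_rr(1.35), 2), 2.04)
  expect_equal(evalue_rr(1.0), 1.0)
  expect_error(evalue_rr(0), "rr must be")
  expect_error(evalue_rr(-2), "rr must be")
  # symmetry property over a grid
  withr::with_seed(3, rr <- exp(runif(50, -3, 3)))
  expect_equal(evalue_rr(rr), evalue_rr(1 / rr), tolerance = 1e-12)
})

test_that("propensity overlap concentrates near the assignment rate and
          flags separation", {
  withr::with_seed(4, {
    X <- cbind(x1 = rnorm(2000), x2 = rnorm(2000))
    A <- rbinom(2000, 1, 0.3)
  })
  ov <- propensity_overlap(X, A, V = 5, seed = 4)
  expect_lt(abs(ov$summary["treated", "mean"] - 0.3), 0.05)
  expect_lt(abs(ov$summary["control", "mean"] - 0.3), 0.05)
  expect_false(ov$separation)
  expect_true(all(ov$overlap_interval >= 0 & ov$overlap_interval <= 1))
  # perfectly separable assignment
  withr::with_seed(5, x <- rnorm(300))
  ov2 <- propensity_overlap(cbind(x = x), as.numeric(x > 0), V = 5, seed = 5)
  expect_true(ov2$separation)
})

test_that("baseline table reproduces printed-table conventions", {
  # a published 2x2 split: male 1,767/99 vs female 1,198/28 (n 2,965/127)
  sch <- covariate_schema("sex_male", "binary")
  d <- data.frame(
    sex_male = c(rep(1, 1767), rep(0, 1198), rep(1, 99), rep(0, 28)),
    treatment = c(rep(0, 2965), rep(1, 127)))
  tab <- baseline_table(d, sch)
  male_row <- tab[tab$covariate == "sex_male" & tab$level == "1", ]
  expect_equal(male_row$control, "1,767 (60)")
  expect_equal(male_row$treated, "99 (78)")
  expect_equal(male_row$p_value, "<0.01")
  # missing counts match the mask
  d2 <- d
  d2$sex_male[1:19] <- NA
  tab2 <- baseline_table(d2, sch)
  miss_row <- tab2[tab2$level == "Missing", ]
  expect_match(miss_row$control, "^19 ")
  # identical arms produce no spurious small p-values
  d3 <- data.frame(sex_male = rep(c(0, 1), 200),
                   treatment = rep(c(0, 1), each = 200))
  tab3 <- baseline_table(d3, sch)
  expect_equal(tab3$p_value[tab3$level == "1"], "1.00")
})
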