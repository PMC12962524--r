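# Synthetic-cohort generator: schema contract, outcome definition,
# determinism, confounding calibration, planted heterogeneity, missingness
# mechanisms and eligibility filtering.

test_that("default schema lists the checkup covariates with valid kinds", {
  s <- default_schema()
  expect_s3_class(s, "covariate_schema")
  expect_false(anyDuplicated(s$name) > 0)
  expect_true(all(s$kind %in% c("binary", "categorical", "continuous")))
  expect_equal(s$kind[s$name == "age"], "continuous")
  expect_setequal(s$levels[[which(s$name == "drinking")]],
                  c("everyday", "sometimes", "rare_never"))
  expect_setequal(s$levels[[which(s$name == "eating_speed")]],
                  c("fast", "normal", "slow"))
  # one column per measured baseline variable
  expect_true(all(c("sex_male", "dx_hypertension", "dx_diabetes",
                    "dx_dyslipidemia", "smoking", "intention", "sbp_baseline",
                    "dbp_baseline", "hba1c", "cci", "days_since_checkup")
                  %in% s$name))
  cat_idx <- s$kind == "categorical"
  expect_true(all(vapply(s$levels[cat_idx], length, 1L) >= 2))
})

test_that("schema JSON round-trips", {
  s <- default_schema()
  path <- withr::local_tempfile(fileext = ".json")
  write_schema_json(s, path)
  s2 <- read_schema_json(path)
  expect_equal(s2$name, s$name)
  expect_equal(s2$kind, s$kind)
  expect_equal(s2$levels, s$levels)
})

test_that("uncontrolled hypertension follows the 140/90 thresholds", {
  expect_equal(compute_outcomes(139, 89), 0L)
  expect_equal(compute_outcomes(140, 80), 1L)
  expect_equal(compute_outcomes(120, 95), 1L)
  expect_equal(compute_outcomes(c(139, 140, 120), c(89, 80, 95)),
               c(0L, 1L, 1L))
  expect_error(compute_outcomes(-5, 80), "non-negative")
  expect_error(compute_outcomes(NA_real_, 80), "finite")
})

test_that("generated cohorts satisfy their invariants and are seeded", {
  cfg <- generation_config(n_total = 800, seed = 11)
  sim <- generate_cohort(cfg)
  expect_equal(nrow(sim$cohort), 800)
  expect_true(all(sim$cohort$treatment %in% 0:1))
  expect_equal(sim$cohort$y_uncontrolled,
               compute_outcomes(sim$cohort$sbp_fu, sim$cohort$dbp_fu))
  expect_equal(attr(sim$oracle, "true_ate"), mean(sim$oracle$true_ite))
  expect_true(all(sim$cohort$followup_days >= 275 &
                    sim$cohort$followup_days <= 455))
  # determinism
  sim2 <- generate_cohort(cfg)
  expect_identical(sim$cohort, sim2$cohort)
  sim3 <- generate_cohort(generation_config(n_total = 800, seed = 12))
  expect_false(identical(sim$cohort$sbp_fu, sim3$cohort$sbp_fu))
  expect_error(generate_cohort(generation_config(n_total = 800, seed = 1,
                                                 outcome_coefs = c(nope = 1))),
               "unknown covariate")
})

test_that("treated fraction is calibrated to the emulated cohort", {
  sim <- generate_cohort(generation_config(n_total = 3092, seed = 3))
  p <- 127 / 3092
  se <- sqrt(p * (1 - p) / 3092)
  expect_lt(abs(mean(sim$cohort$treatment) - p), 3 * se)
  expect_equal(mean(sim$propensity), p, tolerance = 1e-6)
})

test_that("zero interactions give a homogeneous effect; planted modifier
          shifts the oracle ITEs in its own direction", {
  hom <- generate_cohort(generation_config(
    n_total = 500, seed = 5, interaction_coefs = numeric(0),
    outcome_coefs = c("(Intercept)" = -1)))
  expect_lt(max(abs(hom$oracle$true_ite - attr(hom$oracle, "true_ate"))),
            1e-12)
  het <- generate_cohort(generation_config(
    n_total = 4000, seed = 5, interaction_coefs = c(intention = -0.8)))
  m <- tapply(het$oracle$true_ite, het$cohort$intention, mean)
  expect_lt(m[["1"]], m[["0"]])
})

test_that("crude risk difference converges to the true ATE without
          confounding or heterogeneity", {
  cfg <- generation_config(
    n_total = 50000, seed = 21, treated_fraction = 0.5,
    propensity_coefs = c("(Intercept)" = 0),
    interaction_coefs = numeric(0), missing_rates = numeric(0))
  sim <- generate_cohort(cfg)
  y <- sim$cohort$y_uncontrolled
  a <- sim$cohort$treatment
  crude <- mean(y[a == 1]) - mean(y[a == 0])
  se <- sqrt(var(y[a == 1]) / sum(a == 1) + var(y[a == 0]) / sum(a == 0))
  expect_lt(abs(crude - attr(sim$oracle, "true_ate")), 3 * se)
})

test_that("MCAR masking hits its target rate; MAR masking rises with age", {
  cfg <- generation_config(n_total = 3092, seed = 9,
                           missing_rates = c(smoking = 0.04),
                           missing_mechanism = "MCAR")
  sim <- generate_cohort(cfg)
  masked <- impose_missingness(sim$cohort, cfg)
  n_na <- sum(is.na(masked$smoking))
  expect_lt(abs(n_na - 3092 * 0.04), 3 * sqrt(3092 * 0.04 * 0.96))
  expect_false(anyNA(masked$treatment))
  expect_false(anyNA(masked$y_uncontrolled))

  cfg_mar <- generation_config(n_total = 6000, seed = 9,
                               missing_rates = c(smoking = 0.10),
                               missing_mechanism = "MAR")
  sim2 <- generate_cohort(cfg_mar)
  masked2 <- impose_missingness(sim2$cohort, cfg_mar)
  tert <- cut(sim2$cohort$age,
              quantile(sim2$cohort$age, c(0, 1 / 3, 2 / 3, 1)),
              include.lowest = TRUE, labels = c("lo", "mid", "hi"))
  rates <- tapply(is.na(masked2$smoking), tert, mean)
  expect_lt(rates[["lo"]], rates[["hi"]])

  cfg0 <- generation_config(n_total = 500, seed = 2,
                            missing_rates = c(smoking = 0))
  sim0 <- generate_cohort(cfg0)
  expect_identical(impose_missingness(sim0$cohort, cfg0), sim0$cohort)
})

test_that("eligibility keeps the 275-455 day window inclusively", {
  tab <- data.frame(id = 1:4, followup_days = c(200, 275, 455, 500))
  kept <- apply_eligibility(tab, 275, 455)
  expect_equal(kept$followup_days, c(275, 455))
  expect_equal(kept$id, c(2L, 3L))
  inside <- data.frame(id = 1:3, followup_days = c(300, 400, 455))
  expect_identical(apply_eligibility(inside, 275, 455), inside)
  none <- apply_eligibility(tab, 990, 999)
  expect_equal(nrow(none), 0)
  expect_error(apply_eligibility(tab, 455, 275), "min_days")
})

test_that("cohort CSV round-trips with empty missing cells", {
  cfg <- generation_config(n_total = 200, seed = 4)
  sim <- generate_cohort(cfg)
  masked <- impose_missingness(sim$cohort, cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(masked, path)
  back <- read_cohort_csv(path)
  expect_equal(back$drinking, masked$drinking)
  expect_equal(back$sbp_fu, masked$sbp_fu, tolerance = 1e-8)
  expect_equal(sum(is.na(back)), sum(is.na(masked)))
})
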