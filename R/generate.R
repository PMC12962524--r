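# Synthetic-cohort generator.
#
# Emulates the structure of the checkup/claims cohort the analysis assumes:
# a mostly-untreated observational cohort (treated fraction ~ 127/3,092),
# confounded treatment assignment on the logit scale, a logistic model for
# the binary outcome (uncontrolled hypertension at follow-up) with planted
# treatment-by-covariate interactions as ground-truth effect modifiers, and
# follow-up blood pressures drawn consistently with the binary outcome so
# that y_uncontrolled == (sbp_fu >= 140 | dbp_fu >= 90) holds exactly.
# Ground-truth per-person risk differences are returned alongside the data.

# Marginal distributions for the default schema, matching the control-arm
# summaries of the emulated cohort's baseline table. Continuous covariates
# are Gaussian, clamped to physiologic ranges; a latent "metabolic health"
# factor induces correlation among BMI, triglycerides, HbA1c and the liver
# enzymes, and baseline SBP/DBP share a common component. Smoking prevalence
# depends on intention to improve lifestyle habits (health-conscious people
# smoke less), giving the importance ranking a realistic correlated backdrop.
default_marginals <- function() {
  list(
    sex_male = list(p = 0.60),
    dx_hypertension = list(p = 0.69),
    dx_diabetes = list(p = 0.39),
    dx_dyslipidemia = list(p = 0.64),
    smoking = list(p_by_intention = c(yes = 0.15, no = 0.45)),
    drinking = list(probs = c(0.2474, 0.2990, 0.4536)),
    weight_change = list(p = 0.554),
    intention = list(p = 0.838),
    exercise_sweat = list(p = 0.213),
    walking = list(p = 0.477),
    eating_speed = list(probs = c(0.4073, 0.5360, 0.0567)),
    late_dinner = list(p = 0.391),
    skip_breakfast = list(p = 0.21),
    sleep_rest = list(p = 0.603),
    age = list(mean = 50.7, sd = 8.2, lower = 25, upper = 75),
    bmi = list(mean = 25.7, sd = 4.9, lower = 15, upper = 60, load = 0.45),
    triglycerides = list(mean = 127.3, sd = 96.1, lower = 30, upper = 1000,
                         load = 0.40),
    hdl = list(mean = 60.8, sd = 17.4, lower = 20, upper = 150, load = -0.25),
    ldl = list(mean = 122.0, sd = 32.7, lower = 30, upper = 300),
    dbp_baseline = list(mean = 81.2, sd = 12.5, lower = 40, upper = 140),
    sbp_baseline = list(mean = 128.9, sd = 17.8, lower = 80, upper = 220),
    got = list(mean = 26.7, sd = 14.6, lower = 5, upper = 300, load = 0.50),
    gpt = list(mean = 32.7, sd = 26.1, lower = 5, upper = 300, load = 0.55),
    ggtp = list(mean = 49.8, sd = 72.5, lower = 5, upper = 800, load = 0.50),
    hba1c = list(mean = 6.0, sd = 1.1, lower = 4, upper = 14, load = 0.45),
    cci = list(mean = 1.5, sd = 1.7, lower = 0, upper = 12),
    days_since_checkup = list(mean = -203.2, sd = 108.0,
                              lower = -455, upper = -1)
  )
}

#' Configuration of the synthetic-cohort generator
#'
#' Defaults encode the emulated study's conditions: a cohort of 3,092 with a
#' treated fraction calibrated to 127/3,092, confounding of assignment by
#' sex, diabetes, metabolic markers and intention to improve lifestyle
#' habits, a protective average program effect, and exactly two planted
#' effect modifiers (intention to improve lifestyle habits, smoking status)
#' on the logit scale. Coefficients for continuous covariates apply to the
#' standardized (marginal mean/SD) scale; categorical covariates are
#' referenced by indicator name, e.g. `"drinking=sometimes"`.
#'
#' @param n_total Cohort size (>= 2).
#' @param propensity_coefs Named numeric, logit-scale assignment
#'   coefficients; an `"(Intercept)"` entry is used only when
#'   `treated_fraction` is `NULL`.
#' @param treated_fraction If non-`NULL`, the propensity intercept is
#'   calibrated per cohort so the mean assignment probability equals it.
#' @param outcome_coefs Named numeric, logit-scale coefficients of the
#'   outcome (uncontrolled hypertension) model, including `"(Intercept)"`.
#' @param treatment_main_effect Logit-scale main effect of treatment.
#' @param interaction_coefs Named numeric: planted treatment-by-covariate
#'   interactions (the ground-truth effect modifiers).
#' @param missing_rates Named numeric in `[0,1]`: target missingness per
#'   covariate.
#' @param missing_mechanism `"MCAR"` or `"MAR"` (MAR depends on observed age
#'   and sex).
#' @param followup_days_range Integer `(min, max)` follow-up window in days.
#' @param bp_effect_scale mmHg of follow-up SBP/DBP shift per logit of
#'   treatment effect, `(sbp, dbp)`; links the continuous secondary outcomes
#'   to the same heterogeneity structure.
#' @param seed Integer master seed for the generator.
#' @return A list of class `generation_config`.
#' @export
generation_config <- function(
    n_total = 3092,
    propensity_coefs = c(
      "(Intercept)" = -3.2, sex_male = 0.45, dx_diabetes = 0.55,
      intention = 0.50, weight_change = 0.25, age = 0.25, bmi = 0.20,
      triglycerides = 0.20, hdl = -0.25, gpt = 0.20, ggtp = 0.15,
      hba1c = 0.35, cci = 0.30),
    treated_fraction = 127 / 3092,
    outcome_coefs = c(
      "(Intercept)" = -1.2, sbp_baseline = 0.45, dbp_baseline = 0.25,
      age = 0.08, bmi = 0.10, smoking = 0.15, hba1c = 0.08, cci = 0.08,
      ggtp = 0.08, intention = -0.08),
    treatment_main_effect = 0.6,
    interaction_coefs = c(intention = -2.2, smoking = 0.3),
    missing_rates = c(
      smoking = 0.006, drinking = 0.034, weight_change = 0.036,
      intention = 0.040, exercise_sweat = 0.035, walking = 0.036,
      eating_speed = 0.038, late_dinner = 0.037, skip_breakfast = 0.039,
      sleep_rest = 0.038),
    missing_mechanism = c("MAR", "MCAR"),
    followup_days_range = c(275L, 455L),
    bp_effect_scale = c(sbp = 6, dbp = 7),
    seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  if (!is.numeric(n_total) || n_total < 2) stop("n_total must be >= 2")
  if (any(missing_rates < 0 | missing_rates > 1)) {
    stop("missing_rates must lie in [0, 1]")
  }
  if (!is.null(treated_fraction) &&
      (treated_fraction <= 0 || treated_fraction >= 1)) {
    stop("treated_fraction must lie in (0, 1)")
  }
  if (followup_days_range[1] > followup_days_range[2]) {
    stop("followup_days_range must satisfy min <= max")
  }
  structure(list(
    n_total = as.integer(n_total),
    propensity_coefs = propensity_coefs,
    treated_fraction = treated_fraction,
    outcome_coefs = outcome_coefs,
    treatment_main_effect = treatment_main_effect,
    interaction_coefs = interaction_coefs,
    missing_rates = missing_rates,
    missing_mechanism = missing_mechanism,
    followup_days_range = as.integer(followup_days_range),
    bp_effect_scale = bp_effect_scale,
    seed = as.integer(seed)
  ), class = "generation_config")
}

#' Validation configuration: the emulated trial with randomized assignment
#'
#' Identical data-generating process to [generation_config()] (same
#' covariates, outcome model and the two planted effect modifiers) but with
#' treatment assigned at random to half the cohort, i.e. the target
#' randomized trial itself rather than its observational emulation. This is
#' the scenario used to validate the heterogeneity-discovery machinery:
#' with a 4% treated fraction the outcome model's treated-arm information is
#' the bottleneck, which is a property of the estimation problem, not of the
#' clustering / importance procedure under test.
#'
#' @param n_total Cohort size (default 5000).
#' @param seed Integer seed.
#' @return A [generation_config()].
#' @export
recovery_config <- function(n_total = 5000, seed = 1L) {
  generation_config(n_total = n_total, seed = seed,
                    propensity_coefs = c("(Intercept)" = 0),
                    treated_fraction = 0.5,
                    missing_rates = numeric(0))
}

# Draw baseline covariates per the marginals; returns a data.frame in the
# schema's column order. Custom schemas without declared marginals fall back
# to Bernoulli(0.5) / uniform levels / standard normal.
draw_covariates <- function(n, schema, marg) {
  f_met <- stats::rnorm(n)              # latent metabolic-health factor
  z_bp <- stats::rnorm(n)               # shared SBP/DBP component
  out <- list()
  # intention is drawn first because smoking prevalence depends on it
  intention <- NULL
  if ("intention" %in% schema$name) {
    intention <- stats::rbinom(n, 1L, marg[["intention"]]$p %||% 0.5)
  }
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    kind <- schema$kind[i]
    m <- marg[[nm]]
    if (kind == "binary") {
      if (nm == "intention") {
        x <- intention
        out[[nm]] <- x
        next
      }
      if (!is.null(m$p_by_intention) && !is.null(intention)) {
        p <- ifelse(intention == 1, m$p_by_intention[["yes"]],
                    m$p_by_intention[["no"]])
      } else {
        p <- (m$p %||% 0.5)
      }
      x <- stats::rbinom(n, 1L, p)
    } else if (kind == "categorical") {
      lv <- schema$levels[[i]]
      pr <- m$probs %||% rep(1 / length(lv), length(lv))
      x <- factor(sample(lv, n, replace = TRUE, prob = pr), levels = lv)
    } else {
      mu <- m$mean %||% 0
      sd <- m$sd %||% 1
      lam <- m$load %||% 0
      z <- stats::rnorm(n)
      if (nm %in% c("sbp_baseline", "dbp_baseline")) {
        z <- 0.6 * z_bp + sqrt(1 - 0.36) * z
      } else if (lam != 0) {
        z <- lam * f_met + sqrt(1 - lam^2) * z
      }
      x <- mu + sd * z
      x <- pmin(pmax(x, m$lower %||% -Inf), m$upper %||% Inf)
    }
    out[[nm]] <- x
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

# Linear predictor from named coefficients over the standardized design.
# Continuous columns are standardized by their marginal mean/SD so logit
# coefficients are on an interpretable per-SD scale.
linear_predictor <- function(data, schema, coefs, marg, label) {
  mm <- schema_model_matrix(data, schema)
  lp <- rep(0, nrow(mm))
  for (nm in names(coefs)) {
    if (nm == "(Intercept)") {
      lp <- lp + coefs[[nm]]
      next
    }
    if (!nm %in% colnames(mm)) {
      stop(sprintf("%s coefficient refers to unknown covariate '%s'",
                   label, nm))
    }
    x <- mm[, nm]
    m <- marg[[nm]]
    if (!is.null(m$mean)) x <- (x - m$mean) / m$sd
    lp <- lp + coefs[[nm]] * x
  }
  if (any(!is.finite(lp))) {
    stop(label, " linear predictor non-finite; check coefficients")
  }
  lp
}

#' Generate a synthetic cohort with known ground-truth effects
#'
#' Draws baseline covariates, assigns treatment from a logistic propensity
#' model, draws the binary outcome (uncontrolled hypertension at follow-up)
#' from a logistic outcome model with treatment-by-covariate interactions,
#' and draws follow-up SBP/DBP from Gaussian linear models conditioned on
#' the binary outcome (truncated draws) so the threshold definition
#' `y_uncontrolled = 1 iff sbp_fu >= 140 or dbp_fu >= 90` holds row by row.
#'
#' @param config A [generation_config].
#' @param schema A [covariate_schema]; defaults to [default_schema()].
#' @return A list with elements
#'   \describe{
#'     \item{cohort}{data frame: `id`, the covariates, `treatment`,
#'       `followup_days`, `sbp_fu`, `dbp_fu`, `y_uncontrolled`,
#'       `delta_sbp`, `delta_dbp`.}
#'     \item{oracle}{data frame of ground truth: `id`, exact per-person
#'       potential risks `risk1`/`risk0`, `true_ite` (risk difference),
#'       `true_ite_sbp`/`true_ite_dbp` (mmHg mean differences), and
#'       attribute-free scalar summary `true_ate = mean(true_ite)` stored as
#'       `attr(oracle, "true_ate")`.}
#'     \item{propensity}{the assignment probabilities used (diagnostics).}
#'   }
#' @export
generate_cohort <- function(config, schema = default_schema()) {
  stopifnot(inherits(config, "generation_config"))
  n <- config$n_total
  if (n < 2) stop("n_total must be >= 2")
  marg <- default_marginals()
  local_seed(stage_seed(config$seed, "generate"), {
    data <- draw_covariates(n, schema, marg)

    # treatment assignment
    lp_ps <- linear_predictor(data, schema,
                              config$propensity_coefs[
                                names(config$propensity_coefs) != "(Intercept)"],
                              marg, "propensity")
    if (is.null(config$treated_fraction)) {
      icpt <- config$propensity_coefs[["(Intercept)"]] %||% 0
    } else {
      icpt <- stats::uniroot(
        function(c) mean(expit(c + lp_ps)) - config$treated_fraction,
        interval = c(-20, 20), tol = 1e-10)$root
    }
    ps <- expit(icpt + lp_ps)
    treatment <- stats::rbinom(n, 1L, ps)

    # potential outcome risks (exact ground truth)
    lp0 <- linear_predictor(data, schema, config$outcome_coefs, marg,
                            "outcome")
    te <- rep(config$treatment_main_effect, n)
    if (length(config$interaction_coefs)) {
      te <- te + linear_predictor(data, schema, config$interaction_coefs,
                                  marg, "interaction")
    }
    risk0 <- expit(lp0)
    risk1 <- expit(lp0 + te)
    risk <- ifelse(treatment == 1, risk1, risk0)
    y <- as.integer(stats::runif(n) < risk)

    # follow-up blood pressures consistent with y
    te_sbp <- config$bp_effect_scale[["sbp"]] * te
    te_dbp <- config$bp_effect_scale[["dbp"]] * te
    mu_sbp <- 0.65 * data$sbp_baseline + 45 + treatment * te_sbp
    mu_dbp <- 0.65 * data$dbp_baseline + 28 + treatment * te_dbp
    sbp_fu <- mu_sbp + stats::rnorm(n, 0, 10)
    dbp_fu <- mu_dbp + stats::rnorm(n, 0, 7)
    # reconcile with y via truncated redraws
    viol0 <- y == 0 & (sbp_fu >= 140 | dbp_fu >= 90)
    if (any(viol0)) {
      i <- which(viol0 & sbp_fu >= 140)
      sbp_fu[i] <- rtrunc_norm(length(i), mu_sbp[i], 10, upper = 139.999)
      i <- which(viol0 & dbp_fu >= 90)
      dbp_fu[i] <- rtrunc_norm(length(i), mu_dbp[i], 7, upper = 89.999)
    }
    viol1 <- y == 1 & sbp_fu < 140 & dbp_fu < 90
    if (any(viol1)) {
      # lift the margin that is closest (in SD units) to its cutoff
      i <- which(viol1)
      d_s <- (140 - mu_sbp[i]) / 10
      d_d <- (90 - mu_dbp[i]) / 7
      lift_s <- i[d_s <= d_d]
      lift_d <- i[d_s > d_d]
      sbp_fu[lift_s] <- rtrunc_norm(length(lift_s), mu_sbp[lift_s], 10,
                                    lower = 140)
      dbp_fu[lift_d] <- rtrunc_norm(length(lift_d), mu_dbp[lift_d], 7,
                                    lower = 90)
    }
    stopifnot(all(compute_outcomes(sbp_fu, dbp_fu) == y))

    followup_days <- sample(
      seq(config$followup_days_range[1], config$followup_days_range[2]),
      n, replace = TRUE)

    cohort <- cbind(
      data.frame(id = seq_len(n)),
      data,
      data.frame(
        treatment = treatment,
        followup_days = as.integer(followup_days),
        sbp_fu = sbp_fu,
        dbp_fu = dbp_fu,
        y_uncontrolled = y,
        delta_sbp = sbp_fu - data$sbp_baseline,
        delta_dbp = dbp_fu - data$dbp_baseline
      )
    )
    oracle <- data.frame(
      id = seq_len(n),
      risk1 = risk1,
      risk0 = risk0,
      true_ite = risk1 - risk0,
      true_ite_sbp = te_sbp,
      true_ite_dbp = te_dbp
    )
    attr(oracle, "true_ate") <- mean(oracle$true_ite)
    list(cohort = cohort, oracle = oracle, propensity = ps)
  })
}

#' Binary outcome from follow-up blood pressures
#'
#' Uncontrolled hypertension: systolic >= 140 mmHg or diastolic >= 90 mmHg.
#'
#' @param sbp_fu,dbp_fu Follow-up systolic / diastolic pressures (mmHg).
#' @return Integer vector of 0/1.
#' @export
compute_outcomes <- function(sbp_fu, dbp_fu) {
  if (any(!is.finite(sbp_fu)) || any(!is.finite(dbp_fu))) {
    stop("blood pressures must be finite")
  }
  if (any(sbp_fu < 0) || any(dbp_fu < 0)) {
    stop("blood pressures must be non-negative")
  }
  as.integer(sbp_fu >= 140 | dbp_fu >= 90)
}

#' Mask covariate values to emulate checkup-questionnaire missingness
#'
#' MCAR masks each covariate iid Bernoulli at its configured rate. MAR
#' modulates the rate by always-observed age and sex through a logistic
#' model, `logit(p_i) = a_j + 0.8 * age_z_i + 0.4 * sex_male_i`, with the
#' intercept `a_j` calibrated so the cohort-mean masking probability equals
#' the configured rate (older and male respondents skip questionnaire items
#' more often). Treatment, outcomes and follow-up time are never masked.
#'
#' @param table A cohort data frame from [generate_cohort()].
#' @param config A [generation_config] (rates, mechanism, seed).
#' @return The table with masked covariate cells set to `NA`.
#' @export
impose_missingness <- function(table, config) {
  stopifnot(inherits(config, "generation_config"))
  rates <- config$missing_rates
  if (any(rates < 0 | rates > 1)) stop("missing rates must lie in [0, 1]")
  if (!length(rates) || all(rates == 0)) return(table)
  n <- nrow(table)
  protected <- c("id", "treatment", "followup_days", "sbp_fu", "dbp_fu",
                 "y_uncontrolled", "delta_sbp", "delta_dbp")
  local_seed(stage_seed(config$seed, "missingness"), {
    for (nm in names(rates)) {
      r <- rates[[nm]]
      if (r == 0) next
      if (nm %in% protected) stop("cannot mask column: ", nm)
      if (!nm %in% names(table)) stop("unknown covariate: ", nm)
      if (config$missing_mechanism == "MCAR") {
        p <- rep(r, n)
      } else {
        age_z <- (table$age - mean(table$age)) / stats::sd(table$age)
        eta <- 0.8 * age_z + 0.4 * table$sex_male
        a <- stats::uniroot(function(a) mean(expit(a + eta)) - r,
                            interval = c(-30, 10), tol = 1e-10)$root
        p <- expit(a + eta)
      }
      table[[nm]][stats::runif(n) < p] <- NA
    }
    table
  })
}

#' Restrict a cohort to the emulated follow-up window
#'
#' Keeps rows whose follow-up duration lies in `[min_days, max_days]`
#' (default 275 to 455 days after treatment assignment); order preserved.
#'
#' @param table Cohort data frame with a `followup_days` column.
#' @param min_days,max_days Window bounds in days.
#' @return The filtered table.
#' @export
apply_eligibility <- function(table, min_days = 275, max_days = 455) {
  if (min_days > max_days) stop("min_days must be <= max_days")
  table[table$followup_days >= min_days & table$followup_days <= max_days, ,
        drop = FALSE]
}

#' Write / read a cohort as CSV (missing cells empty)
#'
#' @param table Cohort data frame.
#' @param path File path.
#' @param schema A [covariate_schema] used to restore factor levels on read.
#' @return `read_cohort_csv()` returns the cohort data frame.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path, schema = default_schema()) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  for (i in seq_len(nrow(schema))) {
    if (schema$kind[i] == "categorical") {
      nm <- schema$name[i]
      if (nm %in% names(out)) {
        out[[nm]] <- factor(out[[nm]], levels = schema$levels[[i]])
      }
    }
  }
  out
}
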