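# G-formula effect estimation: counterfactual predictions under treatment
# and control from the fitted outcome model, individual treatment effects,
# bootstrap ATE / risk-ratio summaries, NNT, E-values, a propensity-overlap
# (positivity) diagnostic, and a baseline characteristics table.

#' Design matrix for the outcome model
#'
#' Expands schema covariates to a numeric matrix and appends the treatment
#' column, the layout [cv_stack()] expects.
#'
#' @param data Cohort data frame (complete covariates).
#' @param schema A [covariate_schema].
#' @param treatment Name of the treatment column (default `"treatment"`).
#' @return Numeric matrix with a `treatment` column.
#' @export
build_design <- function(data, schema, treatment = "treatment") {
  X <- schema_model_matrix(data, schema)
  if (anyNA(X)) stop("covariates contain missing values; impute first")
  cbind(X, treatment = as.numeric(data[[treatment]]))
}

#' Counterfactual predictions under treatment and control
#'
#' Applies the fitted outcome model to every person twice: once with the
#' treatment column set to 1 and once set to 0 (all other columns
#' untouched).
#'
#' @param model An `ensemble_model` fitted on a design with a `treatment`
#'   column.
#' @param X Design matrix (any value in its `treatment` column is ignored).
#' @return List of class `counterfactual_predictions`: `p1`, `p0`,
#'   `outcome_kind` (`"binary"` or `"continuous"`).
#' @export
counterfactual_predict <- function(model, X) {
  X <- as.matrix(X)
  if (!"treatment" %in% model$feature_names) {
    stop("model was not fitted with a treatment column")
  }
  X1 <- X; X1[, "treatment"] <- 1
  X0 <- X; X0[, "treatment"] <- 0
  structure(list(
    p1 = predict_ensemble(model, X1),
    p0 = predict_ensemble(model, X0),
    outcome_kind = if (model$loss == "binomial") "binary" else "continuous"
  ), class = "counterfactual_predictions")
}

#' Individual treatment effects
#'
#' Per-person difference of the counterfactual predictions, `p1 - p0`; on
#' the risk-difference scale for the binary outcome. Negative values
#' indicate benefit (lower risk of uncontrolled hypertension under the
#' program).
#'
#' @param cf A `counterfactual_predictions` object.
#' @return List of class `ite_vector` with element `ite`.
#' @export
compute_ite <- function(cf) {
  stopifnot(inherits(cf, "counterfactual_predictions"))
  structure(list(ite = cf$p1 - cf$p0, outcome_kind = cf$outcome_kind),
            class = "ite_vector")
}

effect_estimate <- function(scale, point, ci, n_boot, seed) {
  structure(list(scale = scale, point = point,
                 ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                 n_boot = n_boot, seed = seed),
            class = "effect_estimate")
}

#' @method print effect_estimate
#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s: %.4f (95%% CI %.4f to %.4f; %d bootstrap resamples)\n",
              x$scale, x$point, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}

#' Average effects with bootstrap confidence intervals
#'
#' Point estimates are plug-in G-formula quantities on the full data:
#' ATE = mean(p1 - p0) and, for the binary outcome, RR = mean(p1)/mean(p0).
#' Percentile confidence intervals come from `n_boot` bootstrap resamples of
#' persons; by default every resample refits the full cross-validated stack
#' (`fast_boot = FALSE`), while `fast_boot = TRUE` keeps the full-data
#' learner fits fixed and re-estimates only the stacking weights on each
#' resample's rows (a desk-scale approximation).
#'
#' @param X Design matrix including the `treatment` column.
#' @param y Outcome vector.
#' @param library,V Passed to [cv_stack()].
#' @param n_boot Number of bootstrap resamples (>= 1).
#' @param seed Integer seed.
#' @param fast_boot Logical; see above.
#' @param loss Forwarded to [cv_stack()].
#' @return List with `ATE` and (binary loss) `RR` [effect_estimate]s, plus
#'   `NNT`, `E_value`, the fitted `model`, `cf` and `ite` on the full data.
#' @export
estimate_effects <- function(X, y, library = default_library(), V = 10,
                             n_boot = 200, seed = 1L, fast_boot = FALSE,
                             loss = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("need at least two rows")
  A <- X[, "treatment"]
  if (length(unique(A)) < 2) stop("both treatment arms must be present")
  model <- cv_stack(X, y, library = library, V = V,
                    seed = stage_seed(seed, "fit"), loss = loss)
  cf <- counterfactual_predict(model, X)
  ite <- compute_ite(cf)
  ate_point <- mean(ite$ite)
  binary <- cf$outcome_kind == "binary"
  rr_point <- if (binary) mean(cf$p1) / mean(cf$p0) else NA_real_

  boot_ate <- numeric(n_boot)
  boot_rr <- numeric(n_boot)
  ok_fits <- which(is.finite(model$cv_risks))
  local_seed(stage_seed(seed, "bootstrap"), {
    for (b in seq_len(n_boot)) {
      idx <- NULL
      for (try in seq_len(100)) {
        cand <- sample.int(n, n, replace = TRUE)
        if (length(unique(X[cand, "treatment"])) == 2) {
          idx <- cand
          break
        }
      }
      if (is.null(idx)) stop("bootstrap could not draw both arms (100 tries)")
      if (fast_boot) {
        Zb <- model$oof[idx, ok_fits, drop = FALSE]
        wb <- pracma::lsqnonneg(Zb, y[idx])$x
        if (sum(wb) <= 0) wb <- rep(1 / length(ok_fits), length(ok_fits))
        wb <- wb / sum(wb)
        mb <- model
        mb$weights[] <- 0
        mb$weights[ok_fits] <- wb
      } else if (length(library) == 1) {
        # single learner: stacking weight is 1 by normalization, so the
        # honest refit needs no inner cross-validation
        fb <- fit_learner(library[[1]], X[idx, , drop = FALSE], y[idx],
                          model$loss,
                          stage_seed(seed, paste0("boot1_", b)))
        mb <- model
        mb$fits <- list(fb)
        mb$weights <- 1
        mb$cv_risks <- 0
      } else {
        mb <- cv_stack(X[idx, , drop = FALSE], y[idx], library = library,
                       V = V, seed = stage_seed(seed, paste0("boot", b)),
                       loss = loss)
      }
      cfb <- counterfactual_predict(mb, X[idx, , drop = FALSE])
      boot_ate[b] <- mean(cfb$p1 - cfb$p0)
      boot_rr[b] <- if (binary) mean(cfb$p1) / mean(cfb$p0) else NA_real_
    }
  })
  ate_ci <- stats::quantile(boot_ate, c(0.025, 0.975), names = FALSE)
  out <- list(
    ATE = effect_estimate(
      if (binary) "risk difference" else "mean difference",
      ate_point, ate_ci, n_boot, seed),
    model = model, cf = cf, ite = ite
  )
  if (binary) {
    rr_ci <- stats::quantile(boot_rr, c(0.025, 0.975), names = FALSE)
    out$RR <- effect_estimate("risk ratio", rr_point, rr_ci, n_boot, seed)
    out$NNT <- if (ate_point != 0) nnt_from_rd(ate_point) else NA_real_
    out$E_value <- evalue_rr(rr_point)
  }
  out
}

#' Number needed to treat from an absolute risk difference
#'
#' `NNT = 1 / |rd|`; display rounding (one decimal) is applied by
#' [format_effect()], not here, so that `NNT * |rd| = 1` holds exactly.
#'
#' @param rd Risk difference (non-zero).
#' @return The NNT.
#' @export
nnt_from_rd <- function(rd) {
  if (length(rd) != 1 || !is.finite(rd)) stop("rd must be a single number")
  if (rd == 0) stop("NNT undefined for a zero risk difference")
  1 / abs(rd)
}

#' E-value for a risk ratio
#'
#' Minimum strength of association (risk-ratio scale) an unmeasured
#' confounder would need with both treatment and outcome to fully explain
#' the observed risk ratio. Protective ratios are inverted first:
#' with `rr* = max(rr, 1/rr)`, `E = rr* + sqrt(rr* (rr* - 1))`.
#'
#' @param rr Risk ratio (> 0).
#' @return The E-value (unrounded; display uses two decimals).
#' @export
evalue_rr <- function(rr) {
  if (any(!is.finite(rr)) || any(rr <= 0)) stop("rr must be > 0")
  rr_star <- ifelse(rr >= 1, rr, 1 / rr)
  rr_star + sqrt(rr_star * (rr_star - 1))
}

#' Propensity-overlap (positivity) diagnostic
#'
#' Cross-fitted treatment probabilities from a logistic regression of
#' treatment on the covariates, summarized per arm, with the interval where
#' both arms have empirical support and a warning flag if (near-)separation
#' is detected.
#'
#' @param X Numeric covariate matrix (no treatment column).
#' @param A 0/1 treatment vector.
#' @param V Folds for cross-fitting (default 10).
#' @param seed Integer seed for the fold split.
#' @return List: `summary` (per-arm min/quantiles/max/mean of the estimated
#'   treatment probability), `overlap_interval`, `separation` flag, and the
#'   per-person `propensity` estimates.
#' @export
propensity_overlap <- function(X, A, V = 10, seed = 1L) {
  X <- as.matrix(X)
  if (length(unique(A)) < 2) stop("both treatment arms must be present")
  folds <- make_folds(A, V, "binomial", stage_seed(seed, "overlap"))
  p <- numeric(length(A))
  sep <- FALSE
  for (v in seq_len(V)) {
    test <- folds == v
    d <- cbind(`(Intercept)` = 1, X)
    fit <- withCallingHandlers(
      stats::glm.fit(d[!test, , drop = FALSE], A[!test],
                     family = stats::binomial()),
      warning = function(w) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    p[test] <- expit(drop(d[test, , drop = FALSE] %*% beta))
  }
  if (any(p[A == 1] > 1 - 1e-8) || any(p[A == 0] < 1e-8)) sep <- TRUE
  qs <- c(0, 0.05, 0.25, 0.5, 0.75, 0.95, 1)
  summ <- rbind(
    control = c(stats::quantile(p[A == 0], qs), mean = mean(p[A == 0])),
    treated = c(stats::quantile(p[A == 1], qs), mean = mean(p[A == 1])))
  overlap <- c(max(min(p[A == 0]), min(p[A == 1])),
               min(max(p[A == 0]), max(p[A == 1])))
  overlap <- pmin(pmax(overlap, 0), 1)
  list(summary = summ, overlap_interval = overlap, separation = sep,
       propensity = p)
}

fmt_p <- function(p) ifelse(p < 0.01, "<0.01", sprintf("%.2f", p))

#' Baseline characteristics table by treatment arm
#'
#' Counts (%) per level with explicit Missing rows and chi-square tests for
#' discrete covariates; mean (SD) with two-sample t-tests for continuous
#' ones. P-values display with two decimals and a "<0.01" floor.
#'
#' @param data Cohort data frame (may contain `NA`s).
#' @param schema A [covariate_schema].
#' @param treatment Name of the treatment column.
#' @return Data frame with columns `covariate`, `level`, `control`,
#'   `treated`, `p_value`.
#' @export
baseline_table <- function(data, schema = default_schema(),
                           treatment = "treatment") {
  A <- data[[treatment]]
  if (length(unique(A)) < 2) stop("both treatment arms must be present")
  rows <- list()
  n0 <- sum(A == 0); n1 <- sum(A == 1)
  rows[[1]] <- data.frame(covariate = "N", level = "",
                          control = format(n0, big.mark = ","),
                          treated = format(n1, big.mark = ","),
                          p_value = "")
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    x <- data[[nm]]
    if (schema$kind[i] == "continuous") {
      p <- tryCatch(stats::t.test(x[A == 0], x[A == 1])$p.value,
                    error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = nm, level = "mean (SD)",
        control = sprintf("%.1f (%.1f)", mean(x[A == 0], na.rm = TRUE),
                          stats::sd(x[A == 0], na.rm = TRUE)),
        treated = sprintf("%.1f (%.1f)", mean(x[A == 1], na.rm = TRUE),
                          stats::sd(x[A == 1], na.rm = TRUE)),
        p_value = ifelse(is.na(p), "", fmt_p(p)))
    } else {
      lv <- if (schema$kind[i] == "categorical") schema$levels[[i]] else
        c("1", "0")
      xx <- factor(as.character(x), levels = lv)
      tab <- table(xx, A)
      p <- tryCatch(
        suppressWarnings(stats::chisq.test(tab)$p.value),
        error = function(e) NA_real_)
      for (j in seq_along(lv)) {
        cnt0 <- sum(xx == lv[j] & A == 0, na.rm = TRUE)
        cnt1 <- sum(xx == lv[j] & A == 1, na.rm = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = nm, level = lv[j],
          control = sprintf("%s (%.0f)", format(cnt0, big.mark = ","),
                            100 * cnt0 / n0),
          treated = sprintf("%s (%.0f)", format(cnt1, big.mark = ","),
                            100 * cnt1 / n1),
          p_value = if (j == 1 && !is.na(p)) fmt_p(p) else "")
      }
      miss0 <- sum(is.na(x) & A == 0)
      miss1 <- sum(is.na(x) & A == 1)
      if (miss0 + miss1 > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = nm, level = "Missing",
          control = sprintf("%d (%.0f)", miss0, 100 * miss0 / n0),
          treated = sprintf("%d (%.0f)", miss1, 100 * miss1 / n1),
          p_value = "")
      }
    }
  }
  do.call(rbind, rows)
}
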