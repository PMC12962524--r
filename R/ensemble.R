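# Cross-validated stacking ensemble (Super Learner) used as the G-formula
# outcome model. Candidate families: generalized linear model, random
# forest, neural network, adaptive piecewise-linear splines (MARS-style
# hinge basis + penalized GLM), and gradient boosting. The meta-learner is
# non-negative least squares on the out-of-fold prediction matrix, weights
# normalized to the simplex.

#' Describe a candidate learner
#'
#' @param name Unique label for the learner.
#' @param family One of `"glm"`, `"rf"`, `"nnet"`, `"mars"`, `"xgboost"`.
#' @param ... Family-specific hyperparameters (see Details).
#' @details Recognised hyperparameters: `glm`: `interactions` (logical;
#'   include treatment-by-covariate products, default `TRUE`); `rf`:
#'   `num.trees` (300), `min.node.size`; `nnet`: `size` (4), `decay`
#'   (0.01), `maxit` (300); `mars`: `knots` (3 interior quantile knots per
#'   continuous column); `xgboost`: `nrounds` (150), `max_depth` (3), `eta`
#'   (0.1), `subsample`, `colsample_bytree`.
#' @return A `learner_spec` object.
#' @export
learner_spec <- function(name, family, ...) {
  family <- match.arg(family, c("glm", "rf", "nnet", "mars", "xgboost"))
  structure(list(name = name, family = family, params = list(...)),
            class = "learner_spec")
}

#' Default candidate-learner library
#'
#' One member per candidate family, with fixed, documented hyperparameters.
#'
#' @return List of [learner_spec] objects.
#' @export
default_library <- function() {
  list(
    learner_spec("glm_interactions", "glm", interactions = TRUE),
    learner_spec("random_forest", "rf", num.trees = 300),
    learner_spec("neural_net", "nnet", size = 4, decay = 0.01, maxit = 300),
    learner_spec("mars_hinge", "mars", knots = 3),
    learner_spec("xgboost", "xgboost", nrounds = 150, max_depth = 3,
                 eta = 0.1)
  )
}

# ---- individual learner fits (internal) ------------------------------------
# Each fit_* returns a list with a $predict(newx) closure over a numeric
# design matrix whose column names match training.

glm_design <- function(x, interactions) {
  if (interactions && "treatment" %in% colnames(x)) {
    others <- setdiff(colnames(x), "treatment")
    inter <- x[, others, drop = FALSE] * x[, "treatment"]
    colnames(inter) <- paste0("treatment:", others)
    cbind(x, inter)
  } else {
    x
  }
}

fit_glm <- function(x, y, loss, params, seed) {
  interactions <- params$interactions %||% TRUE
  penalize <- params$penalize %||% FALSE
  fam <- if (loss == "binomial") "binomial" else "gaussian"
  if (penalize) {
    # lasso-penalized GLM: shrinks the many treatment-by-covariate products
    # toward zero, stabilizing ITE estimation when treated counts are small;
    # the treatment main effect itself is left unpenalized
    d <- glm_design(x, interactions)
    pf <- as.numeric(colnames(d) != "treatment")
    cv <- local_seed(seed, glmnet::cv.glmnet(d, y, family = fam,
                                             nfolds = 5, alpha = 1,
                                             penalty.factor = pf))
    return(list(predict = function(newx) {
      drop(stats::predict(cv, newx = glm_design(newx, interactions),
                          s = "lambda.min", type = "response"))
    }))
  }
  d <- cbind(`(Intercept)` = 1, glm_design(x, interactions))
  fam_obj <- if (loss == "binomial") stats::binomial() else stats::gaussian()
  fit <- suppressWarnings(stats::glm.fit(d, y, family = fam_obj))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  list(predict = function(newx) {
    nd <- cbind(`(Intercept)` = 1, glm_design(newx, interactions))
    eta <- drop(nd[, names(beta), drop = FALSE] %*% beta)
    if (loss == "binomial") expit(eta) else eta
  })
}

fit_rf <- function(x, y, loss, params, seed) {
  if (loss == "binomial") {
    fit <- ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                          probability = TRUE,
                          num.trees = params$num.trees %||% 300,
                          min.node.size = params$min.node.size %||% 10,
                          seed = seed, num.threads = 1, verbose = FALSE)
    list(predict = function(newx) {
      p <- stats::predict(fit, data = newx, num.threads = 1)$predictions
      p[, "1"]
    })
  } else {
    fit <- ranger::ranger(x = x, y = y,
                          num.trees = params$num.trees %||% 300,
                          min.node.size = params$min.node.size %||% 5,
                          seed = seed, num.threads = 1, verbose = FALSE)
    list(predict = function(newx) {
      stats::predict(fit, data = newx, num.threads = 1)$predictions
    })
  }
}

fit_nnet <- function(x, y, loss, params, seed) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  fit <- local_seed(seed, nnet::nnet(
    x = xs, y = y, size = params$size %||% 4,
    decay = params$decay %||% 0.01, maxit = params$maxit %||% 300,
    linout = loss != "binomial", entropy = loss == "binomial",
    trace = FALSE, MaxNWts = 5000))
  list(predict = function(newx) {
    drop(stats::predict(fit, scale(newx, ctr, scl)))
  })
}

# MARS-style basis: per continuous column, paired hinge functions
# max(x - k, 0) / max(k - x, 0) at interior quantile knots.
mars_basis <- function(x, knots_list) {
  out <- list(x)
  for (nm in names(knots_list)) {
    for (k in knots_list[[nm]]) {
      out[[length(out) + 1L]] <- cbind(
        pmax(x[, nm] - k, 0), pmax(k - x[, nm], 0))
    }
  }
  b <- do.call(cbind, out)
  colnames(b) <- paste0("b", seq_len(ncol(b)))
  b
}

fit_mars <- function(x, y, loss, params, seed) {
  n_knots <- params$knots %||% 3
  cont <- colnames(x)[apply(x, 2, function(v) length(unique(v)) > 8)]
  knots_list <- lapply(stats::setNames(cont, cont), function(nm) {
    unique(stats::quantile(x[, nm], probs = seq_len(n_knots) / (n_knots + 1),
                           names = FALSE))
  })
  b <- mars_basis(x, knots_list)
  fam <- if (loss == "binomial") "binomial" else "gaussian"
  cv <- local_seed(seed, glmnet::cv.glmnet(b, y, family = fam, nfolds = 5,
                                           alpha = 1))
  list(predict = function(newx) {
    drop(stats::predict(cv, newx = mars_basis(newx, knots_list),
                        s = "lambda.min", type = "response"))
  })
}

fit_xgb <- function(x, y, loss, params, seed) {
  obj <- if (loss == "binomial") "binary:logistic" else "reg:squarederror"
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  fit <- local_seed(seed, xgboost::xgb.train(
    params = list(objective = obj, eta = params$eta %||% 0.1,
                  max_depth = params$max_depth %||% 3,
                  subsample = params$subsample %||% 0.8,
                  colsample_bytree = params$colsample_bytree %||% 0.8,
                  nthread = 1, seed = seed),
    data = dtrain, nrounds = params$nrounds %||% 150, verbose = 0))
  list(predict = function(newx) {
    stats::predict(fit, xgboost::xgb.DMatrix(newx))
  })
}

fit_learner <- function(spec, x, y, loss, seed) {
  fitter <- switch(spec$family, glm = fit_glm, rf = fit_rf, nnet = fit_nnet,
                   mars = fit_mars, xgboost = fit_xgb)
  fitter(x, y, loss, spec$params, seed)
}

# Stratified V-fold assignment (stratified by outcome for binary loss).
make_folds <- function(y, V, loss, seed) {
  n <- length(y)
  local_seed(seed, {
    folds <- integer(n)
    if (loss == "binomial") {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        folds[idx] <- sample(rep_len(seq_len(V), length(idx)))
      }
    } else {
      folds <- sample(rep_len(seq_len(V), n))
    }
    folds
  })
}

#' Fit a cross-validated stacking ensemble
#'
#' Computes V-fold out-of-fold predictions for every candidate learner,
#' solves non-negative least squares of the outcome on the out-of-fold
#' prediction matrix for the stacking weights (normalized to sum to one),
#' and refits every learner on the full data. A learner that fails on any
#' fold receives infinite cross-validated risk and weight zero.
#'
#' @param X Numeric matrix of covariates including a `treatment` column.
#' @param y Outcome vector: 0/1 (binomial loss) or continuous (squared
#'   error); the loss is chosen automatically unless `loss` is given.
#' @param library List of [learner_spec]s; default [default_library()].
#' @param V Number of cross-validation folds (default 10).
#' @param seed Integer seed controlling fold assignment and every learner's
#'   internal randomness.
#' @param loss `"binomial"` or `"gaussian"`; `NULL` = auto-detect.
#' @return An object of class `ensemble_model` with elements `library`,
#'   `weights`, `cv_risks`, `folds`, `fits`, `oof` (out-of-fold prediction
#'   matrix), `loss`, `feature_names`, `seed`.
#' @export
cv_stack <- function(X, y, library = default_library(), V = 10, seed = 1L,
                     loss = NULL) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("X and y must be complete (impute first)")
  n <- nrow(X)
  if (is.null(loss)) {
    loss <- if (all(y %in% c(0, 1))) "binomial" else "gaussian"
  }
  if (n < 2 * V) stop("need n >= 2V observations")
  nm <- vapply(library, `[[`, "", "name")
  if (anyDuplicated(nm)) nm <- make.unique(nm)
  folds <- make_folds(y, V, loss, stage_seed(seed, "folds"))
  K <- length(library)
  Z <- matrix(NA_real_, n, K, dimnames = list(NULL, nm))
  ok <- rep(TRUE, K)
  for (k in seq_len(K)) {
    for (v in seq_len(V)) {
      test <- folds == v
      res <- tryCatch({
        fit <- fit_learner(library[[k]], X[!test, , drop = FALSE], y[!test],
                           loss, stage_seed(seed, paste0(nm[k], "_f", v)))
        fit$predict(X[test, , drop = FALSE])
      }, error = function(e) e)
      if (inherits(res, "error") || anyNA(res) || any(!is.finite(res))) {
        warning("learner '", nm[k], "' failed on fold ", v,
                "; excluded from the stack", call. = FALSE)
        ok[k] <- FALSE
        break
      }
      Z[test, k] <- res
    }
  }
  if (!any(ok)) stop("all candidate learners failed")
  if (loss == "binomial") Z[, ok] <- pmin(pmax(Z[, ok], 1e-6), 1 - 1e-6)
  cv_risks <- rep(Inf, K)
  names(cv_risks) <- nm
  cv_risks[ok] <- colMeans((Z[, ok, drop = FALSE] - y)^2)

  w_raw <- pracma::lsqnonneg(Z[, ok, drop = FALSE], y)$x
  if (sum(w_raw) <= 0) {         # degenerate: fall back to best single learner
    w_raw <- as.numeric(seq_along(w_raw) ==
                          which.min(cv_risks[ok]))
  }
  w_ok <- w_raw / sum(w_raw)
  # Discrete-Super-Learner safeguard: the simplex-normalized NNLS combination
  # must never do worse (in cross-validated risk) than the best single
  # learner; if it does, select that learner outright.
  stack_risk <- mean((Z[, ok, drop = FALSE] %*% w_ok - y)^2)
  if (stack_risk > min(cv_risks[ok])) {
    w_ok <- as.numeric(seq_along(w_ok) == which.min(cv_risks[ok]))
  }
  weights <- rep(0, K)
  names(weights) <- nm
  weights[ok] <- w_ok

  fits <- vector("list", K)
  names(fits) <- nm
  for (k in seq_len(K)) {
    if (!ok[k]) next
    fits[[k]] <- fit_learner(library[[k]], X, y, loss,
                             stage_seed(seed, paste0(nm[k], "_full")))
  }
  structure(list(library = library, weights = weights, cv_risks = cv_risks,
                 folds = folds, V = V, fits = fits, oof = Z, loss = loss,
                 feature_names = colnames(X), seed = seed),
            class = "ensemble_model")
}

#' Predict from a fitted stacking ensemble
#'
#' Weighted combination of the refit learners; binary-loss predictions are
#' clipped to `[1e-6, 1 - 1e-6]`.
#'
#' @param model An `ensemble_model` from [cv_stack()].
#' @param X Numeric matrix with the training feature columns.
#' @return Numeric prediction vector.
#' @export
predict_ensemble <- function(model, X) {
  X <- as.matrix(X)
  missing_cols <- setdiff(model$feature_names, colnames(X))
  if (length(missing_cols)) {
    stop("X lacks training columns: ", paste(missing_cols, collapse = ", "))
  }
  X <- X[, model$feature_names, drop = FALSE]
  p <- rep(0, nrow(X))
  for (k in seq_along(model$fits)) {
    w <- model$weights[k]
    if (w == 0 || is.null(model$fits[[k]])) next
    p <- p + w * model$fits[[k]]$predict(X)
  }
  if (model$loss == "binomial") p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  p
}

#' @method print ensemble_model
#' @export
print.ensemble_model <- function(x, ...) {
  cat("Stacking ensemble (", x$loss, " loss, V = ", x$V, ")\n", sep = "")
  tab <- data.frame(weight = round(x$weights, 4),
                    cv_risk = signif(x$cv_risks, 5))
  print(tab)
  invisible(x)
}

# Cross-validated risk of the stacked predictor on the stored folds:
# mean squared error of the weighted out-of-fold predictions.
ensemble_cv_risk <- function(model, y) {
  ok <- is.finite(model$cv_risks)
  zw <- model$oof[, ok, drop = FALSE] %*% model$weights[ok]
  mean((zw - y)^2)
}
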