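# Iterative random-forest imputation of missing baseline covariates.
#
# The algorithm follows the classic iterative-forest scheme: initialize
# missing cells with the column mean (continuous) or mode (categorical /
# binary), visit variables in ascending order of missingness, refit a random
# forest per variable on the currently completed data, overwrite only the
# originally missing cells, and stop when the difference statistic increases
# for both variable kinds (returning the completed table from the iteration
# before the increase).

#' Impute missing covariates with iterative random forests
#'
#' @param table Cohort data frame; only covariate columns from `schema` are
#'   imputed. Treatment and outcome columns must be complete (they are never
#'   imputed and, by default, do not enter the imputation model).
#' @param schema A [covariate_schema] naming the covariates.
#' @param max_iter Maximum sweeps over the variables (default 10).
#' @param trees Trees per forest (default 100).
#' @param seed Integer seed; forests are seeded deterministically from it.
#' @return A list of class `imputation_result`:
#'   \describe{
#'     \item{completed}{the table with all covariate `NA`s filled in;
#'       originally observed cells are untouched.}
#'     \item{n_iterations}{number of sweeps performed.}
#'     \item{convergence_trace}{data frame of per-iteration difference
#'       statistics for continuous and categorical variables.}
#'   }
#' @export
rf_impute <- function(table, schema = default_schema(), max_iter = 10,
                      trees = 100, seed = 1L) {
  if (nrow(table) < 10) stop("need at least 10 rows to impute")
  for (nm in c("treatment", "y_uncontrolled")) {
    if (nm %in% names(table) && anyNA(table[[nm]])) {
      stop("column must be complete (never imputed): ", nm)
    }
  }
  covs <- intersect(schema$name, names(table))
  kind <- stats::setNames(schema$kind, schema$name)[covs]
  mask <- lapply(table[covs], is.na)
  n_miss <- vapply(mask, sum, 1L)
  fully_missing <- covs[n_miss == nrow(table)]
  if (length(fully_missing)) {
    stop("column entirely missing: ", paste(fully_missing, collapse = ", "))
  }
  if (all(n_miss == 0)) {
    return(structure(list(completed = table, n_iterations = 1L,
                          convergence_trace = data.frame(
                            iteration = 1L, diff_continuous = 0,
                            diff_categorical = 0)),
                     class = "imputation_result"))
  }
  if (!any(n_miss == 0)) {
    stop("need at least one fully observed covariate column")
  }

  work <- table
  # initialization: column mean (continuous) / mode (categorical, binary;
  # which.max breaks ties by level order, keeping the rule deterministic)
  for (nm in covs) {
    idx <- mask[[nm]]
    if (!any(idx)) next
    if (kind[[nm]] == "continuous") {
      work[[nm]][idx] <- mean(work[[nm]], na.rm = TRUE)
    } else {
      tab <- table(work[[nm]], useNA = "no")
      mode_lv <- names(tab)[which.max(tab)]
      if (is.factor(work[[nm]])) {
        work[[nm]][idx] <- mode_lv
      } else {
        work[[nm]][idx] <- as.numeric(mode_lv)
      }
    }
  }

  visit <- covs[n_miss > 0][order(n_miss[n_miss > 0])]
  trace <- data.frame(iteration = integer(), diff_continuous = double(),
                      diff_categorical = double())
  prev <- work
  best <- work
  prev_dc <- Inf
  prev_df <- Inf
  it <- 0L
  repeat {
    it <- it + 1L
    for (j in seq_along(visit)) {
      nm <- visit[j]
      idx <- mask[[nm]]
      predictors <- setdiff(covs, nm)
      df <- work[predictors]
      is_cat <- kind[[nm]] != "continuous"
      y <- if (is_cat) {
        f <- if (is.factor(work[[nm]])) droplevels(factor(work[[nm]])) else
          factor(work[[nm]])
        f
      } else {
        work[[nm]]
      }
      fit <- ranger::ranger(
        x = df[!idx, , drop = FALSE], y = y[!idx],
        num.trees = trees,
        seed = stage_seed(seed, paste0("impute_", nm, "_", it)),
        num.threads = 1, verbose = FALSE,
        respect.unordered.factors = "order")
      pred <- stats::predict(fit, data = df[idx, , drop = FALSE],
                             num.threads = 1)$predictions
      if (is_cat) {
        if (is.factor(work[[nm]])) {
          work[[nm]][idx] <- as.character(pred)
        } else {
          work[[nm]][idx] <- as.numeric(as.character(pred))
        }
      } else {
        work[[nm]][idx] <- pred
      }
    }
    # difference statistics over imputed cells only
    cont <- visit[kind[visit] == "continuous"]
    cat_ <- visit[kind[visit] != "continuous"]
    dc <- if (length(cont)) {
      num <- 0; den <- 0
      for (nm in cont) {
        num <- num + sum((work[[nm]][mask[[nm]]] - prev[[nm]][mask[[nm]]])^2)
        den <- den + sum(work[[nm]][mask[[nm]]]^2)
      }
      if (den > 0) num / den else 0
    } else 0
    df_ <- if (length(cat_)) {
      chg <- 0; tot <- 0
      for (nm in cat_) {
        chg <- chg + sum(work[[nm]][mask[[nm]]] != prev[[nm]][mask[[nm]]])
        tot <- tot + sum(mask[[nm]])
      }
      chg / tot
    } else 0
    trace <- rbind(trace, data.frame(iteration = it, diff_continuous = dc,
                                     diff_categorical = df_))
    worse_cont <- length(cont) == 0 || dc > prev_dc
    worse_cat <- length(cat_) == 0 || df_ > prev_df
    if (it > 1 && worse_cont && worse_cat) {
      work <- best      # last completed table before the increase
      break
    }
    best <- work
    prev <- work
    prev_dc <- dc
    prev_df <- df_
    if (it >= max_iter) break
  }

  structure(list(completed = work, n_iterations = it,
                 convergence_trace = trace, mask = mask),
            class = "imputation_result")
}

#' Imputation quality against known truth
#'
#' Normalized root-mean-square error over imputed continuous cells (RMSE
#' divided by the standard deviation of the true values) and proportion of
#' falsely classified imputed categorical/binary cells.
#'
#' @param completed Completed table (e.g. `rf_impute(...)$completed`).
#' @param truth The fully observed table the mask was applied to.
#' @param mask Named list of logical vectors marking imputed cells.
#' @param schema A [covariate_schema].
#' @return A list `nrmse`, `pfc` (either may be `NA` if no cells of that
#'   kind were imputed; an entirely empty mask is an error).
#' @export
imputation_error <- function(completed, truth, mask,
                             schema = default_schema()) {
  if (!any(vapply(mask, any, TRUE))) stop("mask marks no imputed cells")
  kind <- stats::setNames(schema$kind, schema$name)
  se <- c(); tv <- c()
  wrong <- 0L; tot <- 0L
  for (nm in names(mask)) {
    idx <- mask[[nm]]
    if (!any(idx)) next
    if (kind[[nm]] == "continuous") {
      se <- c(se, (as.numeric(completed[[nm]][idx]) -
                     as.numeric(truth[[nm]][idx]))^2)
      tv <- c(tv, as.numeric(truth[[nm]][idx]))
    } else {
      wrong <- wrong + sum(as.character(completed[[nm]][idx]) !=
                             as.character(truth[[nm]][idx]))
      tot <- tot + sum(idx)
    }
  }
  list(
    nrmse = if (length(se)) sqrt(mean(se)) / stats::sd(tv) else NA_real_,
    pfc = if (tot > 0) wrong / tot else NA_real_
  )
}
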