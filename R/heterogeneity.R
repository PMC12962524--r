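# Heterogeneity discovery on the individual treatment effects: small
# Gaussian jitter + standardization (mean 0, SD 0.1), Ward.D2 hierarchical
# clustering of the 1-D standardized ITEs, Beale's-index selection of the
# number of clusters over 2-10, covariate z-score importance with selection
# thresholds, and per-cluster effect summaries / baseline profiles.

#' Jitter and standardize individual treatment effects
#'
#' Adds small iid Gaussian noise (a tie-breaking device for Ward clustering
#' on near-duplicate ITEs), then centers to mean 0 and rescales to a
#' population (1/n) standard deviation of exactly 0.1. The jittered values
#' are used only for clustering; all reported effects use the raw ITEs.
#'
#' @param ite An `ite_vector` from [compute_ite()] or a numeric vector.
#' @param noise_sd Noise SD; default `0.01 * sd(ite)` (relative, so the
#'   noise is always small against the signal).
#' @param seed Integer seed.
#' @return List of class `standardized_ite`: `z_ite`, `noise_sd`, `seed`.
#' @export
jitter_standardize <- function(ite, noise_sd = NULL, seed = 1L) {
  x <- if (inherits(ite, "ite_vector")) ite$ite else as.numeric(ite)
  if (length(x) < 2) stop("need at least two ITEs")
  if (is.null(noise_sd)) noise_sd <- 0.01 * stats::sd(x)
  z <- local_seed(stage_seed(seed, "jitter"),
                  x + stats::rnorm(length(x), 0, noise_sd))
  z <- z - mean(z)
  s <- pop_sd(z)
  if (s == 0) stop("ITEs are constant and noise_sd is 0; cannot standardize")
  z <- z / s * 0.1
  z <- z - mean(z)              # re-center to kill rounding drift
  structure(list(z_ite = z, noise_sd = noise_sd, seed = seed),
            class = "standardized_ite")
}

#' Ward.D2 clustering of standardized treatment effects
#'
#' Agglomerative Ward.D2 linkage on the Euclidean distances of the (1-D)
#' standardized ITEs. Labels for any k in 2-10 come from cutting the tree.
#'
#' @param z A `standardized_ite` or numeric vector (n >= 10, so that 2-10
#'   clusters can be evaluated).
#' @return List of class `cluster_solution`: `hclust` (the linkage),
#'   `heights`, and `labels_for(k)` via [cut_labels()].
#' @export
ward_cluster <- function(z) {
  x <- if (inherits(z, "standardized_ite")) z$z_ite else as.numeric(z)
  if (length(x) < 10) stop("need n >= 10 to evaluate 2-10 clusters")
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  structure(list(hclust = hc, heights = hc$height, n = length(x), data = x),
            class = "cluster_solution")
}

#' Cluster labels for a given k
#'
#' Clusters are relabeled in increasing order of their mean standardized
#' ITE, so cluster 1 is always the highest-benefit (most negative) group.
#'
#' @param solution A `cluster_solution`.
#' @param k Number of clusters.
#' @return Integer labels in `1..k`.
#' @export
cut_labels <- function(solution, k) {
  raw <- stats::cutree(solution$hclust, k = k)
  means <- tapply(solution$data, raw, mean)
  rank_map <- rank(means, ties.method = "first")
  as.integer(rank_map[as.character(raw)])
}

# Within-cluster sum of squares of a 1-D set.
wss <- function(x) sum((x - mean(x))^2)

#' Choose the number of clusters with Beale's index
#'
#' For each transition k -> k+1 the parent cluster that splits is
#' identified; with parent size `n_C`, within-cluster sum of squares `W_C`,
#' children's summed within-cluster sum of squares `W_12` and dimension
#' `p = 1`, Beale's F-ratio is
#' `F = ((W_C - W_12) / W_12) / (((n_C - 1)/(n_C - 2)) * 2^(2/p) - 1)`,
#' referred to an `F(p, (n_C - 2) p)` distribution. A split is accepted iff
#' its p-value is below `alpha`. The chosen k is the largest value reachable
#' from the full data by consecutively significant splits, capped at
#' `k_range[2]`; if even the first split is non-significant, k = 2 is
#' returned with `no_significant_structure = TRUE` (the evaluated range
#' starts at 2).
#'
#' @param solution A `cluster_solution` from [ward_cluster()].
#' @param alpha Significance level (default 0.01).
#' @param k_range Evaluated range of cluster counts (default `c(2, 10)`).
#' @return List: `k`, `beale_path` (data frame of F statistics, degrees of
#'   freedom, p-values and significance flags per split), and
#'   `no_significant_structure`.
#' @export
beale_select_k <- function(solution, alpha = 0.01, k_range = c(2L, 10L)) {
  stopifnot(inherits(solution, "cluster_solution"))
  x <- solution$data
  p_dim <- 1
  k_max <- min(k_range[2], solution$n - 1L)
  path <- data.frame(from_k = integer(), to_k = integer(),
                     parent_size = integer(), F = double(),
                     df1 = double(), df2 = double(), p_value = double(),
                     significant = logical())
  labels_prev <- rep(1L, solution$n)
  for (k in seq(1L, k_max - 1L)) {
    labels_next <- stats::cutree(solution$hclust, k = k + 1L)
    # the parent is the cluster of the k-solution whose members carry two
    # different labels in the (k+1)-solution
    split_parent <- NA_integer_
    for (c_id in unique(labels_prev)) {
      kids <- unique(labels_next[labels_prev == c_id])
      if (length(kids) > 1) {
        split_parent <- c_id
        break
      }
    }
    members <- labels_prev == split_parent
    n_c <- sum(members)
    if (n_c < 3) {
      path <- rbind(path, data.frame(
        from_k = k, to_k = k + 1L, parent_size = n_c, F = NA_real_,
        df1 = p_dim, df2 = NA_real_, p_value = NA_real_,
        significant = FALSE))
      labels_prev <- labels_next
      next
    }
    w_c <- wss(x[members])
    kids <- labels_next[members]
    w_12 <- sum(tapply(x[members], kids, wss))
    denom <- ((n_c - 1) / (n_c - 2)) * 2^(2 / p_dim) - 1
    f_stat <- if (w_12 > 0) ((w_c - w_12) / w_12) / denom else Inf
    df2 <- (n_c - 2) * p_dim
    p_val <- stats::pf(f_stat, p_dim, df2, lower.tail = FALSE)
    path <- rbind(path, data.frame(
      from_k = k, to_k = k + 1L, parent_size = n_c, F = f_stat,
      df1 = p_dim, df2 = df2, p_value = p_val,
      significant = p_val < alpha))
    labels_prev <- labels_next
  }
  # The evaluated range starts at k = 2; the chosen k is the largest value
  # reachable from 2 by consecutively significant splits. The root (1 -> 2)
  # split only informs the no-structure flag: if even it is non-significant
  # the data show no cluster structure at all, and k = 2 is a floor.
  k_chosen <- 2L
  for (i in which(path$from_k >= 2L)) {
    if (isTRUE(path$significant[i])) k_chosen <- path$to_k[i] else break
  }
  no_structure <- !isTRUE(path$significant[path$from_k == 1L])
  list(k = min(k_chosen, k_range[2]), beale_path = path,
       no_significant_structure = no_structure, alpha = alpha)
}

#' Covariate importance from between-cluster z-score differences
#'
#' Categorical covariates are expanded to one indicator per level. For
#' variable j and cluster c, `z_cj = (mean_c(x_j) - mean(x_j)) / SD(x_j)`
#' (population SD over the whole cohort); the importance of variable j is
#' the maximum over cluster pairs of `|z_cj - z_c'j|`, which for two
#' clusters reduces to `|z_1j - z_2j|`. Zero-variance variables get
#' importance 0.
#'
#' @param data Imputed cohort data frame (complete covariates).
#' @param labels Integer cluster labels.
#' @param schema A [covariate_schema].
#' @param thresholds Selection thresholds (default 0.20 / 0.25 / 0.30).
#' @return Data frame of class `importance_table`, sorted by decreasing
#'   importance: `variable`, one `z_cluster<k>` column per cluster,
#'   `importance`, and one logical `selected_<t>` column per threshold.
#' @export
covariate_importance <- function(data, labels, schema = default_schema(),
                                 thresholds = c(0.20, 0.25, 0.30)) {
  X <- schema_model_matrix(data, schema, full_dummies = TRUE)
  if (anyNA(X)) stop("covariates must be complete (impute first)")
  ks <- sort(unique(labels))
  zmat <- matrix(NA_real_, ncol(X), length(ks),
                 dimnames = list(colnames(X), paste0("z_cluster", ks)))
  imp <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    s <- pop_sd(X[, j])
    if (s == 0) {
      zmat[j, ] <- 0
      imp[j] <- 0
      next
    }
    m <- mean(X[, j])
    zc <- vapply(ks, function(c_id) {
      (mean(X[labels == c_id, j]) - m) / s
    }, 0)
    zmat[j, ] <- zc
    imp[j] <- max(stats::dist(zc))
  }
  out <- data.frame(variable = colnames(X), zmat, importance = imp,
                    row.names = NULL, check.names = FALSE)
  for (t in thresholds) {
    out[[sprintf("selected_%.2f", t)]] <- out$importance > t
  }
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  attr(out, "thresholds") <- thresholds
  out
}

#' Threshold sensitivity of effect-modifier selection
#'
#' Selection sets at each threshold, with the monotone-nesting invariant
#' (selected at a higher threshold implies selected at every lower one)
#' asserted.
#'
#' @param imp An `importance_table`.
#' @return Named list of character vectors (selected variables), one per
#'   threshold, plus an attribute `nested = TRUE`.
#' @export
sensitivity_thresholds <- function(imp) {
  thresholds <- sort(attr(imp, "thresholds"))
  sets <- lapply(thresholds, function(t) {
    imp$variable[imp$importance > t]
  })
  names(sets) <- sprintf("%.2f", thresholds)
  for (i in seq_along(sets)[-1]) {
    if (!all(sets[[i]] %in% sets[[i - 1]])) {
      stop("selection sets are not nested; importance table corrupted")
    }
  }
  attr(sets, "nested") <- TRUE
  sets
}

#' Per-cluster conditional average treatment effects
#'
#' `CATE_c = mean(ite | cluster c)`; for the binary outcome also
#' `RR_c = mean(p1 | c) / mean(p0 | c)` with NNT and E-value. Confidence
#' intervals are percentile bootstrap over persons within each cluster with
#' the labels held fixed. Clusters below 10 members are flagged `unstable`.
#'
#' @param ite An `ite_vector`.
#' @param cf The matching `counterfactual_predictions`.
#' @param labels Integer cluster labels.
#' @param n_boot Bootstrap resamples (default 500).
#' @param seed Integer seed.
#' @return Data frame, one row per cluster: `cluster`, `n`, `CATE`,
#'   `cate_ci_low/high`, and for binary outcomes `RR`, `rr_ci_low/high`,
#'   `NNT`, `E_value`, plus `unstable`.
#' @export
cluster_cate <- function(ite, cf, labels, n_boot = 500, seed = 1L) {
  x <- ite$ite
  stopifnot(length(labels) == length(x))
  binary <- cf$outcome_kind == "binary"
  ks <- sort(unique(labels))
  rows <- lapply(ks, function(c_id) {
    idx <- which(labels == c_id)
    cate <- mean(x[idx])
    rr <- if (binary) mean(cf$p1[idx]) / mean(cf$p0[idx]) else NA_real_
    bs <- local_seed(stage_seed(seed, paste0("cate", c_id)), {
      vapply(seq_len(n_boot), function(b) {
        ii <- idx[sample.int(length(idx), length(idx), replace = TRUE)]
        c(mean(x[ii]),
          if (binary) mean(cf$p1[ii]) / mean(cf$p0[ii]) else NA_real_)
      }, c(0, 0))
    })
    ci <- stats::quantile(bs[1, ], c(0.025, 0.975), names = FALSE)
    data.frame(
      cluster = c_id, n = length(idx), CATE = cate,
      cate_ci_low = ci[1], cate_ci_high = ci[2],
      RR = rr,
      rr_ci_low = if (binary)
        stats::quantile(bs[2, ], 0.025, names = FALSE) else NA_real_,
      rr_ci_high = if (binary)
        stats::quantile(bs[2, ], 0.975, names = FALSE) else NA_real_,
      NNT = if (binary && cate != 0) nnt_from_rd(cate) else NA_real_,
      E_value = if (binary) evalue_rr(rr) else NA_real_,
      unstable = length(idx) < 10)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Baseline profiles of the discovered clusters
#'
#' Per-cluster means (continuous) and proportions (indicators) of the
#' covariates selected as potential effect modifiers, ordered by decreasing
#' importance. The high-benefit cluster is the one with the smallest
#' (most negative) CATE.
#'
#' @param data Imputed cohort data frame.
#' @param labels Integer cluster labels.
#' @param imp An `importance_table`.
#' @param cate Output of [cluster_cate()] (used to tag the high-benefit
#'   cluster).
#' @param threshold Selection threshold (default 0.25).
#' @param schema A [covariate_schema].
#' @return Data frame: one row per cluster, one column per selected
#'   variable (importance order), plus `cluster`, `n`, `CATE` and
#'   `high_benefit`.
#' @export
cluster_profile <- function(data, labels, imp, cate, threshold = 0.25,
                            schema = default_schema()) {
  sel <- imp$variable[imp$importance > threshold]
  if (!length(sel)) stop("no variables selected at threshold ", threshold)
  X <- schema_model_matrix(data, schema, full_dummies = TRUE)
  ks <- sort(unique(labels))
  prof <- vapply(sel, function(v) {
    vapply(ks, function(c_id) mean(X[labels == c_id, v]), 0)
  }, numeric(length(ks)))
  prof <- matrix(prof, nrow = length(ks),
                 dimnames = list(NULL, sel))
  out <- data.frame(cluster = ks,
                    n = vapply(ks, function(c_id) sum(labels == c_id), 0L),
                    CATE = cate$CATE[match(ks, cate$cluster)],
                    check.names = FALSE)
  out$high_benefit <- out$CATE == min(out$CATE)
  cbind(out, as.data.frame(prof, check.names = FALSE))
}
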