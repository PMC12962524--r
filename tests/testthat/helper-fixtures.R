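# Shared fixtures and independent oracles for the test suite.

# A small 4-covariate schema for fast imputation / table tests.
mini_schema <- function() {
  covariate_schema(
    name = c("x_bin", "x_cat", "x1", "x2"),
    kind = c("binary", "categorical", "continuous", "continuous"),
    levels = list(NULL, c("a", "b", "c"), NULL, NULL)
  )
}

# Correlated mixed-type fixture: x2 ~ x1 + noise, x_bin/x_cat depend on x1,
# so the forests have signal to exploit when imputing.
mini_cohort <- function(n, seed) {
  withr::with_seed(seed, {
    x1 <- rnorm(n)
    data.frame(
      x_bin = rbinom(n, 1, plogis(x1)),
      x_cat = factor(c("a", "b", "c")[1 + (x1 > -0.5) + (x1 > 0.5)],
                     levels = c("a", "b", "c")),
      x1 = x1,
      x2 = x1 + rnorm(n, 0, 0.3),
      treatment = rbinom(n, 1, 0.5),
      y_uncontrolled = rbinom(n, 1, 0.3)
    )
  })
}

# Single fast learner for pipeline-level tests.
glm_library <- function() {
  list(learner_spec("glm_interactions", "glm", interactions = TRUE))
}

# Independent O(n^3) Ward.D2 oracle for 1-D data: greedy agglomeration with
# the exact centroid form of the merge cost,
# d(A, B) = sqrt(2 |A||B| / (|A|+|B|)) * |mean(A) - mean(B)|,
# recomputed from scratch at every step (no Lance-Williams recursion).
# Returns merge heights and the partition (list of index sets) after each
# merge, i.e. for k = n-1, ..., 1.
naive_ward <- function(x) {
  clusters <- as.list(seq_along(x))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        ni <- length(clusters[[i]])
        nj <- length(clusters[[j]])
        d <- sqrt(2 * ni * nj / (ni + nj)) *
          abs(mean(x[clusters[[i]]]) - mean(x[clusters[[j]]]))
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
    heights <- c(heights, best[1])
    partitions[[length(partitions) + 1L]] <- clusters
  }
  list(heights = heights, partitions = partitions)
}

# Canonical form of a partition: clusters as sorted member vectors, ordered
# by smallest member, so two partitions compare with identical().
canonical_partition <- function(groups) {
  gs <- unname(lapply(groups, function(g) as.integer(sort(g))))
  gs[order(vapply(gs, min, 1L))]
}

labels_to_partition <- function(labels) {
  canonical_partition(split(seq_along(labels), labels))
}
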