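# Internal helpers: seeded RNG scoping, seed fan-out, truncated normals.

#' Evaluate an expression under a local, seeded RNG state
#'
#' Saves and restores `.Random.seed` so library functions that consume
#' randomness do not perturb the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed
#'
#' Counter-based fan-out: each named stage gets a stable sub-seed so that
#' inserting a stage does not shift the seeds of the others.
#'
#' @param seed Master integer seed.
#' @param stage Character stage label.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage))) %% 104729
  as.integer(((abs(as.numeric(seed)) %% 1e6) * 104729 + h) %% 2147483646)
}

# Inverse-CDF sampler for one truncated normal draw per row.
# `lower`/`upper` may be -Inf/Inf; vectorized over mu.
rtrunc_norm <- function(n, mu, sd, lower = -Inf, upper = Inf) {
  p_lo <- stats::pnorm(lower, mu, sd)
  p_hi <- stats::pnorm(upper, mu, sd)
  u <- stats::runif(n)
  p <- p_lo + u * (p_hi - p_lo)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  stats::qnorm(p, mu, sd)
}

expit <- function(x) stats::plogis(x)

# Population (1/n) standard deviation; the convention used for ITE
# standardization and covariate z-scores.
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  sqrt(mean((x - mean(x))^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
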