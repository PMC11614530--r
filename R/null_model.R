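# Simulated uniform null distribution of interval ratios and the
# Kolmogorov-Smirnov comparison against it.
#
# The chance reference for an observed ratio distribution: draw two interval
# durations X, Y independently and uniformly between the minimum and maximum
# of the observed interval range and form the ratio X/(X+Y). Repeating this
# many times (default 100 000) yields the ratio distribution a sequence with
# no rhythmic structure in its interval ordering would produce. Note that
# this null is itself unimodal around 0.5 — ratios of two comparable random
# durations cluster near equality — which is why observed data are compared
# against it rather than against a flat density.

#' Simulate the uniform null ratio distribution
#'
#' @param interval_min_s,interval_max_s Observed interval range in seconds
#'   (`0 <= min < max`).
#' @param n_draws Number of simulated ratios (default 100000).
#' @param seed Integer seed; draws are reproducible given the seed.
#' @return An object of class `null_ratio_distribution`: list with `draws`
#'   (numeric vector in (0, 1)), `interval_min_s`, `interval_max_s`,
#'   `n_draws`, `seed`.
#' @export
simulate_null_ratios <- function(interval_min_s, interval_max_s,
                                 n_draws = 100000L, seed = 1L) {
  if (!(interval_min_s >= 0 && interval_min_s < interval_max_s)) {
    stop("need 0 <= interval_min_s < interval_max_s", call. = FALSE)
  }
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  draws <- withr::with_seed(as.integer(seed), {
    x <- stats::runif(n_draws, interval_min_s, interval_max_s)
    y <- stats::runif(n_draws, interval_min_s, interval_max_s)
    x / (x + y)
  })
  structure(
    list(draws = draws, interval_min_s = interval_min_s,
         interval_max_s = interval_max_s, n_draws = as.integer(n_draws),
         seed = as.integer(seed)),
    class = "null_ratio_distribution"
  )
}

#' @export
print.null_ratio_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_ratio_distribution> %d draws, interval range [%.4g, %.4g] s, seed %d\n",
    x$n_draws, x$interval_min_s, x$interval_max_s, x$seed))
  invisible(x)
}

#' Analytic CDF of the uniform null ratio distribution
#'
#' Distribution function of R = X/(X+Y) for X, Y independent uniform on
#' `[interval_min_s, interval_max_s]`. With `interval_min_s = 0` the closed
#' form is `F(r) = r/(2(1-r))` for `r <= 1/2` and `1 - (1-r)/(2r)` for
#' `r >= 1/2`; for a positive lower bound the CDF is computed by numerical
#' integration of `P(X <= Y r/(1-r))` over Y. Intended as an oracle for
#' [simulate_null_ratios()] in validation, not as part of the analysis path.
#'
#' @param r Ratios in (0, 1) (vectorised).
#' @param interval_min_s,interval_max_s Interval range.
#' @return `P(R <= r)`.
#' @export
null_ratio_cdf <- function(r, interval_min_s = 0, interval_max_s = 1) {
  if (any(r <= 0 | r >= 1)) {
    stop("r must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!(interval_min_s >= 0 && interval_min_s < interval_max_s)) {
    stop("need 0 <= interval_min_s < interval_max_s", call. = FALSE)
  }
  if (interval_min_s == 0) {
    return(ifelse(r <= 0.5, r / (2 * (1 - r)), 1 - (1 - r) / (2 * r)))
  }
  a <- interval_min_s
  b <- interval_max_s
  vapply(r, function(ri) {
    c_ri <- ri / (1 - ri)
    stats::integrate(function(y) {
      pmin(pmax((c_ri * y - a) / (b - a), 0), 1) / (b - a)
    }, lower = a, upper = b, rel.tol = 1e-9)$value
  }, numeric(1))
}

#' Kolmogorov-Smirnov comparison of observed ratios with the null
#'
#' Two-sided asymptotic two-sample Kolmogorov-Smirnov test of the observed
#' interval ratios against the simulated uniform null: D is the supremum
#' distance between the two empirical CDFs; a small p indicates the observed
#' ratio distribution is unlikely to be a product of chance ordering of
#' intervals.
#'
#' @param observed Numeric vector of observed ratios in (0, 1).
#' @param null A `null_ratio_distribution` (or a plain numeric vector of null
#'   draws).
#' @return A one-row tibble: `test`, `statistic` (D), `p_value`, `n_observed`,
#'   `n_null`, `method`.
#' @export
ks_compare <- function(observed, null) {
  draws <- if (inherits(null, "null_ratio_distribution")) null$draws else null
  if (length(observed) == 0 || length(draws) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  kt <- suppressWarnings(
    stats::ks.test(observed, draws, alternative = "two.sided", exact = FALSE)
  )
  tibble::tibble(
    test = "ks_two_sample",
    statistic = unname(kt$statistic),
    p_value = kt$p.value,
    n_observed = length(observed),
    n_null = length(draws),
    method = "asymptotic two-sided"
  )
}

# Deterministic child seed for a named analysis subset, derived from the
# pipeline-level seed; keeps all derived seeds in 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 7919 + h) %% 2147483647)
}
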