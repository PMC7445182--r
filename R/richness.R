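#' Frequency of frequencies
#'
#' Tabulates `f_K`, the number of categories observed exactly `K` times
#' (`K >= 1`). These rare-category frequencies carry the information the
#' Chao1 estimator uses to speculate about unseen categories. By
#' construction `sum(f_K) = observed richness` and
#' `sum(K * f_K) = n_samples`.
#'
#' @param counts A [count_vector()] or bare count vector.
#' @return Named integer vector: names are `K`, values are `f_K`.
#' @examples
#' frequency_of_frequencies(c(1, 1, 2, 5))
#' @export
frequency_of_frequencies <- function(counts) {
  cv <- if (inherits(counts, "count_vector")) counts else count_vector(counts)
  obs <- cv$counts[cv$counts > 0]
  tab <- table(obs)
  ks <- sort(as.numeric(names(tab)))
  structure(stats::setNames(as.integer(tab[as.character(ks)]), ks),
            class = "freq_of_freq")
}

#' Chao1 lower-bound richness estimator
#'
#' Estimates a lower bound on the true number of categories from the
#' singleton and doubleton frequencies:
#' \deqn{\hat n_c = \Pi_0 + f_1^2 / (2 f_2)} when doubletons exist
#' (`f_2 > 0`), and \deqn{\hat n_c = \Pi_0 + f_1 (f_1 - 1) / 2} otherwise.
#' The estimate never falls below the observed richness; absent singletons
#' it collapses to it (no evidence of unseen categories).
#'
#' @param x A [count_vector()], bare counts, or a frequency-of-frequencies
#'   vector as returned by [frequency_of_frequencies()].
#' @return Point estimate (numbers equivalent) with attributes `observed`,
#'   `f1`, `f2`, and `singleton_only` (TRUE when `f_2 = 0` and `f_1 = 1`, a
#'   configuration in which the bias correction vanishes entirely).
#' @examples
#' chao1(c(1, 1, 1, 2, 5)) # 5 + 9/2 = 9.5
#' @export
chao1 <- function(x) {
  f <- if (inherits(x, "freq_of_freq")) {
    if (anyNA(x) || any(x < 0)) {
      stop_invalid("frequency-of-frequencies values must be non-negative")
    }
    x
  } else {
    frequency_of_frequencies(x)
  }
  observed <- sum(f)
  if (observed < 1) stop_invalid("observed richness must be at least 1")
  f1 <- if ("1" %in% names(f)) as.numeric(f[["1"]]) else 0
  f2 <- if ("2" %in% names(f)) as.numeric(f[["2"]]) else 0
  est <- if (f2 > 0) {
    observed + f1^2 / (2 * f2)
  } else {
    observed + f1 * (f1 - 1) / 2
  }
  structure(est, observed = observed, f1 = f1, f2 = f2,
            singleton_only = (f2 == 0 && f1 == 1))
}

#' Confidence interval for the Chao1 estimate
#'
#' The default resamples subjects (observations) with replacement,
#' re-tabulates category counts and re-estimates Chao1 in each replicate,
#' reporting a percentile interval. This mirrors the sampling process that
#' generated the data (subjects are the exchangeable unit, not categories).
#' Because resamples lose rare categories, the raw percentile interval is
#' truncated so that it always contains the point estimate and never falls
#' below the observed richness of the actual sample -- a logically certain
#' lower bound on the true richness.
#' An analytic interval using the classical Chao1 variance with
#' log-transformed bounds is available for comparison; both are documented
#' as approximations since the estimator is a lower bound, not an unbiased
#' point estimate.
#'
#' @param counts A [count_vector()] or bare counts.
#' @param level Coverage level in (0, 1).
#' @param method `"bootstrap"` (default) or `"analytic"`.
#' @param n_boot Number of bootstrap replicates (>= 2).
#' @param seed Integer seed making the bootstrap reproducible.
#' @return List with `estimate`, `lower`, `upper`, `level`, `method`.
#' @examples
#' chao1_ci(c(4, 3, 3, 1, 1, 1, 2), n_boot = 200, seed = 1)
#' @export
chao1_ci <- function(counts, level = 0.95,
                     method = c("bootstrap", "analytic"),
                     n_boot = 1000, seed = NULL) {
  method <- match.arg(method)
  cv <- if (inherits(counts, "count_vector")) counts else count_vector(counts)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop_param("`level` must be in (0, 1)")
  }
  est <- chao1(cv)
  obs <- attr(est, "observed")

  if (method == "bootstrap") {
    if (!is.numeric(n_boot) || n_boot < 2) {
      stop_param("`n_boot` must be at least 2")
    }
    prob <- cv$counts / cv$n_samples
    reps <- with_seed(seed, {
      draws <- stats::rmultinom(n_boot, size = cv$n_samples, prob = prob)
      apply(draws, 2L, function(cc) as.numeric(chao1(count_vector(cc, cv$labels))))
    })
    qs <- stats::quantile(reps, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE, type = 7)
    # resamples lose rare categories, so raw percentiles can fall below what
    # is logically certain: the true richness is at least the observed
    # richness of the actual sample, and the interval must contain the point
    # estimate (itself a valid lower bound). Truncate accordingly.
    lower <- max(obs, min(qs[1], as.numeric(est)))
    upper <- max(qs[2], as.numeric(est))
  } else {
    f1 <- attr(est, "f1"); f2 <- attr(est, "f2")
    v <- if (f2 > 0) {
      r <- f1 / f2
      f2 * (r^2 / 2 + r^3 + r^4 / 4)
    } else if (f1 > 0) {
      f1 * (f1 - 1) / 2 + f1 * (2 * f1 - 1)^2 / 4 - f1^4 / (4 * as.numeric(est))
    } else {
      0
    }
    tt <- as.numeric(est) - obs
    if (tt <= 0 || v <= 0) {
      lower <- upper <- as.numeric(est)
    } else {
      z <- stats::qnorm(1 - (1 - level) / 2)
      k <- exp(z * sqrt(log(1 + v / tt^2)))
      lower <- obs + tt / k
      upper <- obs + tt * k
    }
  }
  list(estimate = as.numeric(est), lower = lower, upper = upper,
       level = level, method = method)
}
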