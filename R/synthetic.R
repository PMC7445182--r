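#' Specification of a synthetic categorical population
#'
#' Defines a finite population of categories with a chosen abundance shape,
#' from which seeded samples can be drawn. The skewed shapes (geometric,
#' Zipf) emulate the empirical situation in which many categories are rare
#' -- the regime where observed richness is badly biased and Chao-type
#' correction matters.
#'
#' @param n_categories True richness of the population.
#' @param shape `"uniform"`, `"geometric"` (`p_i` proportional to
#'   `ratio^(i-1)`) or `"zipf"` (`p_i` proportional to `i^-exponent`).
#' @param ratio Geometric decay ratio in (0, 1).
#' @param exponent Zipf exponent, positive.
#' @return Object of class `population_spec` with the true abundance
#'   distribution in `$p`.
#' @examples
#' population_spec(50, "geometric", ratio = 0.8)
#' @export
population_spec <- function(n_categories,
                            shape = c("uniform", "geometric", "zipf"),
                            ratio = 0.5, exponent = 1) {
  shape <- match.arg(shape)
  n <- n_categories
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop_param("`n_categories` must be a positive integer")
  }
  w <- switch(shape,
    uniform = rep(1, n),
    geometric = {
      if (ratio <= 0 || ratio >= 1) stop_param("`ratio` must be in (0, 1)")
      ratio^(seq_len(n) - 1)
    },
    zipf = {
      if (exponent <= 0) stop_param("`exponent` must be positive")
      seq_len(n)^(-exponent)
    }
  )
  structure(
    list(n_categories = as.integer(n), shape = shape,
         ratio = ratio, exponent = exponent,
         p = abundance_vector(w / sum(w),
                              labels = sprintf("cat_%03d", seq_len(n)))),
    class = "population_spec"
  )
}

#' Draw a multinomial sample of category counts
#'
#' Multinomial draw of `n_samples` observations from the population's
#' abundance distribution, reproducible per seed. All population categories
#' are retained in the result (unsampled ones with count 0), so the
#' generator's truth is always recoverable from the labels.
#'
#' @param spec A [population_spec()].
#' @param n_samples Number of observations to draw.
#' @param seed Integer seed.
#' @return A [count_vector()] over all population categories.
#' @examples
#' sample_counts(population_spec(20, "geometric", ratio = 0.7), 50, seed = 1)
#' @export
sample_counts <- function(spec, n_samples, seed = NULL) {
  if (!inherits(spec, "population_spec")) {
    stop_param("`spec` must be a population_spec")
  }
  if (!is.numeric(n_samples) || n_samples < 1) {
    stop_param("`n_samples` must be at least 1")
  }
  counts <- with_seed(seed, {
    drop(stats::rmultinom(1, size = n_samples, prob = as.numeric(spec$p)))
  })
  count_vector(counts, labels = names(spec$p))
}

# does a single 0/1 profile satisfy the diagnostic criteria?
satisfies_criteria <- function(profile, criteria) {
  sum(profile) >= criteria$min_required &&
    (criteria$min_mandatory == 0L ||
       sum(profile[criteria$mandatory]) >= criteria$min_mandatory)
}

#' Sample criteria-conditioned binary symptom profiles
#'
#' Rejection-samples independent Bernoulli symptom profiles until
#' `n_subjects` rows satisfying the diagnostic criteria are collected, so
#' every subject in the result qualifies for the diagnosis. Refuses when
#' the acceptance probability is below 1e-4 (the criteria are essentially
#' unreachable under the given marginal symptom probabilities).
#'
#' @param criteria A [diagnostic_criteria()].
#' @param n_subjects Number of qualifying rows to generate.
#' @param symptom_probs Marginal probability of each symptom; length
#'   `n_symptoms`.
#' @param seed Integer seed.
#' @return Binary matrix (`n_subjects` x `n_symptoms`) with row names
#'   `subj_...` and column names `sym_...`.
#' @examples
#' gad <- diagnostic_criteria(6, 3)
#' m <- sample_symptom_profiles(gad, 20, rep(0.6, 6), seed = 7)
#' all(rowSums(m) >= 3)
#' @export
sample_symptom_profiles <- function(criteria, n_subjects, symptom_probs,
                                    seed = NULL) {
  if (!inherits(criteria, "diagnostic_criteria")) {
    stop_param("`criteria` must be a diagnostic_criteria")
  }
  n_sym <- criteria$n_symptoms
  if (length(symptom_probs) != n_sym ||
      any(symptom_probs < 0 | symptom_probs > 1)) {
    stop_param("`symptom_probs` must be ", n_sym, " probabilities")
  }
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    stop_param("`n_subjects` must be at least 1")
  }
  with_seed(seed, {
    kept <- matrix(0L, nrow = 0, ncol = n_sym)
    tried <- 0L
    while (nrow(kept) < n_subjects) {
      batch <- matrix(
        stats::rbinom(1000L * n_sym, 1L, rep(symptom_probs, each = 1000L)),
        nrow = 1000L, ncol = n_sym
      )
      ok <- apply(batch, 1L, satisfies_criteria, criteria = criteria)
      tried <- tried + 1000L
      kept <- rbind(kept, batch[ok, , drop = FALSE])
      if (tried >= 20000L && nrow(kept) / tried < 1e-4) {
        stop_invalid(
          "acceptance probability below 1e-4 under these symptom ",
          "probabilities; raise symptom_probs or relax the criteria")
      }
    }
    kept <- kept[seq_len(n_subjects), , drop = FALSE]
    dimnames(kept) <- list(sprintf("subj_%04d", seq_len(n_subjects)),
                           sprintf("sym_%d", seq_len(n_sym)))
    kept
  })
}

#' Generate grouped abundance systems with controlled overlap
#'
#' Builds `n_groups` abundance vectors over label spaces sharing a
#' controlled fraction of categories: `overlap = 0` gives completely
#' disjoint event spaces (the replication-principle fixture), `overlap = 1`
#' identical label spaces with identical distributions (the `beta = 1`
#' fixture), and intermediate values give between-group heterogeneity
#' strictly inside `(1, n_groups)`.
#'
#' Shared categories receive the same abundance in every group, so overlap
#' alone (not shape differences) drives the between-group component.
#'
#' @param n_groups Number of systems.
#' @param overlap Fraction of each group's categories shared by all groups.
#' @param spec A [population_spec()] giving each group's size and shape.
#' @return List of [abundance_vector()]s.
#' @examples
#' gs <- grouped_systems(3, 0, population_spec(4))
#' decompose_heterogeneity(gs, q = 1)$beta # 3
#' @export
grouped_systems <- function(n_groups, overlap, spec) {
  if (!is.numeric(n_groups) || n_groups < 1 || n_groups != round(n_groups)) {
    stop_param("`n_groups` must be a positive integer")
  }
  if (!is.numeric(overlap) || overlap < 0 || overlap > 1) {
    stop_param("`overlap` must be in [0, 1]")
  }
  if (!inherits(spec, "population_spec")) {
    stop_param("`spec` must be a population_spec")
  }
  n <- spec$n_categories
  n_shared <- round(overlap * n)
  p <- as.numeric(spec$p)
  lapply(seq_len(n_groups), function(g) {
    labs <- c(
      if (n_shared > 0) sprintf("shared_%03d", seq_len(n_shared)),
      if (n_shared < n) sprintf("g%d_%03d", g, seq_len(n - n_shared))
    )
    abundance_vector(p, labels = labs)
  })
}

#' Seeded multi-tone time series
#'
#' Sum of sinusoids at given bin-aligned frequencies plus optional white
#' noise: a series whose spectral content -- and hence whose effective
#' number of frequency bands -- is known by construction.
#'
#' @param n Series length.
#' @param freqs Frequencies in cycles per sample (use `k/n` for bin-aligned
#'   tones).
#' @param amps Amplitudes, recycled to `length(freqs)`.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return Numeric series of length `n`.
#' @examples
#' x <- tone_series(128, freqs = c(4, 12) / 128)
#' effective_num_frequencies(x) # 2
#' @export
tone_series <- function(n, freqs, amps = 1, noise_sd = 0, seed = NULL) {
  if (!is.numeric(n) || n < 8) stop_param("`n` must be at least 8")
  amps <- rep_len(amps, length(freqs))
  t0 <- seq_len(n) - 1
  x <- rowSums(vapply(seq_along(freqs),
                      function(i) amps[i] * sin(2 * pi * freqs[i] * t0),
                      numeric(n)))
  if (noise_sd > 0) {
    x <- x + with_seed(seed, stats::rnorm(n, sd = noise_sd))
  }
  x
}
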