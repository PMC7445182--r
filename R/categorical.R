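#' Observed richness
#'
#' The number of categories actually observed in the sample (counts or
#' abundance strictly positive). This is the simplest, most negatively
#' biased estimate of the true event-space size, and equals the Hill number
#' of order 0.
#'
#' @param x A [count_vector()], [abundance_vector()] or bare numeric vector.
#' @return Integer count of categories present.
#' @examples
#' observed_richness(c(5, 3, 2))
#' @export
observed_richness <- function(x) {
  if (inherits(x, "count_vector")) return(sum(x$counts > 0))
  sum(as_abundance(x) > 0)
}

#' Shannon entropy of a categorical distribution
#'
#' Average uncertainty in the system: with base-2 logarithms, the mean number
#' of yes/no questions needed to identify an observation's category. Terms
#' with `p_i = 0` contribute nothing (`0 log 0 := 0` by continuity).
#'
#' @param p Abundance vector (see [as_abundance()]).
#' @param base Logarithm base, greater than 1. Base 2 gives bits; `exp(1)`
#'   gives nats.
#' @return Entropy in `[0, log_base(n_c)]`.
#' @examples
#' shannon_entropy(c(0.5, 0.5), base = 2) # 1 bit
#' @export
shannon_entropy <- function(p, base = exp(1)) {
  if (!is.numeric(base) || length(base) != 1L || is.na(base) || base <= 1) {
    stop_param("`base` must be a single number greater than 1")
  }
  p <- as_abundance(p)
  pos <- p[p > 0]
  -sum(pos * log(pos, base = base))
}

#' Gini-Simpson index
#'
#' Probability that two observations sampled with replacement belong to
#' different categories; the complement of the Simpson concentration.
#'
#' @inheritParams shannon_entropy
#' @return Probability in `[0, 1 - 1/n_c]`.
#' @examples
#' gini_simpson(c(0.9, 0.1)) # 0.18
#' @export
gini_simpson <- function(p) {
  p <- as_abundance(p)
  1 - sum(p^2)
}

#' Simpson concentration
#'
#' Probability that two observations sampled with replacement belong to the
#' same category (also the Herfindahl concentration index). Satisfies
#' `simpson_concentration(p) + gini_simpson(p) == 1`.
#'
#' @inheritParams shannon_entropy
#' @return Probability in `[1/n_c, 1]`.
#' @export
simpson_concentration <- function(p) {
  p <- as_abundance(p)
  sum(p^2)
}
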