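#' Renyi heterogeneity (Hill numbers)
#'
#' The one-parameter numbers-equivalent family
#' \deqn{\Pi_q(p) = \left(\sum_i p_i^q\right)^{1/(1-q)}}
#' also known as the Hill numbers (ecology) or Hannah-Kay indices
#' (economics). The elasticity `q` tunes sensitivity to rare versus common
#' categories: `q = 0` returns the observed richness, `q -> 1` the
#' perplexity (exponential Shannon entropy, the effective number of typical
#' categories), and `q = 2` the inverse Simpson concentration (the effective
#' number of common categories). The value is always the size of a
#' hypothetical perfectly even system with the same heterogeneity, so a
#' uniform distribution over `n` categories scores exactly `n` at every `q`.
#'
#' The `q = 1` case is handled by its analytic limit whenever
#' `|q - 1| < 1e-9`, avoiding catastrophic cancellation in the exponent
#' `1/(1-q)`; all other orders are evaluated in log space so large category
#' sets neither overflow nor underflow.
#'
#' @param p Abundance vector (see [as_abundance()]).
#' @param q Non-negative elasticity order(s); vectorized.
#' @return Numbers equivalent in `[1, n_c]`, one value per element of `q`.
#' @examples
#' renyi_heterogeneity(c(0.9, 0.1), q = 2) # 1/0.82
#' renyi_heterogeneity(rep(1 / 7, 7), q = c(0, 1, 2)) # 7 7 7
#' @export
renyi_heterogeneity <- function(p, q) {
  if (!is.numeric(q) || length(q) == 0L || anyNA(q)) {
    stop_param("`q` must be numeric and non-missing")
  }
  if (any(q < 0)) stop_param("`q` must be non-negative")
  p <- as_abundance(p)
  pos <- as.numeric(p[p > 0])
  lp <- log(pos)
  vapply(q, function(qi) {
    if (qi == 0) return(length(pos))
    if (abs(qi - 1) < 1e-9) return(exp(-sum(pos * lp)))
    # log-sum-exp of q*log(p) keeps Pi_q finite for large q or tiny p
    m <- max(qi * lp)
    lse <- m + log(sum(exp(qi * lp - m)))
    exp(lse / (1 - qi))
  }, numeric(1))
}

#' Diversity profile over a grid of orders
#'
#' Evaluates the Renyi heterogeneity on a grid of elasticities. The profile
#' is non-increasing in `q` for any fixed distribution; how quickly it drops
#' from the richness (`q = 0`) towards the effective number of dominant
#' categories (large `q`) summarizes abundance inequality.
#'
#' @inheritParams renyi_heterogeneity
#' @param q_grid Sorted, non-negative orders.
#' @return A data frame of class `heterogeneity_profile` with columns `q`,
#'   `heterogeneity` (numbers equivalent) and `evenness`
#'   (heterogeneity / richness).
#' @examples
#' diversity_profile(c(0.7, 0.2, 0.1), q_grid = c(0, 1, 2))
#' @export
diversity_profile <- function(p, q_grid = c(0, 0.5, 1, 2, Inf)) {
  q_grid <- q_grid[is.finite(q_grid)]
  if (length(q_grid) == 0L) stop_param("`q_grid` must contain finite orders")
  if (is.unsorted(q_grid)) stop_param("`q_grid` must be sorted increasing")
  p <- as_abundance(p)
  vals <- renyi_heterogeneity(p, q_grid)
  structure(
    data.frame(q = q_grid, heterogeneity = vals,
               evenness = vals / n_categories(p)),
    class = c("heterogeneity_profile", "data.frame")
  )
}

#' Evenness of a distribution at order q
#'
#' Renyi heterogeneity expressed relative to its theoretical maximum (the
#' observed richness): `evenness = Pi_q(p) / n_c`, in `(0, 1]`, equal to 1
#' exactly when abundance is uniform over the support.
#'
#' @inheritParams renyi_heterogeneity
#' @return Ratio in `(0, 1]`.
#' @export
evenness <- function(p, q) {
  p <- as_abundance(p)
  renyi_heterogeneity(p, q) / n_categories(p)
}

#' Pielou's J evenness
#'
#' Shannon entropy over its maximum at the observed richness:
#' `log Pi_1 / log Pi_0`. Undefined for a single-category system.
#'
#' @inheritParams renyi_heterogeneity
#' @return Ratio in `(0, 1]`.
#' @examples
#' pielou_j(c(0.9, 0.1))
#' @export
pielou_j <- function(p) {
  p <- as_abundance(p)
  nc <- n_categories(p)
  if (nc < 2L) {
    stop_invalid("Pielou's J is undefined for a single-category system")
  }
  log(renyi_heterogeneity(p, 1)) / log(nc)
}

#' Pool several categorical systems into one
#'
#' Forms the weighted mixture over the union of the systems' label spaces:
#' `p(x) = sum_g w_g p_g(x)`. Systems sharing labels are merged on label;
#' unnamed equal-length inputs are matched positionally.
#'
#' @param systems List of abundance vectors (or inputs coercible by
#'   [as_abundance()]); names identify categories.
#' @param weights Non-negative group weights summing to 1; defaults to equal.
#' @return Pooled [abundance_vector()] over the union label space.
#' @examples
#' a <- abundance_vector(c(x1 = 0.5, x2 = 0.5))
#' b <- abundance_vector(c(y1 = 0.5, y2 = 0.5))
#' pool_systems(list(a, b)) # uniform over 4
#' @export
pool_systems <- function(systems, weights = NULL) {
  if (!is.list(systems) || length(systems) == 0L) {
    stop_param("`systems` must be a non-empty list")
  }
  systems <- lapply(systems, as_abundance)
  g <- length(systems)
  weights <- weights %||% rep(1 / g, g)
  if (length(weights) != g || any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop_param("`weights` must be ", g, " non-negative values summing to 1")
  }
  labs <- unique(unlist(lapply(systems, names)))
  pooled <- stats::setNames(numeric(length(labs)), labs)
  for (i in seq_len(g)) {
    pooled[names(systems[[i]])] <-
      pooled[names(systems[[i]])] + weights[i] * as.numeric(systems[[i]])
  }
  abundance_vector(pooled / sum(pooled), labels = labs)
}

#' Multiplicative alpha/beta/gamma heterogeneity decomposition
#'
#' Splits the pooled (gamma) heterogeneity of a grouped system into a
#' within-group component (alpha, the numbers-equivalent mean heterogeneity
#' of the groups) and a between-group component `beta = gamma / alpha`, the
#' effective number of completely distinct groups, which lies in
#' `[1, number of groups]`.
#'
#' For `q = 1`, alpha is the exponential of the weighted mean Shannon
#' entropy and any weights are admissible. For `q != 1` the multiplicative
#' decomposition is only well calibrated under equal group weights, in which
#' case \deqn{\Pi_q^\alpha = \left(\frac{1}{G}\sum_g\sum_i p_{gi}^q\right)^{1/(1-q)};}
#' unequal weights with `q != 1` raise an error rather than silently
#' approximating.
#'
#' @inheritParams pool_systems
#' @param q Single non-negative order.
#' @return Object of class `heterogeneity_decomposition`: list with `gamma`,
#'   `alpha`, `beta`, `q` and `weights`. `gamma == alpha * beta` by
#'   construction.
#' @examples
#' a <- abundance_vector(c(x1 = 0.25, x2 = 0.25, x3 = 0.25, x4 = 0.25))
#' b <- abundance_vector(c(y1 = 0.25, y2 = 0.25, y3 = 0.25, y4 = 0.25))
#' decompose_heterogeneity(list(a, b), q = 1) # gamma 8, alpha 4, beta 2
#' @export
decompose_heterogeneity <- function(systems, weights = NULL, q = 1) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0) {
    stop_param("`q` must be a single non-negative number")
  }
  systems <- lapply(systems, as_abundance)
  g <- length(systems)
  weights <- weights %||% rep(1 / g, g)
  if (length(weights) != g || any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop_param("`weights` must be ", g, " non-negative values summing to 1")
  }
  equal_w <- all(abs(weights - 1 / g) < 1e-12)
  pooled <- pool_systems(systems, weights)
  gamma <- renyi_heterogeneity(pooled, q)

  if (abs(q - 1) < 1e-9) {
    h_within <- vapply(systems, shannon_entropy, numeric(1))
    alpha <- exp(sum(weights * h_within))
  } else if (equal_w) {
    sums_q <- vapply(systems, function(p) {
      pos <- as.numeric(p[p > 0])
      if (q == 0) length(pos) else sum(pos^q)
    }, numeric(1))
    alpha <- (mean(sums_q))^(1 / (1 - q))
  } else {
    stop(errorCondition(
      paste0("numbers-equivalent decomposition with q = ", q,
             " requires equal group weights"),
      class = c("renyihet_unsupported_configuration", "error")))
  }
  structure(
    list(gamma = gamma, alpha = alpha, beta = gamma / alpha,
         q = q, weights = weights),
    class = "heterogeneity_decomposition"
  )
}

#' @export
print.heterogeneity_decomposition <- function(x, ...) {
  cat(sprintf(
    "<heterogeneity_decomposition> q = %g\n  gamma (pooled): %.6g\n  alpha (within): %.6g\n  beta (effective groups): %.6g\n",
    x$q, x$gamma, x$alpha, x$beta))
  invisible(x)
}
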