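#' Diagnostic criteria for polythetic presentations
#'
#' Describes a polythetic diagnostic rule: a presentation qualifies when it
#' contains at least `min_required` of `n_symptoms` available symptoms, and
#' at least `min_mandatory` symptoms from a designated `mandatory` subset
#' (e.g. major depression requires 5 of 9 symptoms, of which at least one of
#' two core symptoms -- low mood or loss of interest -- must be present).
#'
#' @param n_symptoms Total number of available symptoms `N`.
#' @param min_required Minimum presentation size `K`, with `0 < K <= N`.
#' @param mandatory Indices (in `1..N`) of the mandatory symptom subset.
#' @param min_mandatory Minimum count of mandatory symptoms required
#'   (0 disables the constraint).
#' @return Object of class `diagnostic_criteria`.
#' @examples
#' mdd <- diagnostic_criteria(9, 5, mandatory = c(1, 2), min_mandatory = 1)
#' count_presentations_constrained(mdd) # 227
#' @export
diagnostic_criteria <- function(n_symptoms, min_required,
                                mandatory = integer(0), min_mandatory = 0L) {
  n <- n_symptoms; k <- min_required
  if (!is.numeric(n) || !is.numeric(k) || length(n) != 1L || length(k) != 1L ||
      n != round(n) || k != round(k) || k <= 0 || k > n) {
    stop_param("need integer symptom counts with 0 < min_required <= n_symptoms")
  }
  mandatory <- as.integer(mandatory)
  if (anyDuplicated(mandatory) || any(mandatory < 1 | mandatory > n)) {
    stop_param("`mandatory` must be distinct symptom indices in 1..n_symptoms")
  }
  if (min_mandatory != round(min_mandatory) || min_mandatory < 0 ||
      min_mandatory > length(mandatory)) {
    stop_param("`min_mandatory` must be between 0 and length(mandatory)")
  }
  structure(list(n_symptoms = as.integer(n), min_required = as.integer(k),
                 mandatory = sort(mandatory),
                 min_mandatory = as.integer(min_mandatory)),
            class = "diagnostic_criteria")
}

#' Combinatorial upper bound on the number of presentations
#'
#' Counts the symptom subsets of size at least `k` drawn from `n` available
#' symptoms: \deqn{S(N, K) = \sum_{j=K}^{N} \binom{N}{j}.} This is an upper
#' bound on the true number of presentations of a polythetic diagnosis,
#' since observed data cannot exceed the combinatorially possible
#' configurations. Computed with exact integer arithmetic (binomial
#' coefficients are integers, summed in doubles which are exact below
#' 2^53).
#'
#' @param n Total available symptoms.
#' @param k Minimum number required, `0 < k <= n`.
#' @return Exact count of qualifying subsets.
#' @examples
#' count_presentations(6, 3)  # 42  (generalized anxiety disorder)
#' count_presentations(9, 5)  # 256 (borderline personality disorder)
#' count_presentations(12, 3) # 4017 (catatonia)
#' @export
count_presentations <- function(n, k) {
  if (!is.numeric(n) || !is.numeric(k) || length(n) != 1L || length(k) != 1L ||
      n != round(n) || k != round(k) || k <= 0 || k > n) {
    stop_param("need 0 < k <= n, both integers")
  }
  out <- sum(choose(n, k:n))
  if (out >= 2^53) {
    warning("count exceeds 2^53; result may lose integer precision")
  }
  out
}

#' Presentation count under a mandatory-symptom constraint
#'
#' Counts symptom subsets of size at least `min_required` that contain at
#' least `min_mandatory` members of the mandatory subset, by summing over
#' the number of mandatory symptoms included:
#' `sum_j C(M, j) * S'(N - M, max(0, K - j))` for `j >= min_mandatory`,
#' where `M` is the mandatory set size and `S'` counts unconstrained subsets
#' of the remaining symptoms (including the empty one when `K - j <= 0`).
#' With `min_mandatory = 0` this reduces to [count_presentations()].
#'
#' @param criteria A [diagnostic_criteria()] object.
#' @return Exact count of qualifying subsets.
#' @examples
#' # major depressive disorder: >= 5 of 9 symptoms, >= 1 of 2 core symptoms
#' count_presentations_constrained(
#'   diagnostic_criteria(9, 5, mandatory = c(1, 2), min_mandatory = 1)) # 227
#' @export
count_presentations_constrained <- function(criteria) {
  if (!inherits(criteria, "diagnostic_criteria")) {
    stop_param("`criteria` must be a diagnostic_criteria object")
  }
  n <- criteria$n_symptoms
  k <- criteria$min_required
  m <- length(criteria$mandatory)
  mm <- criteria$min_mandatory
  if (mm == 0L) return(count_presentations(n, k))
  rest <- n - m
  total <- 0
  for (j in mm:m) {
    need <- max(0L, k - j)
    # subsets of the non-mandatory pool of size >= need (possibly empty)
    rest_count <- if (need > rest) {
      0
    } else if (need == 0L) {
      2^rest
    } else {
      sum(choose(rest, need:rest))
    }
    total <- total + choose(m, j) * rest_count
  }
  total
}

#' Enumerate all qualifying presentations
#'
#' Brute-force enumeration of every symptom subset satisfying the criteria.
#' Serves as the independent oracle for the closed-form counts; refused for
#' more than 20 symptoms, where the 2^N subset lattice becomes impractical
#' and the closed forms should be used instead.
#'
#' @param criteria A [diagnostic_criteria()] object with `n_symptoms <= 20`.
#' @return List of integer vectors, each a qualifying symptom subset.
#' @examples
#' length(enumerate_presentations(diagnostic_criteria(6, 3))) # 42
#' @export
enumerate_presentations <- function(criteria) {
  if (!inherits(criteria, "diagnostic_criteria")) {
    stop_param("`criteria` must be a diagnostic_criteria object")
  }
  n <- criteria$n_symptoms
  if (n > 20L) {
    stop_param("enumeration refused for n_symptoms > 20; ",
               "use count_presentations_constrained() instead")
  }
  ids <- 0:(2^n - 1)
  membership <- vapply(seq_len(n),
                       function(j) bitwAnd(ids, 2^(j - 1)) > 0,
                       logical(length(ids)))
  size <- rowSums(membership)
  ok <- size >= criteria$min_required
  if (criteria$min_mandatory > 0L) {
    mand <- rowSums(membership[, criteria$mandatory, drop = FALSE])
    ok <- ok & (mand >= criteria$min_mandatory)
  }
  apply(membership[ok, , drop = FALSE], 1L, which, simplify = FALSE)
}
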