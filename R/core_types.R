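#' Construct a validated category count vector
#'
#' A count vector is the raw abundance record of a categorical system: one
#' non-negative integer count per category. Zero-count categories may be
#' retained (e.g. known-but-unobserved presentations); they are kept in the
#' label set but excluded from the observed richness and from all index sums.
#'
#' @param counts Non-negative integer-valued vector, at least one positive.
#' @param labels Optional unique category identifiers; defaults to
#'   `names(counts)` or `"1"`, `"2"`, ... if unnamed.
#'
#' @return An object of class `count_vector`: a list with elements `labels`,
#'   `counts` and `n_samples` (the total number of observations).
#' @examples
#' cv <- count_vector(c(a = 3, b = 1, c = 0))
#' cv$n_samples
#' @export
count_vector <- function(counts, labels = NULL) {
  labels <- labels %||% names(counts) %||% as.character(seq_along(counts))
  counts <- as.vector(counts)
  if (!is.numeric(counts) || length(counts) == 0L) {
    stop_invalid("`counts` must be a non-empty numeric vector")
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop_invalid("counts must be non-negative and non-missing")
  }
  if (any(counts != round(counts))) {
    stop_invalid("counts must be integer-valued")
  }
  if (sum(counts) <= 0) {
    stop_invalid("all counts are zero: a system needs at least one observation")
  }
  labels <- as.character(labels)
  if (length(labels) != length(counts)) {
    stop_invalid("`labels` and `counts` lengths differ")
  }
  if (anyDuplicated(labels)) {
    stop_invalid("category labels must be unique; duplicated: ",
                 paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  structure(
    list(labels = labels, counts = as.numeric(counts),
         n_samples = sum(counts)),
    class = "count_vector"
  )
}

#' @export
print.count_vector <- function(x, ...) {
  cat("<count_vector> ", length(x$labels), " categories, ",
      format(x$n_samples, big.mark = ","), " observations (",
      sum(x$counts > 0), " observed)\n", sep = "")
  invisible(x)
}

#' Construct a validated abundance (probability) vector
#'
#' @param p Numeric vector of category probabilities; must be non-negative
#'   and sum to 1 within `1e-12` (zeros allowed and retained).
#' @param labels Optional unique category identifiers.
#'
#' @return Named numeric vector of class `abundance_vector` with attribute
#'   `n_c`, the number of categories with positive abundance.
#' @examples
#' abundance_vector(c(0.75, 0.25, 0))
#' @export
abundance_vector <- function(p, labels = NULL) {
  labels <- labels %||% names(p) %||% as.character(seq_along(p))
  p <- as.vector(p, mode = "numeric")
  if (length(p) == 0L || anyNA(p)) {
    stop_invalid("`p` must be a non-empty numeric vector without NAs")
  }
  if (any(p < 0)) stop_invalid("abundances must be non-negative")
  if (abs(sum(p) - 1) > 1e-12) {
    stop_invalid("abundances must sum to 1 (got ", format(sum(p), digits = 15),
                 "); use normalize_counts() for raw counts")
  }
  labels <- as.character(labels)
  if (length(labels) != length(p) || anyDuplicated(labels)) {
    stop_invalid("labels must be unique and match `p` in length")
  }
  structure(stats::setNames(p, labels), n_c = sum(p > 0),
            class = "abundance_vector")
}

#' @export
print.abundance_vector <- function(x, ...) {
  cat("<abundance_vector> ", length(x), " categories (n_c = ",
      attr(x, "n_c"), " positive)\n", sep = "")
  print(stats::setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

#' Normalize counts into an abundance vector
#'
#' Divides each count by the total so the result is a probability
#' distribution over categories. Zero-count categories are retained with
#' probability 0 but are excluded from the number of positive categories
#' `n_c` (and hence from every index sum, via the `0 log 0 := 0` convention).
#'
#' @param counts A [count_vector()] or a bare non-negative numeric vector.
#' @return An [abundance_vector()].
#' @examples
#' normalize_counts(c(3, 1, 0))
#' @export
normalize_counts <- function(counts) {
  cv <- if (inherits(counts, "count_vector")) counts else count_vector(counts)
  p <- cv$counts / cv$n_samples
  # guard against accumulated rounding so downstream sums hit 1 exactly
  p <- p / sum(p)
  abundance_vector(p, labels = cv$labels)
}

#' Coerce common inputs to an abundance vector
#'
#' Accepts an existing [abundance_vector()], a [count_vector()] (which is
#' normalized), or a bare numeric vector which is interpreted as counts if it
#' contains values above 1 or integer-valued entries not summing to one, and
#' as probabilities otherwise.
#'
#' @param x Object to coerce.
#' @return An [abundance_vector()].
#' @export
as_abundance <- function(x) {
  if (inherits(x, "abundance_vector")) return(x)
  if (inherits(x, "count_vector")) return(normalize_counts(x))
  if (inherits(x, "power_spectrum")) {
    return(abundance_vector(x$power / sum(x$power),
                            labels = format(x$freqs, trim = TRUE)))
  }
  if (!is.numeric(x)) stop_invalid("cannot interpret input as abundances")
  if (abs(sum(x) - 1) <= 1e-12) abundance_vector(x) else normalize_counts(x)
}

n_categories <- function(p) sum(p > 0)

#' Tabulate distinct binary presentation profiles
#'
#' Collapses a subject-by-feature binary matrix (e.g. patients by symptoms)
#' into a count vector with one category per distinct row pattern. Category
#' labels are the canonical 0/1 string of the pattern in input column order,
#' so identical feature sets map to identical labels across runs.
#'
#' @param x Matrix or data frame with entries in `{0, 1}`; rows are subjects,
#'   columns are features.
#' @return A [count_vector()]; categories are sorted by label.
#' @examples
#' m <- rbind(c(1, 0), c(1, 0), c(0, 1))
#' tabulate_presentations(m)
#' @export
tabulate_presentations <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x) && !is.logical(x)) {
    stop_invalid("presentation matrix must be numeric 0/1")
  }
  if (anyNA(x) || !all(x %in% c(0, 1))) {
    stop_invalid("presentation matrix entries must all be 0 or 1")
  }
  patterns <- apply(x, 1L, paste0, collapse = "")
  tab <- table(patterns)
  labs <- sort(names(tab))
  count_vector(as.numeric(tab[labs]), labels = labs)
}
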