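#' Discrete metric distance matrix
#'
#' The distance function that defines a purely categorical system: distance
#' 0 within a category and 1 between any two distinct categories, i.e. no
#' within-category variation and all categories maximally and equally
#' different. Under this metric Rao's quadratic entropy reduces exactly to
#' the Gini-Simpson index.
#'
#' @param n Number of categories.
#' @param labels Optional category labels for the dimnames.
#' @return `n x n` numeric matrix with zero diagonal and unit off-diagonal.
#' @examples
#' discrete_metric(3)
#' @export
discrete_metric <- function(n, labels = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop_param("`n` must be a positive integer")
  }
  d <- matrix(1, n, n) - diag(n)
  labels <- labels %||% as.character(seq_len(n))
  dimnames(d) <- list(labels, labels)
  d
}

validate_distance_matrix <- function(d, tol = 1e-9) {
  d <- as.matrix(d)
  if (!is.numeric(d) || nrow(d) != ncol(d)) {
    stop_invalid("distance matrix must be square and numeric")
  }
  if (any(d < 0)) stop_invalid("distances must be non-negative")
  if (any(abs(diag(d)) > tol)) stop_invalid("distance matrix diagonal must be 0")
  asym <- abs(d - t(d))
  if (any(asym > tol)) {
    w <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop_invalid(sprintf(
      "distance matrix is asymmetric: worst cell (%d, %d), |D_ij - D_ji| = %g",
      w[1], w[2], max(asym)))
  }
  diag(d) <- 0
  (d + t(d)) / 2
}

#' Jaccard distance between two feature sets
#'
#' One minus the ratio of shared to pooled features:
#' `1 - |a intersect b| / |a union b|`, ranging from 0 (complete overlap)
#' to 1 (no features in common). Undefined when both sets are empty.
#'
#' @param a,b Vectors of feature identifiers (duplicates ignored).
#' @return Distance in `[0, 1]`.
#' @examples
#' jaccard_distance(c(1, 2, 3), c(2, 3, 4)) # 0.5
#' @export
jaccard_distance <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) stop_invalid("Jaccard distance undefined for two empty sets")
  1 - length(intersect(a, b)) / u
}

#' Hamming distance between two equal-length vectors
#'
#' Number of positions at which the vectors differ.
#'
#' @param a,b Equal-length vectors.
#' @return Non-negative integer count.
#' @examples
#' hamming_distance(c(1, 0, 1), c(0, 1, 1)) # 2
#' @export
hamming_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop_invalid("Hamming distance requires equal-length vectors")
  }
  sum(a != b)
}

#' Pairwise distances between binary presentation profiles
#'
#' Builds the full distance matrix between 0/1 pattern strings (as produced
#' by [tabulate_presentations()] labels), treating each pattern as the set
#' of features it switches on. Jaccard distances are undefined between two
#' all-zero patterns; such a pair errors.
#'
#' @param patterns Character vector of 0/1 strings of equal length, or a
#'   binary matrix whose rows are profiles.
#' @param metric `"jaccard"` or `"hamming"`.
#' @return Symmetric distance matrix with the patterns as dimnames.
#' @examples
#' profile_distances(c("110", "011"), metric = "hamming")
#' @export
profile_distances <- function(patterns, metric = c("jaccard", "hamming")) {
  metric <- match.arg(metric)
  if (is.matrix(patterns)) {
    m <- patterns
    rownames(m) <- apply(m, 1L, paste0, collapse = "")
  } else {
    bits <- strsplit(as.character(patterns), "")
    if (length(unique(lengths(bits))) != 1L) {
      stop_invalid("all patterns must have the same number of features")
    }
    m <- do.call(rbind, lapply(bits, as.integer))
    rownames(m) <- as.character(patterns)
  }
  if (anyNA(m) || !all(m %in% c(0, 1))) {
    stop_invalid("patterns must be binary")
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      d[i, j] <- d[j, i] <- if (metric == "hamming") {
        hamming_distance(m[i, ], m[j, ])
      } else {
        jaccard_distance(which(m[i, ] == 1), which(m[j, ] == 1))
      }
    }
  }
  d
}

#' Rao's quadratic entropy
#'
#' Abundance-weighted mean pairwise distance between categories:
#' \deqn{Q(D, p) = \sum_{ij} D_{ij} p_i p_j.} Inherits the units of `D`,
#' which is why values computed under different metrics are not directly
#' comparable, and why Q violates the replication principle (see
#' [functional_hill_number()] for its numbers-equivalent transform).
#'
#' @param d Symmetric, zero-diagonal, non-negative distance matrix. If both
#'   `d` and `p` carry names they are aligned by label.
#' @param p Abundance vector aligned with `d`.
#' @return Mean pairwise distance (units of `d`).
#' @examples
#' p <- c(0.5, 0.3, 0.2)
#' rao_quadratic_entropy(discrete_metric(3), p) # equals gini_simpson(p)
#' @export
rao_quadratic_entropy <- function(d, p) {
  p <- as_abundance(p)
  d <- validate_distance_matrix(d)
  if (nrow(d) != length(p)) {
    stop_invalid("distance matrix and abundance vector lengths differ")
  }
  if (!is.null(rownames(d)) && !is.null(names(p)) &&
      !identical(rownames(d), names(p))) {
    if (!setequal(rownames(d), names(p))) {
      stop_invalid("distance matrix labels do not match abundance labels")
    }
    d <- d[names(p), names(p)]
  }
  pv <- as.numeric(p)
  drop(pv %*% d %*% pv)
}

#' Functional Hill numbers
#'
#' Numbers-equivalent transform of Rao's quadratic entropy: the effective
#' number of equally abundant, equally distinct categories with the same
#' mean pairwise distance. For `q != 1`
#' \deqn{{}^qFH = \left(\sum_{ij} \frac{D_{ij} (p_i p_j)^q}{Q}\right)^{\frac{1}{2(1-q)}}}
#' with the `q = 1` case by its analytic limit. A system in perfect
#' conformity (`Q = 0`) is defined to have one effective category.
#'
#' Note a structural limitation inherited from the Q-normalized form: when
#' abundances are exactly uniform the value equals the number of categories
#' regardless of the structure of `D`, i.e. the index is insensitive to
#' distance under equal abundance. The test suite demonstrates this rather
#' than hiding it.
#'
#' @inheritParams rao_quadratic_entropy
#' @param q Non-negative order.
#' @return Numbers equivalent `>= 1`.
#' @export
functional_hill_number <- function(d, p, q) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0) {
    stop_param("`q` must be a single non-negative number")
  }
  p <- as_abundance(p)
  qq <- rao_quadratic_entropy(d, p)
  if (qq <= 0) return(1)
  d <- validate_distance_matrix(d)
  if (!is.null(rownames(d)) && !is.null(names(p)) &&
      setequal(rownames(d), names(p))) {
    d <- d[names(p), names(p)]
  }
  keep <- as.numeric(p) > 0
  dm <- d[keep, keep, drop = FALSE]
  pv <- as.numeric(p)[keep]
  pp <- outer(pv, pv)
  if (abs(q - 1) < 1e-9) {
    exp(-0.5 * sum(dm * pp / qq * log(pp)))
  } else {
    (sum(dm * pp^q) / qq)^(1 / (2 * (1 - q)))
  }
}

#' Convex-hull area of a point cloud
#'
#' Area (2-D) or range length (1-D) of the convex hull enclosing the
#' points, an extreme-point heterogeneity index: it grows with any outlying
#' point and ignores how densely the interior is populated. Supported for
#' one- and two-dimensional coordinates, which covers the planar settings
#' where this index is typically illustrated and critiqued.
#'
#' @param points Numeric matrix (rows = observations, columns = coordinates)
#'   with at least `d + 1` rows.
#' @return Hull volume in coordinate units^d, with attribute `degenerate`
#'   set (and a warning emitted) when the configuration is flat.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' convex_hull_volume(sq) # 1
#' @export
convex_hull_volume <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || anyNA(points)) {
    stop_invalid("`points` must be a numeric matrix without NAs")
  }
  d <- ncol(points)
  if (nrow(points) < d + 1) {
    stop_invalid("need at least d + 1 points for a d-dimensional hull")
  }
  if (d == 1L) {
    vol <- diff(range(points))
  } else if (d == 2L) {
    h <- grDevices::chull(points[, 1], points[, 2])
    xs <- points[h, 1]; ys <- points[h, 2]
    # shoelace formula over the hull polygon
    vol <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  } else {
    stop_param("convex_hull_volume supports 1- or 2-dimensional coordinates")
  }
  degenerate <- vol <= .Machine$double.eps * max(1, sum(abs(points)))
  if (degenerate) {
    warning("degenerate (flat) configuration: hull volume is zero")
    vol <- 0
  }
  structure(vol, degenerate = degenerate)
}

#' Dendrogram branch-length functional diversity
#'
#' Builds an agglomerative tree from a pairwise distance matrix and sums
#' all its branch lengths -- a density-sensitive heterogeneity index. In
#' contrast to the convex hull it is not monotone under point addition:
#' making groups more similar increases the index.
#'
#' @inheritParams rao_quadratic_entropy
#' @param linkage Agglomeration rule: `"upgma"` (average linkage, the
#'   default in the functional-diversity literature), `"single"` or
#'   `"complete"`.
#' @return Total branch length in the units of `d`.
#' @examples
#' dendrogram_fd(rbind(c(0, 3), c(3, 0))) # 3: two branches of 1.5
#' @export
dendrogram_fd <- function(d, linkage = c("upgma", "single", "complete")) {
  linkage <- match.arg(linkage)
  d <- validate_distance_matrix(d)
  if (nrow(d) < 2L) {
    warning("functional diversity of a single item is 0")
    return(0)
  }
  method <- c(upgma = "average", single = "single", complete = "complete")[linkage]
  hc <- stats::hclust(stats::as.dist(d), method = method)
  phy <- ape::as.phylo(hc)
  sum(phy$edge.length)
}
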