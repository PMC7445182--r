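#' Lorenz curve of an abundance distribution
#'
#' Cumulative-share curve with categories sorted most-abundant first: the
#' point `(x, y)` says that the top `x` fraction of categories accounts for
#' the `y` fraction of all observations. Under this ordering the curve runs
#' from (0, 0) to (1, 1), lies on or above the diagonal, and is concave; the
#' diagonal itself is the line of perfect equality. (The classical
#' economics convention sorts ascending, which mirrors the curve below the
#' diagonal; both orderings give identical Gini and Pietra values.)
#'
#' Unlike the entropy-family indices, zero-abundance categories are kept:
#' they are genuine categories holding none of the abundance, and the
#' stated vertex geometry (and the population principle) depends on them
#' counting toward the category axis.
#'
#' @param p Abundance vector (see [as_abundance()]).
#' @return Data frame of class `lorenz_curve` with vertex columns `x`
#'   (cumulative proportion of categories) and `y` (cumulative proportion of
#'   observations).
#' @examples
#' lorenz_curve(c(0.5, 0.3, 0.2))
#' @export
lorenz_curve <- function(p) {
  p <- as_abundance(p)
  shares <- sort(as.numeric(p), decreasing = TRUE)
  n <- length(shares)
  structure(
    data.frame(x = (0:n) / n, y = c(0, cumsum(shares) / sum(shares))),
    class = c("lorenz_curve", "data.frame")
  )
}

#' @export
plot.lorenz_curve <- function(x, ...) {
  graphics::plot(x$x, x$y, type = "l",
                 xlab = "cumulative proportion of categories",
                 ylab = "cumulative proportion of observations", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Gini coefficient of abundance inequality
#'
#' Ratio of the area between the Lorenz curve and the line of perfect
#' equality to the total area between the diagonal and the axis of perfect
#' inequality. Computed geometrically from the piecewise-linear Lorenz
#' curve via trapezoids: `G = 2 * AUC - 1` under the descending-sort
#' convention. Zero iff abundance is uniform over the support; invariant to
#' the number of categories given the shape of the distribution (population
#' principle).
#'
#' @inheritParams lorenz_curve
#' @return Ratio in `[0, 1)`.
#' @examples
#' gini_coefficient(rep(0.25, 4)) # 0
#' gini_coefficient(c(1, 0))      # 0.5
#' @export
gini_coefficient <- function(p) {
  lc <- lorenz_curve(p)
  auc <- sum(diff(lc$x) * (utils::head(lc$y, -1) + utils::tail(lc$y, -1)) / 2)
  2 * auc - 1
}

#' Pietra index (maximum Lorenz gap)
#'
#' Maximum vertical distance from the Lorenz curve to the line of perfect
#' equality; equivalently the proportion of total abundance that would need
#' to be transferred from the most common to the least common categories to
#' reach perfect equality (half the total variation distance from uniform).
#'
#' @inheritParams lorenz_curve
#' @return Ratio in `[0, 1)`.
#' @export
pietra_index <- function(p) {
  lc <- lorenz_curve(p)
  max(lc$y - lc$x)
}

#' Smallest category share accounting for a given sample share
#'
#' With categories sorted most-abundant first, returns the smallest
#' fraction of categories whose cumulative abundance reaches at least
#' `sample_share` -- e.g. "half of all observed presentations are
#' attributable to x% of the symptom combinations".
#'
#' @inheritParams lorenz_curve
#' @param sample_share Target cumulative abundance in `(0, 1]`.
#' @return Fraction of (positive-abundance) categories in `(0, 1]`.
#' @examples
#' share_accounting(c(0.6, 0.3, 0.1), 0.5) # 1/3: the top category suffices
#' @export
share_accounting <- function(p, sample_share) {
  if (!is.numeric(sample_share) || length(sample_share) != 1L ||
      sample_share <= 0 || sample_share > 1) {
    stop_param("`sample_share` must be in (0, 1]")
  }
  p <- as_abundance(p)
  shares <- sort(as.numeric(p), decreasing = TRUE)
  cum <- cumsum(shares)
  k <- which(cum >= sample_share - 1e-12)[1]
  k / length(shares)
}
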