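#' Normalized power spectrum of a time series
#'
#' Plain periodogram over the positive-frequency bins, normalized to sum
#' to 1 so the spectrum can be treated as an abundance distribution over
#' frequency bands. The series is always mean-centered; an optional linear
#' detrend and Hann window are available. Normalization makes every
#' downstream summary invariant to overall amplitude scaling of the input.
#'
#' @param x Numeric series of length at least 8.
#' @param detrend Remove a least-squares linear trend before transforming.
#' @param window `"none"` (default) or `"hann"`. Bin-aligned tones need no
#'   window; windowing trades leakage for resolution on off-bin content.
#' @return Object of class `power_spectrum`: list with `freqs` (cycles per
#'   sample, `k/n` for `k = 1..floor(n/2)`), `power` (summing to 1) and
#'   `normalized = TRUE`.
#' @examples
#' s <- normalized_spectrum(sin(2 * pi * 4 * (0:63) / 64))
#' s$freqs[which.max(s$power)] # 4/64
#' @export
normalized_spectrum <- function(x, detrend = FALSE,
                                window = c("none", "hann")) {
  window <- match.arg(window)
  x <- as.numeric(x)
  if (length(x) < 8L || anyNA(x)) {
    stop_invalid("series must be numeric, NA-free and of length >= 8")
  }
  if (stats::sd(x) == 0) {
    stop_invalid("constant series has no defined normalized spectrum")
  }
  n <- length(x)
  scale0 <- stats::sd(x)
  if (detrend) {
    t0 <- seq_len(n)
    x <- stats::residuals(stats::lm(x ~ t0))
    if (stats::sd(x) <= 1e-10 * scale0) {
      stop_invalid("series is a pure linear trend: nothing left to analyze ",
                   "after detrending")
    }
  }
  x <- x - mean(x)
  if (window == "hann") {
    x <- x * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  }
  pw <- Mod(stats::fft(x))^2
  keep <- 2:(floor(n / 2) + 1) # positive frequencies, DC excluded
  pw <- pw[keep]
  tot <- sum(pw)
  if (tot <= 0) stop_invalid("series has no spectral power after detrending")
  structure(
    list(freqs = (keep - 1) / n, power = pw / tot, normalized = TRUE),
    class = "power_spectrum"
  )
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat("<power_spectrum> ", length(x$freqs), " positive-frequency bins; ",
      "effective number of bands: ",
      format(effective_num_frequencies(x), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Spectral entropy
#'
#' Shannon entropy of the normalized power spectrum: low for a pure tone
#' (all power in one band), maximal for white noise (flat spectrum).
#'
#' @param x A `power_spectrum` or a numeric series (transformed with
#'   defaults).
#' @param base Logarithm base; 2 (default) gives bits.
#' @return Entropy in `[0, log_base(number of bins)]`.
#' @export
spectral_entropy <- function(x, base = 2) {
  s <- if (inherits(x, "power_spectrum")) x else normalized_spectrum(x)
  shannon_entropy(as_abundance(s), base = base)
}

#' Effective number of frequency bands
#'
#' The exponential of the spectral entropy, i.e. the order-1 Renyi
#' heterogeneity of the normalized power spectrum: the number of equal-power
#' frequency bands that would carry the same spectral uncertainty. A pure
#' tone scores 1; a flat spectrum over M bins scores M. This shares the
#' numbers-equivalent code path of [renyi_heterogeneity()] exactly.
#'
#' @inheritParams spectral_entropy
#' @return Numbers equivalent in `[1, number of bins]`.
#' @examples
#' t <- (0:127) / 128
#' effective_num_frequencies(sin(2 * pi * 8 * t)) # 1
#' @export
effective_num_frequencies <- function(x) {
  s <- if (inherits(x, "power_spectrum")) x else normalized_spectrum(x)
  renyi_heterogeneity(as_abundance(s), q = 1)
}
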