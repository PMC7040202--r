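#' First-order intensity features of a VOI
#'
#' Sixteen statistics of the raw intensity distribution inside the VOI.
#' Moments use the population convention (variance with divisor n),
#' skewness is Fisher's (third standardized moment) and kurtosis is
#' non-excess (a normal distribution scores 3). Entropy (base-2) and
#' uniformity are computed on the equal-width discretized histogram
#' (`n_levels` bins over the VOI range); percentiles use linear
#' interpolation. For a constant VOI the standardized moments are defined
#' as 0.
#'
#' @param img an [image_volume].
#' @param mask the paired [mask_volume].
#' @param n_levels histogram bins for entropy/uniformity (default 32).
#' @return named numeric vector of 16 features.
#' @export
first_order_features <- function(img, mask, n_levels = 32L) {
  validate_pair(img, mask)
  x <- voi_values(img, mask)
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 else 0
  dis <- discretize(img, mask, n_levels)
  p <- tabulate(dis$levels[!is.na(dis$levels)], nbins = dis$n_levels) / n
  p <- p[p > 0]
  q <- stats::quantile(x, c(0.1, 0.5, 0.9), names = FALSE)
  c(minimum = min(x),
    maximum = max(x),
    mean = mu,
    median = q[2],
    range = max(x) - min(x),
    variance = m2,
    standard_deviation = sqrt(m2),
    skewness = skew,
    kurtosis = kurt,
    energy = sum(x^2),
    entropy = -sum(p * log2(p)),
    uniformity = sum(p^2),
    mean_absolute_deviation = mean(abs(x - mu)),
    root_mean_square = sqrt(mean(x^2)),
    percentile_10 = q[1],
    percentile_90 = q[3])
}
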