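firstorder_feature_names <- c(
  "Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
  "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
  "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
  "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity")

#' First-order intensity features
#'
#' The 18 first-order statistics of the in-mask intensity distribution.
#' Entropy and Uniformity are computed on the discretized gray levels;
#' all other statistics use the raw intensities. Percentiles use linear
#' interpolation between order statistics (R quantile type 7). Central
#' moments use the population (1/N) convention; Skewness and Kurtosis of
#' a constant region are defined as 0 so that degenerate inputs stay
#' finite.
#'
#' @param volume A [volume3d()].
#' @param mask A [voi_mask()] on the same grid.
#' @param scheme A [discretization_scheme()] for Entropy/Uniformity.
#' @return A 1-row tibble with 18 columns named `firstorder/<name>`.
#' @export
first_order_features <- function(volume, mask,
                                 scheme = discretization_scheme()) {
  check_same_grid(volume, mask)
  x <- volume$data[mask$data]
  n <- length(x)
  vvox <- prod(mask$spacing)
  q <- quantile(x, c(0.10, 0.25, 0.75, 0.90), type = 7, names = FALSE)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  rx <- x[x >= q[1] & x <= q[4]]
  # tiny VOIs can leave the 10-90 percentile window empty
  rmad <- if (length(rx) > 0) mean(abs(rx - mean(rx))) else 0
  qv <- discretize(volume, mask, scheme)
  p <- tabulate(qv$levels[qv$mask$data], nbins = qv$ng) / n
  p <- p[p > 0]
  vals <- c(
    Energy = sum(x^2),
    TotalEnergy = vvox * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[4],
    Maximum = max(x),
    Mean = mu,
    Median = median(x),
    InterquartileRange = q[3] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = rmad,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
  as_feature_row(vals, "firstorder")
}

# named numeric -> 1-row tibble with family-prefixed names
as_feature_row <- function(vals, family) {
  names(vals) <- paste0(family, "/", names(vals))
  as_tibble(as.list(vals))
}
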