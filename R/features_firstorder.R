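#' First-order intensity features
#'
#' The 18 standard first-order features over the raw VOI intensities, with
#' Entropy and Uniformity computed on the discretized gray levels. Moments
#' are population moments; Kurtosis is not excess-corrected (a normal
#' distribution scores 3). Degenerate conventions: Skewness and Kurtosis of
#' a constant VOI are 0, Entropy 0, Uniformity 1.
#'
#' @param values numeric vector of raw VOI intensities (nonempty).
#' @param levels integer vector of discretized gray levels (same length).
#' @param spacing voxel spacing in mm (for TotalEnergy).
#' @return Named numeric vector of 18 features, names prefixed `FO_`.
#' @export
first_order_features <- function(values, levels, spacing = c(1, 1, 1)) {
  stopifnot(length(values) > 0, length(levels) == length(values))
  n <- length(values)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)
  p <- tabulate(levels)
  p <- p[p > 0] / n
  q <- stats::quantile(values, c(0.10, 0.25, 0.50, 0.75, 0.90),
                       names = FALSE, type = 7)
  inner <- values[values >= q[1] & values <= q[5]]
  energy <- sum(values^2)
  out <- c(
    Energy = energy,
    TotalEnergy = prod(spacing) * energy,
    Entropy = -sum(p * log2(p + .eps)),
    Minimum = min(values),
    Percentile10 = q[1],
    Percentile90 = q[5],
    Maximum = max(values),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(values) - min(values),
    MeanAbsoluteDeviation = mean(abs(values - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(inner) > 0) mean(abs(inner - mean(inner))) else 0,
    RootMeanSquared = sqrt(mean(values^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
  names(out) <- paste0("FO_", names(out))
  out
}
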