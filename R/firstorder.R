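# First-order features: raw-intensity minimum/maximum/mean/standard
# deviation, and skewness of the discretised level histogram.

#' Raw first-order intensity features
#'
#' Population statistics over the masked voxels: minimum, maximum, mean and
#' the population (1/N) standard deviation. These are computed on raw
#' intensities and are therefore identical under every settings profile (no
#' preprocessing is applied), unlike the discretisation-dependent histogram
#' and texture features.
#'
#' @param vm A [volume_with_mask()].
#' @return Named list: `minimum`, `maximum`, `mean`, `standard_deviation`.
#' @examples
#' vm <- volume_with_mask(array(c(2, 4, 4, 4, 5, 5, 7, 9), c(2, 2, 2)),
#'                        array(TRUE, c(2, 2, 2)))
#' first_order(vm)  # mean 5, population SD 2
#' @export
first_order <- function(vm) {
  x <- masked_values(vm)
  n <- length(x)
  mu <- mean(x)
  list(minimum = min(x), maximum = max(x), mean = mu,
       standard_deviation = sqrt(sum((x - mu)^2) / n))
}

#' Skewness of the discretised intensity histogram
#'
#' Population skewness `m3 / m2^(3/2)` of the grey-level values over the
#' masked voxels. A degenerate (single-level) discretisation returns 0 by
#' convention, with a warning, to avoid 0/0.
#'
#' @param disc A [discretise()] result.
#' @return Dimensionless skewness.
#' @export
discretised_skewness <- function(disc) {
  stopifnot(inherits(disc, "discretised_roi"))
  g <- as.numeric(disc$levels[disc$mask])
  m2 <- mean((g - mean(g))^2)
  if (disc$degenerate || m2 == 0) {
    if (disc$degenerate)
      warning("degenerate discretisation: skewness set to 0 by convention",
              call. = FALSE)
    return(0)
  }
  mean((g - mean(g))^3) / m2^(3 / 2)
}
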