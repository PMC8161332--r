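#' Potential density anomaly from potential temperature and salinity
#'
#' Computes the potential density anomaly \eqn{\sigma_\theta} (kg/m3,
#' referenced to surface pressure) with the UNESCO 1983 / EOS-80
#' one-atmosphere equation of state (Millero & Poisson polynomial). Because
#' the inputs are potential temperature and the reference pressure is the
#' surface, the density term at pressure zero is all that is needed.
#'
#' @param theta Potential temperature in degrees Celsius (-2 to 40).
#' @param salinity Practical salinity, PSU (0 to 42, exclusive of 0).
#' @return Numeric vector of \eqn{\sigma_\theta} values, kg/m3.
#' @examples
#' compute_sigma_theta(5, 35) # ~27.675
#' @export
compute_sigma_theta <- function(theta, salinity) {
  if (length(theta) != length(salinity)) {
    abort("`theta` and `salinity` must have the same length.")
  }
  bad <- !is.finite(theta) | !is.finite(salinity) |
    theta < -2 | theta > 40 | salinity <= 0 | salinity > 42
  if (any(bad)) {
    abort(sprintf(
      "theta/salinity out of EOS-80 domain (theta in [-2, 40], 0 < S <= 42) at %d value(s).",
      sum(bad)
    ))
  }
  t <- theta
  # Density of pure water (kg/m3), SMOW polynomial.
  rho_w <- 999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 +
    1.001685e-4 * t^3 - 1.120083e-6 * t^4 + 6.536332e-9 * t^5
  a <- 8.24493e-1 - 4.0899e-3 * t + 7.6438e-5 * t^2 -
    8.2467e-7 * t^3 + 5.3875e-9 * t^4
  b <- -5.72466e-3 + 1.0227e-4 * t - 1.6546e-6 * t^2
  c0 <- 4.8314e-4
  rho <- rho_w + a * salinity + b * salinity^1.5 + c0 * salinity^2
  rho - 1000
}
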