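# Internal numeric helpers shared across modules.

# Half-up rounding (the convention used for printed percentages); base R
# round() is half-to-even. Small epsilon guards against 0.49999... artefacts
# of binary floats.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Format a proportion as a printed percentage
#'
#' Converts a proportion in \[0, 1\] to a percentage rounded half-up to one
#' decimal place, the convention used in published anaemia-management tables
#' (49/75 prints as 65.3, 53/75 as 70.7).
#'
#' @param p numeric vector of proportions.
#' @param digits decimal places to keep (default 1).
#' @return numeric vector of percentages.
#' @export
#' @examples
#' percent(49 / 75) # 65.3
#' percent(7 / 75)  # 9.3
percent <- function(p, digits = 1) {
  round_half_up(100 * p, digits)
}

# Moments of a normal truncated to (lo, hi).
tnorm_moments <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  Z <- pnorm(b) - pnorm(a)
  da <- dnorm(a)
  db <- dnorm(b)
  m <- mu + sd * (da - db) / Z
  v <- sd^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(mean = m, var = max(v, 0))
}

# Inverse-CDF sampler for the truncated normal (no rejection, so the draw
# count per patient is fixed and substreams stay aligned).
rtnorm <- function(n, mu, sd, lo, hi) {
  plo <- pnorm((lo - mu) / sd)
  phi <- pnorm((hi - mu) / sd)
  qnorm(runif(n, plo, phi)) * sd + mu
}

# Lognormal draws parameterized by arithmetic mean and SD.
rlnorm_ms <- function(n, mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  if (sd == 0) return(rep(mean, n))
  s2 <- log(1 + (sd / mean)^2)
  rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
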