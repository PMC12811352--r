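#' Wrap angles into (-pi, pi]
#'
#' @param x numeric vector of angles (radians).
#' @return angles wrapped into the interval (-pi, pi].
#' @export
wrap_angle <- function(x) {
  x - 2 * pi * ceiling((x - pi) / (2 * pi))
}

#' State-dependent step-length density
#'
#' Gamma density parameterised by mean and standard deviation (shape
#' \eqn{\mu^2/\sigma^2}, scale \eqn{\sigma^2/\mu}), with an optional
#' point mass at zero for intervals with no displacement (haulouts).
#'
#' @param l step lengths (km per interval), must be >= 0.
#' @param mu mean step length (> 0).
#' @param sigma step-length standard deviation (> 0).
#' @param zeromass probability mass on exactly zero steps, in [0, 1).
#' @return density values; at `l == 0` the zero mass itself is returned.
#' @export
step_density <- function(l, mu, sigma, zeromass = 0) {
  if (any(l < 0, na.rm = TRUE)) stop("step lengths must be non-negative")
  stopifnot(mu > 0, sigma > 0, zeromass >= 0, zeromass < 1)
  out <- ifelse(l == 0, zeromass,
                (1 - zeromass) * dgamma(l, shape = mu^2 / sigma^2,
                                        scale = sigma^2 / mu))
  out
}

#' Wrapped Cauchy turn-angle density
#'
#' Density of the wrapped Cauchy distribution with mean angle 0 and
#' concentration `gamma` on (-pi, pi]. `gamma = 0` gives the circular
#' uniform; `gamma -> 1` concentrates at 0. Angles outside (-pi, pi] are
#' wrapped first.
#'
#' @param phi turn angles (radians).
#' @param gamma concentration parameter in [0, 1).
#' @return density values.
#' @export
angle_density <- function(phi, gamma) {
  stopifnot(gamma >= 0, gamma < 1)
  phi <- wrap_angle(phi)
  (1 - gamma^2) / (2 * pi * (1 + gamma^2 - 2 * gamma * cos(phi)))
}

#' Wrapped Cauchy cumulative distribution on (-pi, pi]
#'
#' Closed-form CDF (measured from -pi) used for pseudo-residuals.
#'
#' @inheritParams angle_density
#' @return probabilities in [0, 1].
#' @export
angle_cdf <- function(phi, gamma) {
  stopifnot(gamma >= 0, gamma < 1)
  phi <- wrap_angle(phi)
  out <- 0.5 + atan(((1 + gamma) / (1 - gamma)) * tan(phi / 2)) / pi
  # tan(phi/2) overflows exactly at phi = pi; the limit is 1
  out[phi == pi] <- 1
  out
}

#' Sample wrapped Cauchy turn angles (mean 0)
#'
#' @param n number of draws.
#' @inheritParams angle_density
#' @return angles in (-pi, pi].
#' @export
rwcauchy <- function(n, gamma) {
  stopifnot(gamma >= 0, gamma < 1)
  if (gamma == 0) return(runif(n, -pi, pi))
  wrap_angle(rcauchy(n, location = 0, scale = -log(gamma)))
}

#' Sample step lengths from the state-dependent distribution
#'
#' @inheritParams step_density
#' @param n number of draws.
#' @return non-negative step lengths; exact zeros occur with probability
#'   `zeromass`.
#' @export
rstep <- function(n, mu, sigma, zeromass = 0) {
  stopifnot(mu > 0, sigma > 0, zeromass >= 0, zeromass < 1)
  l <- rgamma(n, shape = mu^2 / sigma^2, scale = sigma^2 / mu)
  if (zeromass > 0) l[runif(n) < zeromass] <- 0
  l
}

# mixed step CDF (atom at zero handled with a mid-distribution transform)
step_cdf <- function(l, mu, sigma, zeromass = 0) {
  ifelse(l == 0, 0.5 * zeromass,
         zeromass + (1 - zeromass) * pgamma(l, shape = mu^2 / sigma^2,
                                            scale = sigma^2 / mu))
}
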