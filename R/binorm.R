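# Bivariate standard-normal orthant probabilities.
#
# Evaluated by one-dimensional quadrature of
#   P(X > h, Y > k) = int_h^Inf dnorm(x) * pnorm((k - rho*x)/sqrt(1-rho^2),
#                                                lower.tail = FALSE) dx,
# which is accurate to ~1e-10 with stats::integrate and underlies both the
# tetrachoric correlation and the Gaussian-copula dependence calibration.

pbinorm_upper <- function(h, k, rho) {
  stopifnot(length(h) == 1L, length(k) == 1L, length(rho) == 1L)
  if (!is.finite(rho) || abs(rho) > 1) stop("`rho` must lie in [-1, 1]")
  if ((is.infinite(h) && h > 0) || (is.infinite(k) && k > 0)) return(0)
  if (is.infinite(h)) return(pnorm(k, lower.tail = FALSE))
  if (is.infinite(k)) return(pnorm(h, lower.tail = FALSE))
  if (rho == 1) return(pnorm(max(h, k), lower.tail = FALSE))
  if (rho == -1) return(max(0, 1 - pnorm(h) - pnorm(k)))
  s <- sqrt(1 - rho^2)
  f <- function(x) dnorm(x) * pnorm((k - rho * x) / s, lower.tail = FALSE)
  integrate(f, lower = h, upper = Inf,
            rel.tol = 1e-10, abs.tol = 1e-13, stop.on.error = TRUE)$value
}

# P(X < a, Y < b); equals the upper orthant of (-X, -Y), same correlation.
pbinorm_lower <- function(a, b, rho) pbinorm_upper(-a, -b, rho)

# Bivariate standard-normal density, used for delta-method standard errors
# (Plackett's identity: d/drho P(X>h, Y>k) = phi2(h, k; rho)).
dbinorm <- function(h, k, rho) {
  s2 <- 1 - rho^2
  exp(-(h^2 - 2 * rho * h * k + k^2) / (2 * s2)) / (2 * pi * sqrt(s2))
}
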