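# Independent oracles used across the suite. These deliberately avoid the
# package's own quadrature/sampling code paths.

# Upper-orthant probability P(X > h, Y > k) of a standard bivariate normal by
# plain 2-D midpoint-rule summation of the joint density.
riemann_orthant <- function(h, k, rho, upper = 8, n_grid = 700) {
  dx <- (upper - h) / n_grid
  dy <- (upper - k) / n_grid
  xs <- h + (seq_len(n_grid) - 0.5) * dx
  ys <- k + (seq_len(n_grid) - 0.5) * dy
  s2 <- 1 - rho^2
  gx <- matrix(xs, n_grid, n_grid)
  gy <- matrix(ys, n_grid, n_grid, byrow = TRUE)
  dens <- exp(-(gx^2 - 2 * rho * gx * gy + gy^2) / (2 * s2)) /
    (2 * pi * sqrt(s2))
  sum(dens) * dx * dy
}

# Generate data from the PSSA model itself: probit outcome on markers,
# conditionally independent sources with fixed Sn/Sp.
selfgen_pssa_data <- function(n, k, alpha0, alpha, sn1, sp1, sn2, sp2,
                              marker_prev = 0.25, seed = 1) {
  set.seed(seed)
  x <- matrix(rbinom(n * k, 1L, marker_prev), n, k)
  pi <- pnorm(alpha0 + drop(x %*% rep(alpha, length.out = k)))
  d <- rbinom(n, 1L, pi)
  y1 <- rbinom(n, 1L, ifelse(d == 1L, sn1, 1 - sp1))
  y2 <- rbinom(n, 1L, ifelse(d == 1L, sn2, 1 - sp2))
  list(x = x, d = d, y1 = y1, y2 = y2)
}

# Brute-force posterior for the intercept-only PSSA model on a tiny dataset:
# quadrature over prior-quantile grids (equal prior mass per node, so prior
# weights drop out) of the accuracy parameters, with a fine inner grid over
# the probit intercept, and the Sn + Sp > 1 truncation applied as in the
# sampler. Returns the posterior mean of mean_i P(D_i = 1 | y_i, theta), the
# quantity the Gibbs prevalence chain estimates. Log-likelihoods are rescaled
# online to avoid underflow.
grid_posterior_prevalence <- function(y1, y2, coef_sd = 10,
                                      sn_shape = c(2, 1), sp_shape = c(2, 1),
                                      n_grid_acc = 17, n_grid_a0 = 501) {
  ua <- (seq_len(n_grid_a0) - 0.5) / n_grid_a0
  a0 <- qnorm(ua, 0, coef_sd)
  ub <- (seq_len(n_grid_acc) - 0.5) / n_grid_acc
  sn <- qbeta(ub, sn_shape[1], sn_shape[2])
  sp <- qbeta(ub, sp_shape[1], sp_shape[2])
  th <- expand.grid(sn1 = sn, sp1 = sp, sn2 = sn, sp2 = sp)
  th <- th[(th$sn1 + th$sp1 > 1) & (th$sn2 + th$sp2 > 1), ]

  nv <- c(sum(y1 & y2), sum(y1 & !y2), sum(!y1 & y2), sum(!y1 & !y2))
  n <- length(y1)
  l1 <- cbind(th$sn1 * th$sn2, th$sn1 * (1 - th$sn2),
              (1 - th$sn1) * th$sn2, (1 - th$sn1) * (1 - th$sn2))
  l0 <- cbind((1 - th$sp1) * (1 - th$sp2), (1 - th$sp1) * th$sp2,
              th$sp1 * (1 - th$sp2), th$sp1 * th$sp2)

  num <- 0
  den <- 0
  shift <- -Inf
  for (a in seq_along(a0)) {
    pi <- pnorm(a0[a])
    mix <- pi * l1 + (1 - pi) * l0
    ll <- as.vector(log(pmax(mix, 1e-300)) %*% nv)
    m <- max(ll)
    if (m > shift) {
      scale <- exp(shift - m)
      num <- num * scale
      den <- den * scale
      shift <- m
    }
    w <- exp(ll - shift)
    pd <- as.vector((pi * l1 / pmax(mix, 1e-300)) %*% nv) / n
    num <- num + sum(w * pd)
    den <- den + sum(w)
  }
  num / den
}

# A small observed-sources object from explicit vectors.
src <- function(y1, y2) observed_sources(y1, y2)
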