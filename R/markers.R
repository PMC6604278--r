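#' Build a marker correlation matrix
#'
#' Constructs the latent-scale correlation matrix for a panel of binary
#' disease markers. With the exchangeable pattern every off-diagonal equals
#' `corr_mean`. With the unstructured pattern the off-diagonals are drawn
#' uniformly on `[max(0, corr_mean - 0.15), min(0.95, corr_mean + 0.15)]` and
#' the matrix is projected to the nearest positive-definite correlation matrix
#' ([Matrix::nearPD()]), iterating a mean-recentering step until the mean
#' off-diagonal is within 0.01 of `corr_mean`.
#'
#' @param pattern `"exchangeable"` or `"unstructured"`.
#' @param corr_mean Target mean off-diagonal correlation.
#' @param n_markers Matrix dimension (>= 2).
#' @param seed RNG seed for the unstructured draw.
#' @return A symmetric positive-definite correlation matrix.
#' @export
#' @examples
#' marker_correlation("exchangeable", 0.2, 4)
marker_correlation <- function(pattern = c("exchangeable", "unstructured"),
                               corr_mean, n_markers, seed = NULL) {
  pattern <- match.arg(pattern)
  stopifnot(n_markers >= 2, corr_mean < 1)
  if (corr_mean <= -1 / (n_markers - 1)) {
    stop(sprintf(
      "an exchangeable correlation of %.3f is not positive definite for %d markers (needs > %.3f)",
      corr_mean, n_markers, -1 / (n_markers - 1)), call. = FALSE)
  }
  if (pattern == "exchangeable") {
    m <- matrix(corr_mean, n_markers, n_markers)
    diag(m) <- 1
    return(m)
  }
  set_seed_if(seed)
  lo <- max(0, corr_mean - 0.15)
  hi <- min(0.95, corr_mean + 0.15)
  m <- diag(n_markers)
  off <- upper.tri(m)
  m[off] <- runif(sum(off), lo, hi)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  for (iter in 1:25) {
    m <- as.matrix(Matrix::nearPD(m, corr = TRUE)$mat)
    drift <- corr_mean - mean(m[off])
    if (abs(drift) <= 0.005) break
    m[off] <- pmin(0.99, pmax(-0.99, m[off] + drift))
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 1
  }
  dimnames(m) <- NULL
  m
}

#' Generate correlated binary disease markers
#'
#' Gaussian-copula generation: a latent multivariate normal vector with
#' correlation `corr` is drawn for each individual and column *k* is
#' dichotomised at the standard-normal `1 - prevalences[k]` quantile (success =
#' latent value above the threshold), so each marker's marginal success
#' probability equals its target prevalence.
#'
#' @param n Number of individuals.
#' @param prevalences Vector of target marker prevalences, each in (0, 1).
#' @param corr Latent correlation matrix (dimension `length(prevalences)`).
#' @param seed RNG seed.
#' @return An object of class `"marker_panel"`: a list with the 0/1 `values`
#'   matrix (`n` rows), `target_prevalences` and `target_corr`.
#' @export
generate_markers <- function(n, prevalences, corr, seed = NULL) {
  k <- length(prevalences)
  assert_prob(prevalences, "prevalences")
  if (!is.matrix(corr) || nrow(corr) != k || ncol(corr) != k) {
    stop("`corr` must be a square matrix matching `length(prevalences)`",
         call. = FALSE)
  }
  set_seed_if(seed)
  z <- matrix(rnorm(n * k), n, k) %*% chol(corr)
  thr <- qnorm(1 - prevalences)
  x <- matrix(0L, n, k)
  for (j in seq_len(k)) x[, j] <- as.integer(z[, j] > thr[j])
  colnames(x) <- paste0("x", seq_len(k))
  structure(list(values = x,
                 target_prevalences = as.numeric(prevalences),
                 target_corr = corr),
            class = "marker_panel")
}

#' @export
#' @method print marker_panel
print.marker_panel <- function(x, ...) {
  cat(sprintf("Marker panel: %d individuals x %d binary markers\n",
              nrow(x$values), ncol(x$values)))
  cat("  target prevalences:",
      paste(sprintf("%.3f", x$target_prevalences), collapse = " "), "\n")
  invisible(x)
}

#' Logistic disease model for true status
#'
#' @param intercept Log-odds intercept.
#' @param coefficients Log-odds coefficients, one per marker.
#' @return An object of class `"disease_model"`.
#' @export
disease_model <- function(intercept, coefficients) {
  stopifnot(is.finite(intercept), all(is.finite(coefficients)))
  structure(list(intercept = intercept,
                 coefficients = as.numeric(coefficients)),
            class = "disease_model")
}

#' Calibrate the logistic intercept to a target prevalence
#'
#' Finds the intercept `b0` such that the mean over panel rows of
#' `plogis(b0 + x %*% coefficients)` equals `target_prev` to within `tol`.
#' The mean is strictly increasing in `b0`, so monotone root-finding
#' ([stats::uniroot()]) always succeeds.
#'
#' @param coefficients Marker log-odds coefficients.
#' @param panel A [generate_markers()] panel (or 0/1 matrix).
#' @param target_prev Target mean disease probability, in (0, 1).
#' @param tol Tolerance on the achieved mean probability.
#' @return The calibrated intercept (scalar).
#' @export
calibrate_intercept <- function(coefficients, panel, target_prev, tol = 1e-6) {
  x <- if (inherits(panel, "marker_panel")) panel$values else panel
  stopifnot(nrow(x) >= 1, ncol(x) == length(coefficients))
  assert_prob(target_prev, "target_prev")
  eta <- drop(x %*% coefficients)
  f <- function(b0) mean(plogis(b0 + eta)) - target_prev
  span <- max(1, max(abs(eta))) + abs(qlogis(target_prev)) + 5
  root <- uniroot(f, interval = c(-span, span), extendInt = "upX",
                  tol = min(tol, 1e-8))$root
  if (abs(f(root)) > tol) {
    root <- uniroot(f, interval = root + c(-1, 1), tol = 1e-12)$root
  }
  root
}

#' Generate true disease status from markers
#'
#' Each individual's status is drawn Bernoulli with probability
#' `plogis(intercept + x %*% coefficients)`.
#'
#' @param panel A [generate_markers()] panel.
#' @param model A [disease_model()].
#' @param seed RNG seed.
#' @return Integer 0/1 vector of true disease status, one per individual.
#' @export
generate_truth <- function(panel, model, seed = NULL) {
  x <- if (inherits(panel, "marker_panel")) panel$values else panel
  if (ncol(x) != length(model$coefficients)) {
    stop("model dimension does not match the marker panel", call. = FALSE)
  }
  set_seed_if(seed)
  p <- plogis(model$intercept + drop(x %*% model$coefficients))
  rbinom(nrow(x), 1L, p)
}
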