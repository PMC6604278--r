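#' Prevalence estimate container
#'
#' @param method Label: one of `"source1"`, `"source2"`, `"OR"`, `"AND"`,
#'   `"RSSA"`, `"PSSA"`.
#' @param point Point estimate (proportion).
#' @param ci_low,ci_high Confidence/credible bounds (truncated to \[0, 1\]).
#' @param ci_method `"wald"`, `"percentile_bootstrap"` or `"posterior"`.
#' @param n Number of individuals behind the estimate.
#' @return An object of class `"prev_estimate"`.
#' @export
prev_estimate <- function(method, point, ci_low = NA_real_, ci_high = NA_real_,
                          ci_method = NA_character_, n = NA_integer_) {
  method <- match.arg(method,
                      c("source1", "source2", "OR", "AND", "RSSA", "PSSA"))
  point <- min(max(point, 0), 1)
  if (!is.na(ci_low)) ci_low <- min(max(ci_low, 0), point)
  if (!is.na(ci_high)) ci_high <- max(min(ci_high, 1), point)
  structure(list(method = method, point = point,
                 ci_low = ci_low, ci_high = ci_high,
                 ci_method = ci_method, n = n),
            class = "prev_estimate")
}

#' @export
#' @method print prev_estimate
print.prev_estimate <- function(x, digits = 4, ...) {
  ci <- if (is.na(x$ci_low)) "" else
    sprintf(" (95%% CI %.*f-%.*f, %s)", digits, x$ci_low, digits, x$ci_high,
            x$ci_method)
  cat(sprintf("%-7s prevalence %.*f%s  [n = %s]\n", x$method, digits, x$point,
              ci, format(x$n)))
  invisible(x)
}

#' @export
#' @method as.data.frame prev_estimate
as.data.frame.prev_estimate <- function(x, ...) {
  data.frame(method = x$method, point = x$point, ci_low = x$ci_low,
             ci_high = x$ci_high, ci_method = x$ci_method, n = x$n,
             stringsAsFactors = FALSE)
}

#' Normal-approximation (Wald) confidence interval for a proportion
#'
#' `p +/- z * sqrt(p (1 - p) / n)`, truncated to \[0, 1\]. The 95% level uses
#' z = 1.959964.
#'
#' @param p Observed proportion.
#' @param n Sample size (>= 1).
#' @param level Confidence level.
#' @return Length-2 vector `c(low, high)`.
#' @export
wald_ci <- function(p, n, level = 0.95) {
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  assert_prob(p, "p", open_low = FALSE, open_high = FALSE)
  z <- qnorm(1 - (1 - level) / 2)
  hw <- z * sqrt(p * (1 - p) / n)
  c(max(0, p - hw), min(1, p + hw))
}

#' Rule-based OR and AND prevalence estimators
#'
#' `estimate_or()` counts an individual as a case when either source flags
#' them; `estimate_and()` requires both sources. Wald confidence intervals
#' are attached. The two satisfy the inclusion-exclusion identity
#' `OR + AND = mean(y1) + mean(y2)` exactly.
#'
#' @param sources An [observed_sources()] object (or list with `y1`, `y2`).
#' @param level Confidence level.
#' @return A [prev_estimate()].
#' @export
estimate_or <- function(sources, level = 0.95) {
  s <- as_observed(sources)
  n <- length(s$y1)
  if (n == 0L) stop("empty input", call. = FALSE)
  p <- mean(s$y1 == 1L | s$y2 == 1L)
  ci <- wald_ci(p, n, level)
  prev_estimate("OR", p, ci[1], ci[2], "wald", n)
}

#' @rdname estimate_or
#' @export
estimate_and <- function(sources, level = 0.95) {
  s <- as_observed(sources)
  n <- length(s$y1)
  if (n == 0L) stop("empty input", call. = FALSE)
  p <- mean(s$y1 == 1L & s$y2 == 1L)
  ci <- wald_ci(p, n, level)
  prev_estimate("AND", p, ci[1], ci[2], "wald", n)
}

#' Rogan-Gladen prevalence correction
#'
#' De-biases an observed prevalence using assumed sensitivity and
#' specificity: `(obs_prev + Sp - 1) / (Sn + Sp - 1)`, truncated to \[0, 1\].
#' Requires a strictly positive Youden index.
#'
#' @param obs_prev Observed (error-prone) prevalence.
#' @param acc An [accuracy_spec()] with the assumed accuracy.
#' @return Corrected prevalence (scalar in \[0, 1\]).
#' @export
#' @examples
#' rogan_gladen(0.30, accuracy_spec(0.72, 0.95))  # 0.25 / 0.67
rogan_gladen <- function(obs_prev, acc) {
  stopifnot(inherits(acc, "accuracy_spec"))
  assert_prob(obs_prev, "obs_prev", open_low = FALSE, open_high = FALSE)
  youden <- acc$sensitivity + acc$specificity - 1
  if (youden <= 0) {
    stop("Rogan-Gladen correction requires sensitivity + specificity > 1",
         call. = FALSE)
  }
  min(max((obs_prev + acc$specificity - 1) / youden, 0), 1)
}

#' Rule-based sensitivity-specificity adjusted (RSSA) estimator
#'
#' Applies the Rogan-Gladen correction to each source's observed prevalence
#' with its assumed accuracy, then combines the two corrected estimates —
#' by unweighted average (default) or inverse-variance weighting. The
#' percentile-bootstrap confidence interval resamples individuals with
#' replacement; because the RSSA statistic depends on the data only through
#' the four (y1, y2) cell counts, the resampling is carried out as a
#' multinomial redraw of the cell counts, which is distributionally identical
#' to row resampling and much faster.
#'
#' @param sources An [observed_sources()] object.
#' @param assumed An [accuracy_pair()] with the assumed accuracies
#'   (default: the published validation-study averages).
#' @param weights `"equal"` for the unweighted mean of the two corrected
#'   prevalences, `"invvar"` for inverse-variance weights (delta-method
#'   variance `m_j (1 - m_j) / (n * Youden_j^2)`).
#' @param ci `"bootstrap"` for a percentile-bootstrap interval, `"none"`.
#' @param B Number of bootstrap resamples.
#' @param level Confidence level.
#' @param seed RNG seed for the bootstrap.
#' @return A [prev_estimate()].
#' @export
estimate_rssa <- function(sources, assumed = default_assumed_accuracy(),
                          weights = c("equal", "invvar"),
                          ci = c("bootstrap", "none"),
                          B = 999, level = 0.95, seed = NULL) {
  weights <- match.arg(weights)
  ci <- match.arg(ci)
  s <- as_observed(sources)
  stopifnot(inherits(assumed, "accuracy_pair"))
  n <- length(s$y1)
  if (n == 0L) stop("empty input", call. = FALSE)

  rssa_point <- function(m1, m2) {
    c1 <- rogan_gladen(m1, assumed$source1)
    c2 <- rogan_gladen(m2, assumed$source2)
    if (weights == "equal") return((c1 + c2) / 2)
    v1 <- max(m1 * (1 - m1), 1 / n) /
      (n * (assumed$source1$sensitivity + assumed$source1$specificity - 1)^2)
    v2 <- max(m2 * (1 - m2), 1 / n) /
      (n * (assumed$source2$sensitivity + assumed$source2$specificity - 1)^2)
    (c1 / v1 + c2 / v2) / (1 / v1 + 1 / v2)
  }

  point <- rssa_point(mean(s$y1), mean(s$y2))
  lo <- hi <- NA_real_
  if (ci == "bootstrap") {
    counts <- c(sum(s$y1 & s$y2), sum(s$y1 & !s$y2),
                sum(!s$y1 & s$y2), sum(!s$y1 & !s$y2))
    set_seed_if(seed)
    draw <- stats::rmultinom(B, n, counts / n)
    m1s <- (draw[1, ] + draw[2, ]) / n
    m2s <- (draw[1, ] + draw[3, ]) / n
    stats_b <- vapply(seq_len(B), function(b) rssa_point(m1s[b], m2s[b]),
                      numeric(1))
    a <- (1 - level) / 2
    q <- quantile(stats_b, c(a, 1 - a), names = FALSE)
    lo <- q[1]; hi <- q[2]
  }
  prev_estimate("RSSA", point, lo, hi,
                if (ci == "bootstrap") "percentile_bootstrap" else NA_character_,
                n)
}

#' Percentile-bootstrap confidence interval for a prevalence statistic
#'
#' Resamples individuals (rows) with replacement `B` times, re-applies the
#' estimator to each resample, and returns the empirical `(1-level)/2` and
#' `1-(1-level)/2` percentiles. Deterministic under a fixed seed.
#'
#' @param estimator A function `(y1, y2) -> numeric(1)`.
#' @param sources An [observed_sources()] object.
#' @param B Number of bootstrap resamples (default 999).
#' @param level Confidence level.
#' @param seed RNG seed.
#' @return Length-2 vector `c(low, high)`.
#' @export
bootstrap_percentile_ci <- function(estimator, sources, B = 999,
                                    level = 0.95, seed = NULL) {
  stopifnot(is.function(estimator), B >= 1)
  s <- as_observed(sources)
  n <- length(s$y1)
  set_seed_if(seed)
  stats_b <- numeric(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    stats_b[b] <- tryCatch(
      estimator(s$y1[idx], s$y2[idx]),
      error = function(e) stop(sprintf("estimator failed on resample %d: %s",
                                       b, conditionMessage(e)), call. = FALSE))
  }
  a <- (1 - level) / 2
  quantile(stats_b, c(a, 1 - a), names = FALSE)
}

#' Single-source naive prevalence estimate
#'
#' @param sources An [observed_sources()] object.
#' @param source Which source (1 or 2).
#' @param level Confidence level.
#' @return A [prev_estimate()] with a Wald interval.
#' @export
estimate_source <- function(sources, source = 1, level = 0.95) {
  s <- as_observed(sources)
  y <- if (source == 1) s$y1 else s$y2
  n <- length(y)
  if (n == 0L) stop("empty input", call. = FALSE)
  p <- mean(y)
  ci <- wald_ci(p, n, level)
  prev_estimate(paste0("source", source), p, ci[1], ci[2], "wald", n)
}
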