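#' Priors for the PSSA latent-class model
#'
#' Weakly informative defaults: independent normal(0, `coef_sd`^2) priors on
#' the probit outcome coefficients and Beta(2, 1) priors on each source's
#' sensitivity and specificity. Sensitivity/specificity draws are truncated
#' to `Sn + Sp > 1`, which removes the label-switching mode in which the
#' latent classes swap meaning.
#'
#' @param coef_sd Prior standard deviation for probit coefficients.
#' @param sn_shape,sp_shape Length-2 Beta shape parameters `(a, b)` for
#'   sensitivity and specificity.
#' @return An object of class `"pssa_priors"`.
#' @export
pssa_priors <- function(coef_sd = 10, sn_shape = c(2, 1), sp_shape = c(2, 1)) {
  stopifnot(coef_sd > 0, all(sn_shape > 0), all(sp_shape > 0))
  structure(list(coef_sd = coef_sd, sn_shape = sn_shape, sp_shape = sp_shape),
            class = "pssa_priors")
}

#' Probabilistic sensitivity-specificity adjusted (PSSA) prevalence model
#'
#' Fits a Bayesian latent-class model in which true disease status `D` is
#' unobserved: a probit outcome model links the binary disease markers to
#' `P(D = 1)`, and an intercept-only reporting model links `D` to each
#' error-prone source indicator through that source's sensitivity and
#' specificity. The two sources are assumed conditionally independent given
#' `D`. Fitting is by Gibbs sampling: latent statuses from their Bernoulli
#' full conditionals, probit coefficients by Albert-Chib truncated-normal data
#' augmentation, and sensitivities/specificities from conjugate Beta full
#' conditionals (truncated to `Sn + Sp > 1`).
#'
#' The prevalence chain records, at each iteration, the mean of the sampled
#' latent statuses — the population prevalence implied by that draw.
#'
#' @param y1,y2 0/1 source indicators (or an [observed_sources()] object
#'   passed as `y1`).
#' @param markers Marker matrix (0/1 or numeric covariates; an intercept
#'   column is added internally), or a [generate_markers()] panel.
#' @param priors A [pssa_priors()] object.
#' @param n_iter Total Gibbs iterations per chain (default 10000).
#' @param burn_in Iterations discarded from the front of each chain
#'   (default 500).
#' @param n_chains Number of independent chains (>= 2 for between-chain
#'   convergence diagnostics; a single chain uses split-halves).
#' @param seed Integer seed; chain `c` runs under `seed + c - 1`.
#' @return An object of class `"pssa"` with components `prevalence`
#'   (retained-iteration x chain matrix), `coefficients` and `accuracy`
#'   (arrays of draws), `deviance`, `psrf` (per-parameter potential scale
#'   reduction factors), `dic`, `p_d`, and the data/settings used.
#' @seealso [posterior_prevalence()], [compute_dic()], [gelman_rubin_psrf()]
#' @export
pssa <- function(y1, y2 = NULL, markers, priors = pssa_priors(),
                 n_iter = 10000, burn_in = 500, n_chains = 2, seed = 1) {
  if (inherits(y1, "observed_sources")) {
    y2 <- y1$y2
    y1 <- y1$y1
  }
  x <- if (inherits(markers, "marker_panel")) markers$values else as.matrix(markers)
  stopifnot(length(y1) == length(y2), nrow(x) == length(y1))
  assert_binary(y1, "y1")
  assert_binary(y2, "y2")
  stopifnot(burn_in >= 0, burn_in < n_iter, n_chains >= 1)
  if ((all(y1 == 0L) && all(y2 == 0L)) || (all(y1 == 1L) && all(y2 == 1L))) {
    stop("degenerate data: both sources are constant at the same value",
         call. = FALSE)
  }
  const_col <- apply(x, 2, function(v) length(unique(v)) == 1L)
  if (any(const_col)) {
    warning(sprintf(
      "marker column(s) %s are constant; their coefficients are prior-dominated",
      paste(which(const_col), collapse = ", ")))
  }
  X <- cbind(`(Intercept)` = 1, x)
  if (is.null(colnames(x)) && ncol(x) > 0) {
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(x))))
  }
  p <- ncol(X)
  keep <- n_iter - burn_in

  prev <- matrix(NA_real_, keep, n_chains)
  devm <- matrix(NA_real_, keep, n_chains)
  coefs <- array(NA_real_, c(keep, p, n_chains),
                 dimnames = list(NULL, colnames(X), NULL))
  accs <- array(NA_real_, c(keep, 4L, n_chains),
                dimnames = list(NULL, c("sn1", "sp1", "sn2", "sp2"), NULL))

  for (ch in seq_len(n_chains)) {
    set.seed(as.integer(seed) + ch - 1L)
    alpha0 <- c(qnorm(min(max(mean(y1 | y2), 0.02), 0.98)), rep(0, p - 1))
    acc0 <- c(0.7 + 0.1 * runif(1), 0.9, 0.7 + 0.1 * runif(1), 0.9)
    res <- gibbs_chain(X, as.integer(y1), as.integer(y2),
                       as.integer(n_iter), priors$coef_sd,
                       priors$sn_shape[1], priors$sn_shape[2],
                       priors$sp_shape[1], priors$sp_shape[2],
                       alpha0, acc0)
    idx <- (burn_in + 1):n_iter
    prev[, ch] <- res$prevalence[idx]
    devm[, ch] <- res$deviance[idx]
    coefs[, , ch] <- res$coefficients[idx, , drop = FALSE]
    accs[, , ch] <- res$accuracy[idx, , drop = FALSE]
  }

  psrf <- c(
    prevalence = gelman_rubin_psrf(prev),
    setNames(vapply(seq_len(p), function(j)
      gelman_rubin_psrf(coefs[, j, , drop = TRUE]), numeric(1)),
      colnames(X)),
    setNames(vapply(1:4, function(j)
      gelman_rubin_psrf(accs[, j, , drop = TRUE]), numeric(1)),
      c("sn1", "sp1", "sn2", "sp2"))
  )

  fit <- structure(
    list(prevalence = prev, coefficients = coefs, accuracy = accs,
         deviance = devm, psrf = psrf,
         n_iter = n_iter, burn_in = burn_in, n_chains = n_chains,
         seed = seed, priors = priors,
         data = list(X = X, y1 = as.integer(y1), y2 = as.integer(y2)),
         call = match.call()),
    class = "pssa")
  dic <- compute_dic(fit)
  fit$dic <- dic$dic
  fit$p_d <- dic$p_d
  fit
}

# Marginalized (latent-status-summed) deviance of the observed sources.
pssa_marginal_deviance <- function(alpha, acc, X, y1, y2) {
  pi <- pnorm(drop(X %*% alpha))
  l1 <- ifelse(y1 == 1L, acc[1], 1 - acc[1]) *
    ifelse(y2 == 1L, acc[3], 1 - acc[3])
  l0 <- ifelse(y1 == 1L, 1 - acc[2], acc[2]) *
    ifelse(y2 == 1L, 1 - acc[4], acc[4])
  -2 * sum(log(pmax(pi * l1 + (1 - pi) * l0, 1e-300)))
}

#' Deviance information criterion for a PSSA fit
#'
#' Uses the observed-data likelihood of `(y1, y2)` given the parameters, with
#' the latent statuses marginalized analytically:
#' `DIC = mean(D(theta)) + p_D` where
#' `p_D = mean(D(theta)) - D(posterior means)`.
#'
#' @param fit A [pssa()] fit.
#' @return List with `dic`, `p_d`, `mean_deviance`, `deviance_at_means`.
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "pssa"))
  dbar <- mean(fit$deviance)
  if (!is.finite(dbar)) stop("non-finite posterior deviance", call. = FALSE)
  alpha_hat <- apply(fit$coefficients, 2, mean)
  acc_hat <- apply(fit$accuracy, 2, mean)
  dhat <- pssa_marginal_deviance(alpha_hat, acc_hat, fit$data$X,
                                 fit$data$y1, fit$data$y2)
  p_d <- dbar - dhat
  list(dic = dbar + p_d, p_d = p_d, mean_deviance = dbar,
       deviance_at_means = dhat)
}

#' Posterior prevalence estimate from a PSSA fit
#'
#' Point estimate is the posterior mean of the prevalence chain (all chains
#' pooled); the interval is the 2.5/97.5 posterior percentile by default.
#'
#' @param fit A [pssa()] fit (or a numeric vector/matrix of prevalence draws).
#' @param level Credible level.
#' @return A [prev_estimate()] with method `"PSSA"`.
#' @export
posterior_prevalence <- function(fit, level = 0.95) {
  draws <- if (inherits(fit, "pssa")) fit$prevalence else fit
  draws <- as.numeric(draws)
  if (length(draws) == 0L || all(is.na(draws))) {
    stop("empty prevalence chain", call. = FALSE)
  }
  n <- if (inherits(fit, "pssa")) length(fit$data$y1) else NA_integer_
  a <- (1 - level) / 2
  q <- quantile(draws, c(a, 1 - a), names = FALSE)
  prev_estimate("PSSA", mean(draws), q[1], q[2], "posterior", n)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Standard between/within-chain variance-ratio PSRF. Values close to 1
#' indicate convergence. A single chain is split into halves (split-Rhat).
#'
#' @param chains A matrix with one column per chain (rows = iterations), or a
#'   single numeric vector (split in half).
#' @return Scalar PSRF.
#' @export
gelman_rubin_psrf <- function(chains) {
  if (is.matrix(chains) && ncol(chains) == 1L) chains <- chains[, 1L]
  if (is.numeric(chains) && is.null(dim(chains))) {
    half <- floor(length(chains) / 2)
    if (half < 10) stop("need at least 2 chains of length >= 10", call. = FALSE)
    chains <- cbind(chains[1:half], chains[(half + 1):(2 * half)])
  }
  chains <- as.matrix(chains)
  m <- ncol(chains)
  n <- nrow(chains)
  if (m < 2) stop("need at least 2 chains", call. = FALSE)
  if (n < 10) stop("chains must have length >= 10", call. = FALSE)
  w <- mean(apply(chains, 2, var))
  if (w < .Machine$double.eps) return(1)
  b <- n * var(colMeans(chains))
  vplus <- (n - 1) / n * w + b / n
  sqrt(vplus / w)
}

#' @export
#' @method print pssa
print.pssa <- function(x, ...) {
  est <- posterior_prevalence(x)
  cat("PSSA latent-class prevalence model (probit outcome, Gibbs sampling)\n")
  cat(sprintf("  n = %d, %d markers, %d chain(s) x %d iterations (%d burn-in)\n",
              length(x$data$y1), ncol(x$data$X) - 1L, x$n_chains,
              x$n_iter, x$burn_in))
  cat(sprintf("  posterior prevalence: %.4f (95%% CrI %.4f-%.4f)\n",
              est$point, est$ci_low, est$ci_high))
  cat(sprintf("  max PSRF = %.3f; DIC = %.1f (p_D = %.1f)\n",
              max(x$psrf), x$dic, x$p_d))
  invisible(x)
}

#' @export
#' @method summary pssa
summary.pssa <- function(object, ...) {
  tab <- rbind(
    prevalence = c(mean(object$prevalence), sd(object$prevalence),
                   quantile(object$prevalence, c(0.025, 0.975))),
    t(apply(object$coefficients, 2, function(d)
      c(mean(d), sd(d), quantile(d, c(0.025, 0.975))))),
    t(apply(object$accuracy, 2, function(d)
      c(mean(d), sd(d), quantile(d, c(0.025, 0.975)))))
  )
  colnames(tab) <- c("mean", "sd", "q2.5", "q97.5")
  tab <- cbind(tab, psrf = object$psrf[rownames(tab)])
  res <- list(table = tab, dic = object$dic, p_d = object$p_d,
              n = length(object$data$y1))
  class(res) <- "summary.pssa"
  res
}

#' @export
#' @method print summary.pssa
print.summary.pssa <- function(x, digits = 4, ...) {
  cat("PSSA posterior summary\n")
  print(round(x$table, digits))
  cat(sprintf("DIC = %.1f (p_D = %.1f), n = %d\n", x$dic, x$p_d, x$n))
  invisible(x)
}

#' @export
#' @method coef pssa
coef.pssa <- function(object, ...) {
  apply(object$coefficients, 2, mean)
}

#' @export
#' @method plot pssa
plot.pssa <- function(x, parameter = "prevalence", ...) {
  draws <- switch(parameter,
    prevalence = x$prevalence,
    sn1 = x$accuracy[, "sn1", , drop = TRUE],
    sp1 = x$accuracy[, "sp1", , drop = TRUE],
    sn2 = x$accuracy[, "sn2", , drop = TRUE],
    sp2 = x$accuracy[, "sp2", , drop = TRUE],
    x$coefficients[, parameter, , drop = TRUE])
  draws <- as.matrix(draws)
  matplot(draws, type = "l", lty = 1, xlab = "retained iteration",
          ylab = parameter, main = sprintf("Trace: %s", parameter), ...)
  invisible(x)
}

#' Simulate replicate source data from a PSSA fit
#'
#' For each replicate a retained posterior draw is selected at random, latent
#' statuses are drawn from the probit outcome model, and source indicators
#' from the reporting model.
#'
#' @param object A [pssa()] fit.
#' @param nsim Number of replicate datasets.
#' @param seed RNG seed.
#' @param ... Unused.
#' @return A list of `nsim` data frames with columns `d`, `y1`, `y2`.
#' @export
#' @method simulate pssa
simulate.pssa <- function(object, nsim = 1, seed = NULL, ...) {
  set_seed_if(seed)
  keep <- nrow(object$prevalence)
  X <- object$data$X
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    it <- sample.int(keep, 1)
    ch <- sample.int(object$n_chains, 1)
    alpha <- object$coefficients[it, , ch]
    acc <- object$accuracy[it, , ch]
    d <- rbinom(nrow(X), 1L, pnorm(drop(X %*% alpha)))
    y1 <- rbinom(nrow(X), 1L, ifelse(d == 1L, acc[1], 1 - acc[2]))
    y2 <- rbinom(nrow(X), 1L, ifelse(d == 1L, acc[3], 1 - acc[4]))
    out[[s]] <- data.frame(d = d, y1 = y1, y2 = y2)
  }
  out
}

#' Export PSSA chains as long-format delimited text
#'
#' Writes one row per (chain, iteration, parameter) so that the chains can be
#' consumed by standard MCMC-diagnostic tooling.
#'
#' @param fit A [pssa()] fit.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
export_chains <- function(fit, path) {
  stopifnot(inherits(fit, "pssa"))
  keep <- nrow(fit$prevalence)
  rows <- list()
  for (ch in seq_len(fit$n_chains)) {
    blocks <- cbind(prevalence = fit$prevalence[, ch],
                    fit$coefficients[, , ch],
                    fit$accuracy[, , ch],
                    deviance = fit$deviance[, ch])
    rows[[ch]] <- data.frame(
      chain = ch,
      iteration = rep(seq_len(keep) + fit$burn_in, ncol(blocks)),
      parameter = rep(colnames(blocks), each = keep),
      value = as.numeric(blocks))
  }
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
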