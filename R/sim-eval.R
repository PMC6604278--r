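#' Percent absolute relative bias
#'
#' `100 * |true_prev - mean(estimates)| / true_prev`.
#'
#' @param estimates Vector of replication estimates.
#' @param true_prev True prevalence (> 0).
#' @return Percent absolute relative bias (scalar >= 0).
#' @export
#' @examples
#' relative_bias(rep(0.105, 10), 0.20)  # 47.5
relative_bias <- function(estimates, true_prev) {
  if (length(estimates) == 0L) stop("empty estimates", call. = FALSE)
  if (!is.finite(true_prev) || true_prev <= 0) {
    stop("`true_prev` must be positive", call. = FALSE)
  }
  100 * abs(true_prev - mean(estimates)) / true_prev
}

#' Mean squared error of replication estimates (x 100)
#'
#' `scale * (variance + squared bias)` where the variance uses the population
#' (divide-by-R) convention by default, matching the plug-in decomposition
#' `MSE = var + |true - mean|^2`; results are multiplied by 100 to match the
#' reporting convention.
#'
#' @param estimates Vector of replication estimates (one is allowed, with
#'   zero variance).
#' @param true_prev True prevalence.
#' @param scale Multiplier for the reported value (default 100).
#' @param variance `"population"` (divide by R) or `"sample"` (R - 1).
#' @return Scaled MSE (scalar >= 0).
#' @export
#' @examples
#' mean_squared_error(rep(0.105, 5), 0.20)  # 100 * 0.095^2 = 0.9025
mean_squared_error <- function(estimates, true_prev, scale = 100,
                               variance = c("population", "sample")) {
  variance <- match.arg(variance)
  if (length(estimates) == 0L) stop("empty estimates", call. = FALSE)
  m <- mean(estimates)
  v <- if (length(estimates) == 1L) 0 else if (variance == "population") {
    mean((estimates - m)^2)
  } else {
    var(estimates)
  }
  scale * (v + (true_prev - m)^2)
}

# Resolve the data-generating ingredients for one condition: marker
# prevalences (drawn once from U(0.05, 0.35) unless supplied), latent marker
# correlation matrix, marker coefficients log(1.5)..log(2.5) equally spaced,
# the calibrated logistic intercept, and the calibrated generating
# accuracy/dependence.
resolve_condition <- function(condition, base_seed = 1,
                              calibration_size = 50000,
                              specificity = c(0.95, 0.90),
                              accuracy = NULL) {
  seed0 <- condition_seed(base_seed, condition)
  k <- condition$n_markers
  prevs <- condition$marker_prevalences
  if (is.null(prevs)) {
    set.seed(seed0)
    prevs <- runif(k, 0.05, 0.35)
  }
  corr <- marker_correlation(condition$marker_corr_pattern,
                             condition$marker_corr, k,
                             seed = (seed0 + 1L) %% 2147483647L)
  coefs <- seq(log(1.5), log(2.5), length.out = k)
  cal_panel <- generate_markers(calibration_size, prevs, corr,
                                seed = (seed0 + 2L) %% 2147483647L)
  b0 <- calibrate_intercept(coefs, cal_panel, condition$true_prev, tol = 1e-5)
  if (is.null(accuracy)) {
    accuracy <- calibrate_accuracy(condition, specificity = specificity)
  } else {
    stopifnot(all(c("acc1", "acc2") %in% names(accuracy)))
    if (is.null(accuracy$dep)) accuracy$dep <- dependence_spec()
  }
  list(seed = seed0, marker_prevalences = prevs, marker_corr = corr,
       model = disease_model(b0, coefs), accuracy = accuracy)
}

# Generate one replication of a resolved condition.
generate_replication <- function(condition, resolved, rep_seed,
                                 population_size = condition$population_size) {
  panel <- generate_markers(population_size, resolved$marker_prevalences,
                            resolved$marker_corr, seed = rep_seed)
  truth <- generate_truth(panel, resolved$model,
                          seed = (rep_seed + 1L) %% 2147483647L)
  sources <- apply_misclassification(truth, resolved$accuracy$acc1,
                                     resolved$accuracy$acc2,
                                     resolved$accuracy$dep,
                                     seed = (rep_seed + 2L) %% 2147483647L)
  list(panel = panel, truth = truth, sources = sources)
}

#' Run all replications of one simulation condition
#'
#' For each replication a population is generated (markers, then true status
#' from the calibrated logistic model, then misclassified source indicators),
#' each requested estimator is applied, and percent absolute relative bias
#' and scaled MSE are aggregated per method. Fully seeded: the condition seed
#' is `base_seed` offset by a stable hash of the condition fields, and each
#' replication derives its own seed from it, so any cell or replication can
#' be reproduced in isolation.
#'
#' @param condition A [sim_condition()].
#' @param reps Number of replications (reference design: 500).
#' @param methods Subset of `c("source1", "source2", "or", "and", "rssa",
#'   "pssa")`.
#' @param assumed [accuracy_pair()] assumed by the RSSA correction.
#' @param pssa_control List of PSSA fitting settings: `n_iter`, `burn_in`,
#'   `n_chains`, and optionally `population_size` to fit PSSA on a smaller
#'   generated population.
#' @param base_seed Base RNG seed.
#' @param population_size Population per replication (defaults to the
#'   condition's).
#' @param specificity Generating specificities passed to
#'   [calibrate_accuracy()].
#' @param calibration_size Panel size used to calibrate the logistic
#'   intercept.
#' @param accuracy Optional list with `acc1`, `acc2` (and optionally `dep`)
#'   to bypass [calibrate_accuracy()] and generate under explicitly chosen
#'   accuracy, e.g. perfect sources.
#' @return An object of class `"condition_result"`: per-method replication
#'   estimates, mean estimate, `rb`, `mse`, plus metadata (seeds, calibrated
#'   accuracy, PSSA convergence flags).
#' @export
run_condition <- function(condition, reps = 500,
                          methods = c("or", "and", "rssa"),
                          assumed = default_assumed_accuracy(),
                          pssa_control = list(n_iter = 2000, burn_in = 500,
                                              n_chains = 1),
                          base_seed = 1,
                          population_size = condition$population_size,
                          specificity = c(0.95, 0.90),
                          calibration_size = 50000, accuracy = NULL) {
  methods <- match.arg(methods,
                       c("source1", "source2", "or", "and", "rssa", "pssa"),
                       several.ok = TRUE)
  resolved <- resolve_condition(condition, base_seed,
                                calibration_size = calibration_size,
                                specificity = specificity,
                                accuracy = accuracy)
  pssa_n <- pssa_control$population_size
  if (is.null(pssa_n)) pssa_n <- population_size
  est <- matrix(NA_real_, reps, length(methods),
                dimnames = list(NULL, methods))
  pssa_flagged <- logical(reps)
  for (r in seq_len(reps)) {
    rep_seed <- as.integer((resolved$seed + 1000 + 17 * r) %% 2147483647)
    gen <- generate_replication(condition, resolved, rep_seed,
                                population_size)
    s <- gen$sources
    for (m in methods) {
      est[r, m] <- switch(m,
        source1 = mean(s$y1),
        source2 = mean(s$y2),
        or = mean(s$y1 | s$y2),
        and = mean(s$y1 & s$y2),
        rssa = estimate_rssa(s, assumed, ci = "none")$point,
        pssa = {
          gp <- if (pssa_n == population_size) gen else
            generate_replication(condition, resolved, rep_seed, pssa_n)
          fit <- pssa(gp$sources$y1, gp$sources$y2, gp$panel,
                      n_iter = pssa_control$n_iter,
                      burn_in = pssa_control$burn_in,
                      n_chains = pssa_control$n_chains,
                      seed = rep_seed)
          if (fit$psrf["prevalence"] > 1.2) pssa_flagged[r] <- TRUE
          mean(fit$prevalence)
        })
    }
  }
  per_method <- lapply(methods, function(m) {
    v <- est[, m]
    list(estimates = v, mean = mean(v),
         rb = relative_bias(v, condition$true_prev),
         mse = mean_squared_error(v, condition$true_prev))
  })
  names(per_method) <- methods
  structure(
    list(condition = condition, methods = per_method, n_reps = reps,
         population_size = population_size,
         seed = resolved$seed, base_seed = base_seed,
         calibration = resolved$accuracy,
         pssa_flagged = if ("pssa" %in% methods) sum(pssa_flagged) else NA),
    class = "condition_result")
}

#' @export
#' @method print condition_result
print.condition_result <- function(x, ...) {
  cat(sprintf("Condition result (%d replications, population %d)\n",
              x$n_reps, x$population_size))
  print(x$condition)
  for (m in names(x$methods)) {
    cat(sprintf("  %-8s mean %.4f  RB %6.2f%%  MSE(x100) %.4f\n",
                m, x$methods[[m]]$mean, x$methods[[m]]$rb,
                x$methods[[m]]$mse))
  }
  invisible(x)
}

#' Run a grid of simulation conditions
#'
#' Conditions are run independently, each under its own hash-derived seed, so
#' the grid is resumable per condition; a failing condition is recorded as an
#' error entry and the run continues.
#'
#' @param conditions List of [sim_condition()] objects.
#' @param reps Replications per condition.
#' @param methods,assumed,pssa_control,base_seed,specificity Passed to
#'   [run_condition()].
#' @return An object of class `"grid_result"`: list of per-condition results
#'   (or error records) plus metadata.
#' @export
run_grid <- function(conditions, reps = 500, methods = c("or", "and", "rssa"),
                     assumed = default_assumed_accuracy(),
                     pssa_control = list(n_iter = 2000, burn_in = 500,
                                         n_chains = 1),
                     base_seed = 1, specificity = c(0.95, 0.90),
                     calibration_size = 50000) {
  if (length(conditions) == 0L) stop("empty condition list", call. = FALSE)
  results <- lapply(conditions, function(cond) {
    tryCatch(
      run_condition(cond, reps = reps, methods = methods, assumed = assumed,
                    pssa_control = pssa_control, base_seed = base_seed,
                    specificity = specificity,
                    calibration_size = calibration_size),
      error = function(e) structure(list(condition = cond,
                                         error = conditionMessage(e)),
                                    class = "condition_error"))
  })
  structure(list(results = results, reps = reps, base_seed = base_seed,
                 methods = methods,
                 package_version = as.character(packageVersion("prevcomb"))),
            class = "grid_result")
}

#' @export
#' @method as.data.frame grid_result
as.data.frame.grid_result <- function(x, ...) {
  rows <- list()
  for (res in x$results) {
    cond <- res$condition
    base <- data.frame(true_prev = cond$true_prev,
                       obs_prev_1 = cond$obs_prev[1],
                       obs_prev_2 = cond$obs_prev[2],
                       source_corr = cond$source_corr,
                       n_markers = cond$n_markers,
                       marker_corr = cond$marker_corr,
                       pattern = cond$marker_corr_pattern)
    if (inherits(res, "condition_error")) {
      rows[[length(rows) + 1L]] <- cbind(base, method = NA, mean_estimate = NA,
                                         rb = NA, mse = NA, error = res$error)
      next
    }
    for (m in names(res$methods)) {
      rows[[length(rows) + 1L]] <- cbind(
        base, method = m, mean_estimate = res$methods[[m]]$mean,
        rb = res$methods[[m]]$rb, mse = res$methods[[m]]$mse, error = NA)
    }
  }
  do.call(rbind, rows)
}

#' Write grid results as delimited text
#'
#' Writes a tidy long-format file (one row per condition x method with RB and
#' MSE) and a wide file with one row per condition and RB/MSE columns per
#' method.
#'
#' @param grid A [run_grid()] result.
#' @param dir Output directory (created if needed).
#' @return Paths of the files written, invisibly.
#' @export
write_grid_result <- function(grid, dir) {
  stopifnot(inherits(grid, "grid_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tidy <- as.data.frame(grid)
  long_path <- file.path(dir, "grid_long.csv")
  write.csv(tidy, long_path, row.names = FALSE)
  ok <- tidy[!is.na(tidy$method), ]
  wide <- stats::reshape(
    ok[, c("true_prev", "obs_prev_1", "obs_prev_2", "source_corr",
           "n_markers", "marker_corr", "pattern", "method", "rb", "mse")],
    direction = "wide", timevar = "method",
    idvar = c("true_prev", "obs_prev_1", "obs_prev_2", "source_corr",
              "n_markers", "marker_corr", "pattern"))
  wide_path <- file.path(dir, "grid_wide.csv")
  write.csv(wide, wide_path, row.names = FALSE)
  invisible(c(long_path, wide_path))
}

#' Tetrachoric correlation of two binary variables
#'
#' Maximum-likelihood tetrachoric correlation from the 2x2 table under a
#' thresholded bivariate-normal model: the thresholds are fixed at the normal
#' quantiles of the margins (their ML estimates) and the latent correlation
#' solves `P(X > h, Y > k; rho) = p11`. The confidence interval is a delta
#' method interval using Plackett's identity (the derivative of the orthant
#' probability in rho is the bivariate-normal density at the thresholds).
#'
#' @param y1,y2 0/1 vectors (both margins must be non-degenerate).
#' @param level Confidence level.
#' @return List of class `"tetrachoric"`: `rho`, `ci`, `se`, `n`, `boundary`
#'   (TRUE when an empty off-diagonal cell forced rho to +/-1).
#' @export
tetrachoric_correlation <- function(y1, y2, level = 0.95) {
  assert_binary(y1, "y1")
  assert_binary(y2, "y2")
  stopifnot(length(y1) == length(y2))
  n <- length(y1)
  m1 <- mean(y1)
  m2 <- mean(y2)
  if (m1 %in% c(0, 1) || m2 %in% c(0, 1)) {
    stop("degenerate margin: each variable needs both 0s and 1s",
         call. = FALSE)
  }
  n11 <- sum(y1 == 1L & y2 == 1L)
  n10 <- sum(y1 == 1L & y2 == 0L)
  n01 <- sum(y1 == 0L & y2 == 1L)
  n00 <- n - n11 - n10 - n01
  boundary <- FALSE
  if (n10 == 0L || n01 == 0L) {
    rho <- 1
    boundary <- TRUE
  } else if (n11 == 0L || n00 == 0L) {
    rho <- -1
    boundary <- TRUE
  } else {
    rho <- tetrachoric_from_cells(n11 / n, m1, m2)
  }
  if (boundary || abs(rho) >= 1) {
    out <- list(rho = rho, ci = c(rho, rho), se = NA_real_, n = n,
                boundary = TRUE)
    class(out) <- "tetrachoric"
    return(out)
  }
  h <- qnorm(1 - m1)
  k <- qnorm(1 - m2)
  p11 <- n11 / n
  dens <- dbinorm(h, k, rho)
  se <- sqrt(p11 * (1 - p11) / n) / dens
  z <- qnorm(1 - (1 - level) / 2)
  ci <- c(max(-1, rho - z * se), min(1, rho + z * se))
  structure(list(rho = rho, ci = ci, se = se, n = n, boundary = FALSE),
            class = "tetrachoric")
}

#' @export
#' @method print tetrachoric
print.tetrachoric <- function(x, ...) {
  if (x$boundary) {
    cat(sprintf("Tetrachoric correlation: %.0f (boundary: empty cell), n = %d\n",
                x$rho, x$n))
  } else {
    cat(sprintf("Tetrachoric correlation: %.3f (95%% CI %.3f-%.3f), n = %d\n",
                x$rho, x$ci[1], x$ci[2], x$n))
  }
  invisible(x)
}

#' Export a generated population as delimited text
#'
#' Writes one row per individual with header columns `id`, `d` (true
#' status), `y1`, `y2` (observed sources) and `x1..xK` (markers).
#'
#' @param truth 0/1 true-status vector.
#' @param sources An [observed_sources()] object.
#' @param panel A [generate_markers()] panel (or 0/1 matrix).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_population <- function(truth, sources, panel, path) {
  s <- as_observed(sources)
  x <- if (inherits(panel, "marker_panel")) panel$values else panel
  stopifnot(length(truth) == length(s$y1), nrow(x) == length(truth))
  colnames(x) <- paste0("x", seq_len(ncol(x)))
  df <- cbind(data.frame(id = seq_along(truth), d = as.integer(truth),
                         y1 = s$y1, y2 = s$y2), as.data.frame(x))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
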