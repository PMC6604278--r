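#' Sensitivity/specificity specification for one source
#'
#' @param sensitivity,specificity Proportions in (0, 1].
#' @param strict Require a strictly positive Youden index
#'   (`sensitivity + specificity > 1`). This is mandatory wherever the
#'   Rogan-Gladen correction is applied; generating specifications used by the
#'   simulator may sit exactly at Youden = 0 (an uninformative source) and can
#'   be built with `strict = FALSE`.
#' @return An object of class `"accuracy_spec"`.
#' @export
#' @examples
#' accuracy_spec(0.72, 0.95)
accuracy_spec <- function(sensitivity, specificity, strict = TRUE) {
  assert_prob(sensitivity, "sensitivity", open_high = FALSE)
  assert_prob(specificity, "specificity", open_high = FALSE)
  youden <- sensitivity + specificity - 1
  if (strict && youden <= 0) {
    stop("sensitivity + specificity must exceed 1 (positive Youden index)",
         call. = FALSE)
  }
  if (!strict && youden < -1e-12) {
    stop("sensitivity + specificity must be at least 1", call. = FALSE)
  }
  structure(list(sensitivity = sensitivity, specificity = specificity),
            class = "accuracy_spec")
}

#' @export
#' @method print accuracy_spec
print.accuracy_spec <- function(x, ...) {
  cat(sprintf("Accuracy: Sn = %.4f, Sp = %.4f (Youden %.4f)\n",
              x$sensitivity, x$specificity,
              x$sensitivity + x$specificity - 1))
  invisible(x)
}

#' Assumed accuracy for the two sources
#'
#' Bundles the per-source sensitivity/specificity pairs assumed by the RSSA
#' correction. `default_assumed_accuracy()` returns the published averages
#' from Canadian hypertension validation studies: 0.72/0.95 for administrative
#' health records and 0.87/0.90 for electronic medical records.
#'
#' @param source1,source2 [accuracy_spec()] objects.
#' @return An object of class `"accuracy_pair"`.
#' @export
accuracy_pair <- function(source1, source2) {
  stopifnot(inherits(source1, "accuracy_spec"),
            inherits(source2, "accuracy_spec"))
  structure(list(source1 = source1, source2 = source2),
            class = "accuracy_pair")
}

#' @rdname accuracy_pair
#' @export
default_assumed_accuracy <- function() {
  accuracy_pair(accuracy_spec(0.72, 0.95), accuracy_spec(0.87, 0.90))
}

#' Between-source error dependence
#'
#' Within each stratum of true status the two sources' conditional Bernoulli
#' errors are coupled through a shared Gaussian copula; this object holds the
#' stratum-specific latent correlations. Any correlation in (-1, 1) yields a
#' valid joint Bernoulli distribution under the Gaussian copula, whatever the
#' marginal sensitivities/specificities.
#'
#' @param diseased,nondiseased Latent error correlations for the diseased and
#'   non-diseased strata.
#' @return An object of class `"dependence_spec"`.
#' @export
dependence_spec <- function(diseased = 0, nondiseased = 0) {
  for (v in c(diseased, nondiseased)) {
    if (!is.finite(v) || abs(v) >= 1) {
      stop("dependence correlations must lie in (-1, 1)", call. = FALSE)
    }
  }
  structure(list(diseased = diseased, nondiseased = nondiseased),
            class = "dependence_spec")
}

# 2x2 cell probability P(Y1 = 1, Y2 = 1) implied by per-stratum accuracies and
# the shared-error Gaussian copula with common correlation r in both strata.
joint_positive_prob <- function(true_prev, acc1, acc2, r1, r0 = r1) {
  cell <- function(p1, p2, r) {
    if (p1 <= 0 || p2 <= 0) return(0)
    if (p1 >= 1) return(p2)
    if (p2 >= 1) return(p1)
    pbinorm_lower(qnorm(p1), qnorm(p2), r)
  }
  true_prev * cell(acc1$sensitivity, acc2$sensitivity, r1) +
    (1 - true_prev) * cell(1 - acc1$specificity, 1 - acc2$specificity, r0)
}

# Tetrachoric correlation implied by margins (m1, m2) and joint cell p11:
# the rho for which the thresholded bivariate normal reproduces p11.
tetrachoric_from_cells <- function(p11, m1, m2) {
  h <- qnorm(1 - m1)
  k <- qnorm(1 - m2)
  lo_ind <- pbinorm_upper(h, k, 0)
  f <- function(rho) pbinorm_upper(h, k, rho) - p11
  # monotone increasing in rho
  if (p11 <= pbinorm_upper(h, k, -0.9999)) return(-1)
  if (p11 >= pbinorm_upper(h, k, 0.9999)) return(1)
  uniroot(f, interval = c(-0.9999, 0.9999), tol = 1e-10)$root
}

#' Calibrate generating accuracy and dependence for a simulation condition
#'
#' Solves for per-source generating sensitivity/specificity and a shared-error
#' dependence parameter such that (i) the marginal constraint
#' `Sn_j * p + (1 - Sp_j) * (1 - p) = obs_prev_j` holds exactly for each
#' source, and (ii) the tetrachoric correlation between the two observed
#' indicators (computed from the implied 2x2 cell probabilities) matches the
#' condition's `source_corr`.
#'
#' The marginal constraint leaves one degree of freedom per source, closed by
#' fixing the generating specificity at the assumed RSSA values (0.95 and
#' 0.90 by default). When the implied sensitivity falls outside (0, 1] —
#' which happens whenever the observed prevalence is below the false-positive
#' floor `(1 - Sp_j)(1 - p)` — the source falls back to allocating a share
#' `fp_share` (default one half) of its observed positives to false
#' positives: `Sp_j = 1 - fp_share * obs_j / (1 - p)` and
#' `Sn_j = (1 - fp_share) * obs_j / p`. The dependence parameter is then
#' solved by monotone root-finding over the shared-error correlation. When
#' the fixed-specificity solution leaves a source too uninformative to reach
#' the correlation target, the fallback is engaged for that source as well
#' (the marginal constraint always holds exactly). For degenerate cases in
#' which dependence cannot move the joint cell at all (perfect or one-sided
#' tests) the dependence is returned as zero with
#' `dependence_saturated = TRUE` and the achieved tetrachoric recorded.
#'
#' @param condition A [sim_condition()].
#' @param specificity Length-2 vector of generating specificities to fix
#'   (perturb these to emulate a misspecified-specificity scenario).
#' @param fp_share False-positive share used by the fallback rule.
#' @return A list with elements `acc1`, `acc2` ([accuracy_spec()],
#'   non-strict), `dep` ([dependence_spec()]), the implied `cells`
#'   (2x2 probabilities), the achieved `tetrachoric`, and `fallback` flags.
#' @export
#' @examples
#' cond <- sim_condition(0.20, c(0.18, 0.15), 0.85, 16, 0)
#' calibrate_accuracy(cond)
calibrate_accuracy <- function(condition, specificity = c(0.95, 0.90),
                               fp_share = 0.5) {
  stopifnot(inherits(condition, "sim_condition"), length(specificity) == 2L)
  p <- condition$true_prev
  obs <- condition$obs_prev

  solutions <- function(j) {
    out <- list()
    sp <- specificity[j]
    sn <- (obs[j] - (1 - sp) * (1 - p)) / p
    if (sn > 0 && sn <= 1) {
      out$primary <- accuracy_spec(sn, sp, strict = FALSE)
    }
    sp_f <- 1 - fp_share * obs[j] / (1 - p)
    sn_f <- (1 - fp_share) * obs[j] / p
    if (sn_f <= 1 && sp_f > 0 && sp_f <= 1 && sn_f + sp_f >= 1) {
      out$fallback <- accuracy_spec(sn_f, sp_f, strict = FALSE)
    }
    if (length(out) == 0L) {
      stop(sprintf(
        "no feasible generating accuracy for source %d: obs %.3f at true prevalence %.3f",
        j, obs[j], p), call. = FALSE)
    }
    out
  }
  s1 <- solutions(1)
  s2 <- solutions(2)

  # dependence target: the joint cell a thresholded bivariate normal with the
  # requested tetrachoric correlation would produce for these margins
  p11_target <- pbinorm_upper(qnorm(1 - obs[1]), qnorm(1 - obs[2]),
                              condition$source_corr)
  r_hi <- 0.9999

  finish <- function(acc1, acc2, r, fallback, saturated = FALSE) {
    p11 <- joint_positive_prob(p, acc1, acc2, r)
    cells <- c(p11 = p11, p10 = obs[1] - p11, p01 = obs[2] - p11,
               p00 = 1 - obs[1] - obs[2] + p11)
    list(acc1 = acc1, acc2 = acc2, dep = dependence_spec(r, r),
         cells = cells,
         tetrachoric = tetrachoric_from_cells(p11, obs[1], obs[2]),
         fallback = fallback, dependence_saturated = saturated)
  }

  # prefer the fixed-specificity solution for each source; fall back per
  # source only when the shared-error dependence cannot reach the target
  combos <- expand.grid(a = names(s1), b = names(s2),
                        stringsAsFactors = FALSE)
  combos <- combos[order(combos$a != "primary", combos$b != "primary"), ]
  degenerate <- NULL
  ranges <- NULL
  for (i in seq_len(nrow(combos))) {
    acc1 <- s1[[combos$a[i]]]
    acc2 <- s2[[combos$b[i]]]
    fb <- c(combos$a[i] == "fallback", combos$b[i] == "fallback")
    f <- function(r) joint_positive_prob(p, acc1, acc2, r) - p11_target
    lo <- f(-r_hi)
    hi <- f(r_hi)
    if (hi - lo < 1e-10) {
      # dependence cannot move the cells (perfect or one-sided tests); the
      # fixed-specificity solution takes precedence even so
      if (i == 1L) return(finish(acc1, acc2, 0, fb, TRUE))
      if (is.null(degenerate)) degenerate <- finish(acc1, acc2, 0, fb, TRUE)
      next
    }
    if (lo <= 0 && hi >= 0) {
      r <- uniroot(f, interval = c(-r_hi, r_hi), tol = 1e-10)$root
      return(finish(acc1, acc2, r, fb))
    }
    ranges <- rbind(ranges, vapply(c(-r_hi, r_hi), function(r) {
      tetrachoric_from_cells(joint_positive_prob(p, acc1, acc2, r),
                             obs[1], obs[2])
    }, numeric(1)))
  }
  if (!is.null(degenerate)) return(degenerate)
  stop(sprintf(
    "source correlation %.2f is not attainable for this condition; attainable tetrachoric range is [%.3f, %.3f]",
    condition$source_corr, min(ranges[, 1]), max(ranges[, 2])),
    call. = FALSE)
}

#' Apply misclassification to true disease status
#'
#' Given true status `D`, each source reports positive with probability
#' `Sn_j` when `D = 1` and `1 - Sp_j` when `D = 0` (the conditional Bernoulli
#' construction with a uniform threshold). Within each stratum of `D` the two
#' sources' draws are coupled through a shared standard-normal error with the
#' stratum's dependence correlation, so marginal sensitivity and specificity
#' are preserved exactly in expectation while between-source correlation can
#' exceed the conditional-independence bound.
#'
#' @param truth Integer 0/1 vector of true status.
#' @param acc1,acc2 [accuracy_spec()] objects for the two sources.
#' @param dep A [dependence_spec()]; the default is conditional independence.
#' @param seed RNG seed.
#' @return An object of class `"observed_sources"`: list with 0/1 vectors
#'   `y1` and `y2`.
#' @export
apply_misclassification <- function(truth, acc1, acc2,
                                    dep = dependence_spec(), seed = NULL) {
  assert_binary(truth, "truth")
  stopifnot(inherits(acc1, "accuracy_spec"), inherits(acc2, "accuracy_spec"),
            inherits(dep, "dependence_spec"))
  set_seed_if(seed)
  n <- length(truth)
  d1 <- truth == 1L
  r <- ifelse(d1, dep$diseased, dep$nondiseased)
  e1 <- rnorm(n)
  e2 <- r * e1 + sqrt(1 - r^2) * rnorm(n)
  p1 <- ifelse(d1, acc1$sensitivity, 1 - acc1$specificity)
  p2 <- ifelse(d1, acc2$sensitivity, 1 - acc2$specificity)
  observed_sources(as.integer(e1 < qnorm(p1)), as.integer(e2 < qnorm(p2)))
}

#' Observed source indicators
#'
#' @param y1,y2 Equal-length 0/1 vectors, one per source.
#' @return An object of class `"observed_sources"`.
#' @export
observed_sources <- function(y1, y2) {
  if (length(y1) != length(y2)) stop("`y1` and `y2` must have equal length",
                                     call. = FALSE)
  assert_binary(y1, "y1")
  assert_binary(y2, "y2")
  structure(list(y1 = as.integer(y1), y2 = as.integer(y2)),
            class = "observed_sources")
}

#' @export
#' @method print observed_sources
print.observed_sources <- function(x, ...) {
  cat(sprintf(
    "Observed sources: n = %d, prevalences %.4f / %.4f, agreement %.4f\n",
    length(x$y1), mean(x$y1), mean(x$y2), mean(x$y1 == x$y2)))
  invisible(x)
}

as_observed <- function(sources) {
  if (inherits(sources, "observed_sources")) return(sources)
  if (is.list(sources) && all(c("y1", "y2") %in% names(sources))) {
    return(observed_sources(sources$y1, sources$y2))
  }
  stop("`sources` must be an observed_sources object or a list with y1, y2",
       call. = FALSE)
}
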