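test_that("OR and AND estimators match their definitions on explicit data", {
  s <- src(c(1, 0, 1, 0), c(0, 0, 1, 1))
  expect_equal(estimate_or(s)$point, 0.75)
  expect_equal(estimate_and(s)$point, 0.25)
  same <- src(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(estimate_or(same)$point, 0.5)
  expect_equal(estimate_and(same)$point, 0.5)
  disjoint <- src(c(1, 0, 0, 0), c(0, 1, 0, 0))
  expect_equal(estimate_or(disjoint)$point, 0.5)
  expect_error(estimate_or(src(integer(0), integer(0))), "empty")
})

test_that("ordering and inclusion-exclusion identities hold on random data", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(50:500, 1)
    s <- src(rbinom(n, 1, runif(1, 0.05, 0.6)),
             rbinom(n, 1, runif(1, 0.05, 0.6)))
    orp <- estimate_or(s)$point
    andp <- estimate_and(s)$point
    expect_lte(andp, min(mean(s$y1), mean(s$y2)))
    expect_gte(orp, max(mean(s$y1), mean(s$y2)))
    expect_equal(orp + andp, mean(s$y1) + mean(s$y2), tolerance = 1e-12)
  }
})

test_that("Rogan-Gladen correction evaluates its closed form", {
  expect_equal(rogan_gladen(0.30, accuracy_spec(0.72, 0.95)), 0.25 / 0.67,
               tolerance = 1e-12)
  expect_equal(rogan_gladen(0.15, accuracy_spec(0.87, 0.90)), 0.05 / 0.77,
               tolerance = 1e-12)
  expect_equal(rogan_gladen(0.05, accuracy_spec(0.72, 0.95)), 0)
  expect_error(rogan_gladen(0.3, accuracy_spec(0.5, 0.5, strict = FALSE)),
               "sensitivity \\+ specificity")
})

test_that("Rogan-Gladen is monotone in its arguments", {
  acc <- accuracy_spec(0.72, 0.95)
  obs <- seq(0.06, 0.5, by = 0.02)
  vals <- vapply(obs, rogan_gladen, numeric(1), acc = acc)
  expect_true(all(diff(vals) > 0))
  # decreasing in assumed sensitivity above the false-positive floor
  sns <- seq(0.55, 0.95, by = 0.05)
  vals2 <- vapply(sns, function(sn) rogan_gladen(0.3, accuracy_spec(sn, 0.95)),
                  numeric(1))
  expect_true(all(diff(vals2) < 0))
})

test_that("RSSA composes per-source corrections by unweighted average", {
  y1 <- rep(c(1L, 0L), c(1800, 8200))
  y2 <- rep(c(1L, 0L), c(1500, 8500))
  est <- estimate_rssa(src(y1, y2), ci = "none")
  expect_equal(est$point, ((0.18 - 0.05) / 0.67 + (0.15 - 0.10) / 0.77) / 2,
               tolerance = 1e-12)
  expect_equal(est$point, 0.1294825, tolerance = 1e-6)
  # identity correction: perfect assumed accuracy on identical sources
  same <- src(rep(c(1L, 0L), c(30, 70)), rep(c(1L, 0L), c(30, 70)))
  perfect <- accuracy_pair(accuracy_spec(1, 1), accuracy_spec(1, 1))
  expect_equal(estimate_rssa(same, perfect, ci = "none")$point, 0.3)
})

test_that("RSSA is unbiased under correct specification and consistent in n", {
  assumed <- default_assumed_accuracy()
  gen <- function(n, seed) {
    set.seed(seed)
    truth <- rbinom(n, 1L, 0.2)
    apply_misclassification(truth, assumed$source1, assumed$source2,
                            seed = seed + 1)
  }
  # large-n unbiasedness
  est <- estimate_rssa(gen(200000, 100), assumed, ci = "none")$point
  expect_lt(abs(est - 0.2), 0.005)
  # consistency: per-replication absolute error shrinks like n^(-1/2)
  ns <- c(1000, 10000, 100000)
  reps <- c(120, 40, 8)
  mean_abs_err <- mapply(function(n, R) {
    errs <- vapply(seq_len(R), function(r) {
      abs(estimate_rssa(gen(n, 1000 * n + r), assumed, ci = "none")$point - 0.2)
    }, numeric(1))
    mean(errs)
  }, ns, reps)
  slope <- coef(lm(log(mean_abs_err) ~ log(ns)))[2]
  expect_lt(slope, -0.3)
})

test_that("Wald intervals match textbook values", {
  expect_equal(wald_ci(0.5, 100), c(0.402, 0.598), tolerance = 5e-4)
  expect_equal(wald_ci(0, 100), c(0, 0))
  hw <- diff(wald_ci(0.3, 10000)) / 2
  expect_equal(as.numeric(hw), 1.959964 * sqrt(0.3 * 0.7 / 10000),
               tolerance = 1e-6)
  expect_error(wald_ci(0.5, 0), "at least 1")
})

test_that("percentile bootstrap behaves on degenerate, asymptotic and repeated calls", {
  set.seed(77)
  s <- src(rbinom(10000, 1, 0.3), rbinom(10000, 1, 0.25))
  # constant estimator: degenerate interval
  ci0 <- bootstrap_percentile_ci(function(y1, y2) 0.42, s, B = 50, seed = 1)
  expect_equal(ci0, c(0.42, 0.42))
  # mean estimator: agrees with the Wald interval asymptotically
  ci <- bootstrap_percentile_ci(function(y1, y2) mean(y1), s, B = 999, seed = 2)
  w <- wald_ci(mean(s$y1), 10000)
  expect_true(ci[1] <= mean(s$y1) && mean(s$y1) <= ci[2])
  expect_lt(abs(diff(ci) - diff(w)) / diff(w), 0.2)
  # determinism
  ci2 <- bootstrap_percentile_ci(function(y1, y2) mean(y1), s, B = 999, seed = 2)
  expect_identical(ci, ci2)
})

test_that("the cell-count bootstrap agrees with row resampling for RSSA", {
  set.seed(88)
  s <- src(rbinom(4000, 1, 0.3), rbinom(4000, 1, 0.25))
  fast <- estimate_rssa(s, B = 999, seed = 3)
  slow <- bootstrap_percentile_ci(
    function(y1, y2) estimate_rssa(src(y1, y2), ci = "none")$point,
    s, B = 999, seed = 3)
  expect_lt(abs(fast$ci_low - slow[1]), 0.01)
  expect_lt(abs(fast$ci_high - slow[2]), 0.01)
  expect_lt(abs(diff(c(fast$ci_low, fast$ci_high)) - diff(slow)) / diff(slow),
            0.15)
})

test_that("RSSA bootstrap interval attains nominal coverage under correct specification", {
  assumed <- default_assumed_accuracy()
  n_data <- 500
  covered <- logical(n_data)
  for (i in seq_len(n_data)) {
    set.seed(3000 + i)
    truth <- rbinom(2000, 1L, 0.2)
    s <- apply_misclassification(truth, assumed$source1, assumed$source2,
                                 seed = 4000 + i)
    est <- estimate_rssa(s, assumed, B = 999, seed = 5000 + i)
    covered[i] <- est$ci_low <= 0.2 && 0.2 <= est$ci_high
  }
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})
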