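test_that("marginal accuracy calibration solves the constraint algebra", {
  cond <- sim_condition(0.20, c(0.18, 0.15), 0.85, 8, 0)
  cal <- calibrate_accuracy(cond)
  # Sn = (obs - (1 - Sp)(1 - p)) / p with Sp fixed at 0.95
  expect_equal(cal$acc1$sensitivity, (0.18 - 0.05 * 0.80) / 0.20,
               tolerance = 1e-12)
  expect_equal(cal$acc1$specificity, 0.95)
  # substitution: marginal constraint holds exactly for both sources
  for (j in 1:2) {
    acc <- cal[[paste0("acc", j)]]
    obs <- acc$sensitivity * 0.20 + (1 - acc$specificity) * 0.80
    expect_equal(obs, cond$obs_prev[j], tolerance = 1e-10)
  }
  # achieved tetrachoric matches the target
  expect_lt(abs(cal$tetrachoric - 0.85), 0.01)
})

test_that("error-free boundary: observed prevalence equal to truth with perfect specificity", {
  cond <- sim_condition(0.10, c(0.10, 0.10), 0.9, 8, 0)
  cal <- calibrate_accuracy(cond, specificity = c(1, 1))
  expect_equal(cal$acc1$sensitivity, 1.0)
  expect_equal(cal$acc2$sensitivity, 1.0)
})

test_that("fallback calibration engages below the false-positive floor", {
  # obs 0.05 for source 2 at true prev 0.10 sits below (1 - 0.90) * 0.90
  cond <- sim_condition(0.10, c(0.08, 0.05), 0.85, 16, 0)
  cal <- calibrate_accuracy(cond)
  expect_false(cal$fallback[1])
  expect_true(cal$fallback[2])
  for (j in 1:2) {
    acc <- cal[[paste0("acc", j)]]
    obs <- acc$sensitivity * 0.10 + (1 - acc$specificity) * 0.90
    expect_equal(obs, cond$obs_prev[j], tolerance = 1e-10)
    expect_gte(acc$sensitivity + acc$specificity, 1)
  }
})

test_that("calibration round-trips through Monte-Carlo generation", {
  cond <- sim_condition(0.20, c(0.15, 0.15), 0.85, 8, 0)
  cal <- calibrate_accuracy(cond)
  n <- 200000
  set.seed(11)
  truth <- rbinom(n, 1L, 0.20)
  s <- apply_misclassification(truth, cal$acc1, cal$acc2, cal$dep, seed = 12)
  expect_lt(abs(mean(s$y1) - 0.15), 0.005)
  expect_lt(abs(mean(s$y2) - 0.15), 0.005)
  expect_lt(abs(tetrachoric_correlation(s$y1, s$y2)$rho - 0.85), 0.03)
})

test_that("round-trip calibration holds across feasible reference-design cells", {
  cells <- list(list(0.20, c(0.18, 0.10), 0.65),
                list(0.10, c(0.08, 0.07), 0.85),
                list(0.10, c(0.05, 0.05), 0.65))
  for (cell in cells) {
    cond <- sim_condition(cell[[1]], cell[[2]], cell[[3]], 8, 0)
    cal <- calibrate_accuracy(cond)
    set.seed(13)
    truth <- rbinom(200000, 1L, cond$true_prev)
    expect_lt(abs(mean(truth) - cond$true_prev), 0.005)
    s <- apply_misclassification(truth, cal$acc1, cal$acc2, cal$dep, seed = 14)
    expect_lt(abs(mean(s$y1) - cond$obs_prev[1]), 0.005)
    expect_lt(abs(mean(s$y2) - cond$obs_prev[2]), 0.005)
    expect_lt(abs(tetrachoric_correlation(s$y1, s$y2)$rho - cond$source_corr),
              0.03)
  }
})

test_that("infeasible conditions raise informative errors", {
  # no sensitivity/specificity pair can produce these margins
  cond <- sim_condition(0.10, c(0.90, 0.05), 0.5, 8, 0)
  expect_error(calibrate_accuracy(cond), "no feasible generating accuracy")
  # margins solvable, but no joint distribution reaches the correlation
  cond2 <- sim_condition(0.60, c(0.50, 0.10), 0.95, 8, 0)
  expect_error(calibrate_accuracy(cond2), "attainable tetrachoric range")
})

test_that("misclassification preserves marginal accuracy and perfect tests are identity", {
  truth <- rbinom(1000, 1L, 0.3)
  perfect <- accuracy_spec(1, 1)
  s <- apply_misclassification(truth, perfect, perfect, seed = 1)
  expect_identical(s$y1, as.integer(truth))
  expect_identical(s$y2, as.integer(truth))

  set.seed(21)
  truth <- rbinom(200000, 1L, 0.2)
  acc1 <- accuracy_spec(0.72, 0.95)
  s <- apply_misclassification(truth, acc1, acc1, seed = 22)
  expect_lt(abs(mean(s$y1[truth == 1L]) - 0.72), 0.005)
  expect_lt(abs(mean(1 - s$y1[truth == 0L]) - 0.95), 0.005)
})

test_that("zero dependence yields conditional independence within strata", {
  set.seed(31)
  truth <- rbinom(200000, 1L, 0.2)
  s <- apply_misclassification(truth, accuracy_spec(0.7, 0.9),
                               accuracy_spec(0.8, 0.85),
                               dependence_spec(0, 0), seed = 32)
  for (d in 0:1) {
    expect_lt(abs(cor(s$y1[truth == d], s$y2[truth == d])), 0.01)
  }
})

test_that("with independent errors the phi correlation respects the analytic bound", {
  set.seed(41)
  configs <- list(c(0.7, 0.9, 0.8, 0.85, 0.2),
                  c(0.35, 0.95, 0.25, 0.97, 0.1),
                  c(0.9, 0.99, 0.85, 0.95, 0.3))
  for (cf in configs) {
    acc1 <- accuracy_spec(cf[1], cf[2], strict = FALSE)
    acc2 <- accuracy_spec(cf[3], cf[4], strict = FALSE)
    p <- cf[5]
    truth <- rbinom(100000, 1L, p)
    s <- apply_misclassification(truth, acc1, acc2, dependence_spec(0, 0))
    # analytic joint cells under conditional independence
    m1 <- cf[1] * p + (1 - cf[2]) * (1 - p)
    m2 <- cf[3] * p + (1 - cf[4]) * (1 - p)
    p11 <- p * cf[1] * cf[3] + (1 - p) * (1 - cf[2]) * (1 - cf[4])
    phi_bound <- (p11 - m1 * m2) / sqrt(m1 * (1 - m1) * m2 * (1 - m2))
    expect_lte(cor(s$y1, s$y2), phi_bound + 0.015)
  }
})

test_that("misclassification is deterministic under a fixed seed", {
  truth <- rbinom(500, 1L, 0.2)
  acc <- accuracy_spec(0.8, 0.9)
  dep <- dependence_spec(0.5, 0.5)
  a <- apply_misclassification(truth, acc, acc, dep, seed = 9)
  b <- apply_misclassification(truth, acc, acc, dep, seed = 9)
  expect_identical(a$y1, b$y1)
  expect_identical(a$y2, b$y2)
})

test_that("accuracy and dependence specs validate their invariants", {
  expect_error(accuracy_spec(0.3, 0.6), "Youden")
  expect_silent(accuracy_spec(0.05, 0.95, strict = FALSE))
  expect_error(accuracy_spec(0.02, 0.95, strict = FALSE), "at least 1")
  expect_error(dependence_spec(1.2), "\\(-1, 1\\)")
})
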