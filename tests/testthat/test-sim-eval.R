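test_that("relative bias and MSE evaluate their formulas", {
  expect_equal(relative_bias(rep(0.105, 5), 0.20), 47.5)
  expect_equal(relative_bias(c(0.19, 0.21), 0.20), 0)
  expect_equal(relative_bias(rep(0.18, 3), 0.20), 10.0)
  expect_error(relative_bias(numeric(0), 0.2), "empty")
  expect_error(relative_bias(0.1, 0), "positive")

  expect_equal(mean_squared_error(rep(0.105, 5), 0.20), 100 * 0.095^2)
  expect_equal(mean_squared_error(c(0.1, 0.3), 0.2), 1.0)
  sym <- 0.2 + c(-0.02, -0.01, 0.01, 0.02)
  expect_equal(mean_squared_error(sym, 0.2), 100 * mean((sym - 0.2)^2))
  expect_equal(mean_squared_error(0.15, 0.2), 100 * 0.05^2)
})

test_that("MSE decomposes exactly into variance plus squared bias", {
  set.seed(3)
  for (i in 1:10) {
    est <- runif(sample(5:60, 1), 0.05, 0.4)
    truth <- runif(1, 0.1, 0.3)
    mse <- mean_squared_error(est, truth)
    bias2 <- (truth - mean(est))^2
    expect_equal(mse / 100 - bias2, mean((est - mean(est))^2),
                 tolerance = 1e-12)
  }
})

test_that("a perfect-accuracy condition yields near-zero bias for the rule-based methods", {
  cond <- sim_condition(0.20, c(0.20, 0.20), 0.9, 4, 0,
                        population_size = 5000)
  perfect <- accuracy_spec(1, 1)
  res <- run_condition(cond, reps = 30, methods = c("or", "and", "rssa"),
                       assumed = accuracy_pair(perfect, perfect),
                       accuracy = list(acc1 = perfect, acc2 = perfect),
                       base_seed = 2, calibration_size = 20000)
  for (m in c("or", "and", "rssa")) {
    expect_lt(res$methods[[m]]$rb, 1.0)
    expect_lt(res$methods[[m]]$mse, 0.01)
  }
})

test_that("condition runs are deterministic and invariant to replication order", {
  cond <- sim_condition(0.10, c(0.08, 0.07), 0.85, 4, 0,
                        population_size = 1000)
  a <- run_condition(cond, reps = 5, methods = c("or", "rssa"),
                     base_seed = 5, calibration_size = 5000)
  b <- run_condition(cond, reps = 5, methods = c("or", "rssa"),
                     base_seed = 5, calibration_size = 5000)
  expect_identical(a$methods$or$estimates, b$methods$or$estimates)
  expect_identical(a$methods$rssa$mse, b$methods$rssa$mse)
  # aggregates do not depend on replication order
  shuffled <- sample(a$methods$or$estimates)
  expect_equal(relative_bias(shuffled, 0.1), a$methods$or$rb)
  expect_equal(mean_squared_error(shuffled, 0.1), a$methods$or$mse)
})

test_that("the full reference grid runs end to end at smoke scale", {
  obs_by_prev <- list(`0.2` = list(c(0.18, 0.15), c(0.18, 0.10), c(0.15, 0.15)),
                      `0.1` = list(c(0.08, 0.07), c(0.08, 0.05), c(0.05, 0.05)))
  conditions <- list()
  for (tp in c(0.2, 0.1)) {
    for (obs in obs_by_prev[[as.character(tp)]]) {
      for (sc in c(0.65, 0.85)) {
        for (k in c(8, 16)) {
          for (mc in c(0, 0.2, 0.5)) {
            for (pat in c("exchangeable", "unstructured")) {
              conditions[[length(conditions) + 1L]] <-
                sim_condition(tp, obs, sc, k, mc, pat, population_size = 400)
            }
          }
        }
      }
    }
  }
  expect_length(conditions, 144)
  grid <- run_grid(conditions, reps = 3, methods = c("or", "and", "rssa"),
                   base_seed = 11, calibration_size = 4000)
  df <- as.data.frame(grid)
  ok <- df[is.na(df$error), ]
  expect_equal(length(unique(paste(df$true_prev, df$obs_prev_1, df$obs_prev_2,
                                   df$source_corr, df$n_markers,
                                   df$marker_corr, df$pattern))), 144)
  expect_true(all(is.finite(ok$rb)))
  expect_true(all(is.finite(ok$mse)))
  expect_true(all(is.na(df$error)))

  # single-condition re-run reproduces the stored entry exactly
  res17 <- run_condition(conditions[[17]], reps = 3,
                         methods = c("or", "and", "rssa"), base_seed = 11,
                         calibration_size = 4000)
  expect_identical(res17$methods$or$estimates,
                   grid$results[[17]]$methods$or$estimates)

  # writers round-trip
  dir <- tempfile()
  write_grid_result(grid, dir)
  back <- read.csv(file.path(dir, "grid_long.csv"))
  expect_equal(nrow(back), 144 * 3)
  unlink(dir, recursive = TRUE)
})

test_that("tetrachoric correlation matches definition cases and a numerical oracle", {
  y <- rep(c(1L, 0L), c(30, 70))
  t_same <- tetrachoric_correlation(y, y)
  expect_equal(t_same$rho, 1)
  expect_true(t_same$boundary)

  set.seed(12)
  a <- rbinom(100000, 1, 0.3)
  b <- rbinom(100000, 1, 0.4)
  expect_lt(abs(tetrachoric_correlation(a, b)$rho), 0.03)

  # 2x2 counts (40, 10; 10, 40) against a brute-force orthant ML search
  y1 <- rep(c(1L, 1L, 0L, 0L), c(40, 10, 10, 40))
  y2 <- rep(c(1L, 0L, 1L, 0L), c(40, 10, 10, 40))
  fit <- tetrachoric_correlation(y1, y2)
  h <- qnorm(1 - 0.5)
  rhos <- seq(-0.99, 0.99, by = 0.001)
  ll <- vapply(rhos, function(r) {
    p11 <- riemann_orthant(h, h, r, n_grid = 250)
    p10 <- 0.5 - p11
    40 * log(p11) + 10 * log(p10) + 10 * log(p10) + 40 * log(1 - 2 * 0.5 + p11)
  }, numeric(1))
  oracle <- rhos[which.max(ll)]
  expect_lt(abs(fit$rho - oracle), 0.001 + 1e-8)
  expect_true(fit$ci[1] <= fit$rho && fit$rho <= fit$ci[2])

  expect_error(tetrachoric_correlation(rep(1L, 10), rbinom(10, 1, 0.5)),
               "degenerate margin")
})

test_that("generated populations export with the standard column layout", {
  panel <- generate_markers(50, c(0.2, 0.3), diag(2), seed = 1)
  truth <- generate_truth(panel, disease_model(qlogis(0.2), c(0, 0)), seed = 2)
  s <- apply_misclassification(truth, accuracy_spec(0.8, 0.95),
                               accuracy_spec(0.9, 0.9), seed = 3)
  path <- tempfile(fileext = ".csv")
  write_population(truth, s, panel, path)
  back <- read.csv(path)
  expect_equal(names(back), c("id", "d", "y1", "y2", "x1", "x2"))
  expect_equal(back$d, as.integer(truth))
  expect_equal(back$y1, s$y1)
  unlink(path)
})
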