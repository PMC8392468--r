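test_that("prediction tables validate their inputs", {
  expect_error(prediction_table(c("111111", "111111"), c(1, 1), c(1, 1)),
               "duplicate")
  expect_error(prediction_table("111111", 1.5, 1), "\\[-1, 1\\]")
  expect_error(prediction_table("111111", 1, 0.9, -0.1), "non-negative")
  tb <- prediction_table(c("111111", "645655"), c(1, 0.32), c(1, 0.35),
                         c(0, 0.02))
  expect_s3_class(tb, "prediction_table")
})

test_that("rmse and agreement behave on degenerate tables", {
  tb <- prediction_table(c("a1" = "111111", "645655"), c(1, 0.3), c(1, 0.3))
  expect_equal(rmse(tb), 0)
  off <- prediction_table(c("111621", "645655", "123432"),
                          c(0.8, 0.3, 0.6), c(0.75, 0.25, 0.55))
  a <- bland_altman(off)
  expect_equal(a$mean_bias, 0.05)
  expect_equal(a$diff_sd, 0)
  expect_equal(a$loa_range, 0)
  expect_error(bland_altman(off[1, ]), "two rows")
})

test_that("agreement internal identities hold for arbitrary tables", {
  set.seed(61)
  for (i in 1:10) {
    n <- sample(3:40, 1)
    st <- sample(enumerate_states(), n)
    obs <- runif(n, -0.5, 1)
    pred <- pmin(1, pmax(-1, obs + rnorm(n, 0, 0.05)))
    a <- bland_altman(prediction_table(st, obs, pred))
    expect_equal(a$loa_range, a$loa_high - a$loa_low)
    expect_equal(a$loa_range, 2 * 1.96 * a$diff_sd)
    expect_equal(a$loa_low, a$mean_bias - 1.96 * a$diff_sd)
    expect_gte(rmse(prediction_table(st, obs, pred)), abs(a$mean_bias))
  }
})

test_that("published-table metrics are reproduced from the fixture", {
  t1 <- table1_fixture()
  expect_identical(nrow(t1), 51L)
  expect_true("111111" %in% t1$state)
  crude <- prediction_table(t1$state, t1$observed_mean, t1$crude_mean,
                            t1$crude_sd)
  model1 <- prediction_table(t1$state, t1$observed_mean, t1$model1_mean,
                             t1$model1_sd)
  expect_equal(rmse(crude), 0.035, tolerance = 0.002 / 0.035)
  expect_equal(rmse(model1), 0.028, tolerance = 0.002 / 0.028)
  ac <- bland_altman(crude)
  am <- bland_altman(model1)
  expect_lt(abs(ac$loa_range - 0.136), 0.003)
  expect_lt(abs(am$loa_range - 0.109), 0.003)
  expect_lt(abs(ac$diff_sd - 0.035), 0.002)
  expect_lt(abs(am$diff_sd - 0.027), 0.001)
  expect_lt(abs(ac$mean_bias - 0.0064), 0.001)
  expect_lt(abs(am$mean_bias - 0.0049), 0.001)
  expect_lt(rmse(model1), rmse(crude))
})

test_that("monotonicity audit scores monotone and noise predictors correctly", {
  sys <- sf6d_system()
  # strictly monotone: linear with negative per-level increments
  lin <- function(codes) {
    Xc <- sweep(state_levels(codes, sys), 2, rep(1, 6))
    1 - drop(Xc %*% rep(0.03, 6))
  }
  r <- monotonicity_audit(lin, sys, n_pairs = 2000L, seed = 1)
  expect_identical(r$n_violations, 0L)
  expect_equal(r$violation_rate, 0)

  # constant predictor: all ties, no violations
  r0 <- monotonicity_audit(function(codes) rep(0.5, length(codes)), sys,
                           n_pairs = 1000L, seed = 2)
  expect_identical(r0$n_violations, 0L)

  # independent uniform noise: rate near 1/2 at 10,000 pairs
  noise <- function(codes) {
    vapply(codes, function(s) {
      set.seed(as.integer(s))
      runif(1)
    }, numeric(1))
  }
  rn <- monotonicity_audit(noise, sys, n_pairs = 10000L, seed = 3)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(rn$violation_rate - 0.5), 3 * se + 0.01)

  # identical reports under a fixed seed, and sampling without replacement
  expect_identical(monotonicity_audit(lin, sys, n_pairs = 500L, seed = 9),
                   monotonicity_audit(lin, sys, n_pairs = 500L, seed = 9))
  expect_identical(r$violation_rate, r$n_violations / r$n_pairs)
})

test_that("cost-per-QALY arithmetic matches the worked example", {
  q <- qaly_cost_illustration(0.5, 0.54, 1, 10000)
  expect_equal(q$cost_per_qaly_a, 20000)
  expect_equal(round(q$cost_per_qaly_b), 18519)
  expect_equal(floor(q$cost_per_qaly_b), 18518)
  same <- qaly_cost_illustration(0.7, 0.7, 2, 5000)
  expect_equal(same$cost_per_qaly_a, same$cost_per_qaly_b)
  dbl <- qaly_cost_illustration(0.5, 0.54, 2, 10000)
  expect_equal(dbl$cost_per_qaly_a, q$cost_per_qaly_a / 2)
  expect_error(qaly_cost_illustration(0, 0.5, 1, 100), "\\(0, 1\\]")
})

test_that("model comparison consolidates agreement, ordering and scatter data", {
  t1 <- table1_fixture()
  tabs <- list(crude = prediction_table(t1$state, t1$observed_mean,
                                        t1$crude_mean),
               model1 = prediction_table(t1$state, t1$observed_mean,
                                         t1$model1_mean))
  cmp <- compare_models(tabs)
  expect_identical(nrow(cmp$agreement), 2L)
  expect_lt(cmp$agreement$rmse[cmp$agreement$model == "model1"],
            cmp$agreement$rmse[cmp$agreement$model == "crude"])
  f1c <- cmp$figure1[cmp$figure1$model == "crude", ]
  expect_false(is.unsorted(f1c$predicted))
  expect_identical(nrow(cmp$figure3), 2L * nrow(t1))

  # identical tables give identical reports
  cmp2 <- compare_models(list(a = tabs$crude, b = tabs$crude))
  expect_equal(cmp2$agreement$rmse[1], cmp2$agreement$rmse[2])
  expect_error(compare_models(list(a = tabs$crude,
                                   b = tabs$model1[-1, ])),
               "same states")
})
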