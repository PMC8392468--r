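make_donor <- function(states, mean, sd = 0.02) {
  country_posterior(c(full_health_code(), states), c(1, mean),
                    diag(c(0, rep(sd^2, length(states)))))
}

test_that("transfer prior sums donor moments and adds the fresh GP layer", {
  states <- c("123432", "213243", "322221")
  d1 <- make_donor(states, c(0.8, 0.7, 0.6), sd = 0.03)
  d2 <- make_donor(states, c(0.75, 0.65, 0.55), sd = 0.05)

  # degenerate plug-in: zero offsets, vanishing fresh layer, noiseless donor
  d0 <- make_donor(states, c(0.8, 0.7, 0.6), sd = 0)
  tp0 <- build_transfer_prior(d0, states, sigma_sq = 0)
  expect_equal(tp0$mean, c(0.8, 0.7, 0.6))
  expect_equal(unname(tp0$cov), matrix(0, 3, 3))

  # n = 1 reduces the n-country form to the two-country form elementwise
  tp1 <- build_transfer_prior(d1, states, offset_intercept = -0.05,
                              offset_slopes = rep(0.01, 6), sigma_sq = 0.04)
  Xc <- sweep(state_levels(states), 2, rep(1, 6))
  expect_equal(tp1$mean,
               unname(d1$mean[match(states, d1$states)] - 0.05 +
                        drop(Xc %*% rep(0.01, 6))))
  expect_equal(tp1$cov,
               unname(d1$cov[match(states, d1$states),
                             match(states, d1$states)] +
                        0.04 * kernel_matrix(states, jitter = 0)))

  # n = 2: covariance is the elementwise sum of donor covariances + GP layer
  tp2 <- build_transfer_prior(list(d1, d2), states, sigma_sq = 0.02)
  i1 <- match(states, d1$states); i2 <- match(states, d2$states)
  expect_equal(tp2$donor_cov, d1$cov[i1, i1] + d2$cov[i2, i2])
  expect_equal(tp2$mean, d1$mean[i1] + d2$mean[i2])
  expect_equal(tp2$cov,
               unname(tp2$donor_cov + 0.02 * kernel_matrix(states, jitter = 0)))

  # zero-mean donors with zero offsets give the zero prior mean function
  z1 <- country_posterior(states, rep(0, 3), diag(0.01, 3))
  z2 <- country_posterior(states, rep(0, 3), diag(0.01, 3))
  expect_equal(build_transfer_prior(list(z1, z2), states, sigma_sq = 0)$mean,
               rep(0, 3))

  # donor missing a target state is an explicit error
  expect_error(build_transfer_prior(d1, c(states, "645655")), "645655")
})

test_that("transfer fit recovers known cross-country offsets", {
  sc <- tiny_scenario(seed = 31, n_states = 24L, n_resp = 40L, quota = 8L)
  sc$target_states <- sc$donor_states[1:16]
  truth <- quiet(sample_true_utilities(sc))
  vals <- generate_valuations(truth)
  don <- country_posterior(c(full_health_code(), names(truth$u_donor)),
                           c(1, truth$u_donor),
                           matrix(0, length(truth$u_donor) + 1,
                                  length(truth$u_donor) + 1))
  cfg <- mcmc_config(n_iterations = 2500, n_burnin = 800, thin = 2, seed = 31)
  fit <- quiet(fit_transfer(vals$target, don, config = cfg))
  th <- fit$draws$theta
  tr <- sc$truth
  ci_g <- quantile(th[, 1], c(0.025, 0.975))
  expect_gt(tr$transfer_gamma, ci_g[1])
  expect_lt(tr$transfer_gamma, ci_g[2])
  # slope offsets: truth inside a modestly widened interval for each
  for (d in 1:6) {
    ci <- quantile(th[, d + 1], c(0.005, 0.995))
    expect_gt(tr$transfer_beta[d], ci[1])
    expect_lt(tr$transfer_beta[d], ci[2])
  }
})

test_that("a vacuous donor reproduces the crude posterior within Monte-Carlo error", {
  sc <- tiny_scenario(seed = 17, n_states = 6L, n_resp = 40L, quota = 6L)
  truth <- quiet(sample_true_utilities(sc))
  vals <- generate_valuations(truth)
  data <- vals$donor
  states <- sort(unique(data$state))
  vague <- country_posterior(c(full_health_code(), states),
                             c(1, rep(0.7, length(states))),
                             diag(c(0, rep(25, length(states)))))
  cfg <- mcmc_config(n_iterations = 4000, n_burnin = 1000, thin = 1, seed = 17)
  fc <- quiet(fit_crude(data, config = cfg, mean_basis = "intercept"))
  ft <- quiet(fit_transfer(data, vague, config = cfg, mean_basis = "intercept"))
  # compare the identified population means: the latent u itself differs
  # slightly along the multiplier/disutility scale direction, which the
  # data cannot distinguish, but ubar = 1 - alpha_bar (1 - u) must agree
  # in the data-dominant regime
  ubc <- 1 - fc$draws$alpha_bar * (1 - fc$draws$u)
  ubt <- 1 - ft$draws$alpha_bar * (1 - ft$draws$u)
  expect_lt(max(abs(colMeans(ubc) - colMeans(ubt))), 0.01)
})

test_that("transfer posterior shrinks the pits state between donor prior and data", {
  # donor says pits = 0.30 (confident); target data say 0.50 (light noise)
  states <- c("645655", "123432", "213243")
  don <- make_donor(states, c(0.30, 0.75, 0.70), sd = 0.015)
  set.seed(40)
  df <- data.frame(respondent_id = rep(sprintf("r%02d", 1:12), each = 3),
                   state = rep(states, 12))
  obs_u <- c(0.50, 0.80, 0.72)
  df$y <- obs_u[match(df$state, states)] + rnorm(nrow(df), 0, 0.03)
  cfg <- mcmc_config(n_iterations = 2000, n_burnin = 600, thin = 2, seed = 40)
  fit <- quiet(fit_transfer(df, don, config = cfg, mean_basis = "intercept"))
  pits_mean <- colMeans(fit$draws$u)[match("645655", fit$states)]
  data_mean <- mean(df$y[df$state == "645655"])
  expect_gt(pits_mean, 0.30)
  expect_lt(pits_mean, data_mean)
})

test_that("the two-stage plug-in never mutates donor bundles", {
  sc <- tiny_scenario(seed = 19, n_states = 6L, n_resp = 10L, quota = 4L)
  truth <- quiet(sample_true_utilities(sc))
  vals <- generate_valuations(truth)
  states <- sort(unique(vals$donor$state))
  don <- make_donor(c(states, "131313"), c(truth$u_donor[states], 0.5))
  snapshot <- unserialize(serialize(don, NULL))
  cfg <- mcmc_config(n_iterations = 300, n_burnin = 100, thin = 2, seed = 19)
  fit <- quiet(fit_transfer(vals$donor, don, config = cfg,
                            mean_basis = "intercept"))
  expect_identical(don, snapshot)
  invisible(predict_states(fit, "131313"))
  expect_identical(don, snapshot)
})
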