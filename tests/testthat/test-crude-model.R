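test_that("sampler is deterministic given seed, and draws satisfy invariants", {
  f1 <- tiny_fit(seed = 2)$fit
  f2 <- tiny_fit(seed = 2)$fit
  expect_identical(f1$draws$u, f2$draws$u)
  expect_identical(f1$draws$sigma_sq, f2$draws$sigma_sq)

  d <- f1$draws
  expect_true(all(d$tau_sq > 0))
  expect_true(all(d$v_sq > 0))
  expect_true(all(d$sigma_sq > 0))
  expect_true(all(d$alpha > 0))
  expect_equal(d$alpha_bar, exp(d$gamma0 + d$tau_sq / 2))
})

test_that("with multipliers pinned at 1 and tiny noise the posterior tracks state means", {
  # y = u(x) + eps with eps ~ N(0, 1e-6): posterior mean at each valued
  # state must sit on the per-state sample mean within Monte-Carlo error
  states <- c("123432", "213243", "322221", "645655")
  set.seed(9)
  df <- data.frame(respondent_id = rep(sprintf("r%02d", 1:10), each = 4),
                   state = rep(states, times = 10))
  u_true <- c(0.8, 0.7, 0.6, 0.35)
  df$y <- u_true[match(df$state, states)] + rnorm(nrow(df), 0, 1e-3)
  cfg <- mcmc_config(n_iterations = 1200, n_burnin = 400, thin = 1, seed = 1,
                     fix = list(alpha = 1, gamma0 = 0, tau_sq = 1e-6,
                                v_sq = 1e-6))
  fit <- fit_crude(df, config = cfg, mean_basis = "intercept")
  sample_means <- tapply(df$y, df$state, mean)[fit$states]
  expect_lt(max(abs(colMeans(fit$draws$u) - sample_means)), 2e-3)
})

test_that("u block update matches the closed-form GP regression in the linear-Gaussian case", {
  # alpha pinned at 1, all variances and the (flat) GP mean pinned: the
  # model reduces to y = u + eps with a known GP prior, so the posterior
  # of u is available in closed form from dense-matrix algebra
  states <- c("123432", "213243", "645655")
  set.seed(13)
  df <- data.frame(respondent_id = rep(c("a", "b", "c", "d"), each = 3),
                   state = rep(states, times = 4))
  df$y <- c(0.8, 0.7, 0.3)[match(df$state, states)] + rnorm(12, 0, 0.05)
  v_sq <- 0.05^2; sigma_sq <- 0.04; m0 <- 0.6
  cfg <- mcmc_config(n_iterations = 4200, n_burnin = 200, thin = 1, seed = 2,
                     fix = list(alpha = 1, gamma0 = 0, tau_sq = 1e-6,
                                v_sq = v_sq, sigma_sq = sigma_sq,
                                theta = m0))
  fit <- fit_crude(df, config = cfg, mean_basis = "intercept")

  # oracle: condition the anchored GP prior on the data by brute force
  b <- default_roughness()
  C <- kernel_matrix(states, b, jitter = 0)
  c0 <- sapply(states, function(s) kernel_correlation(s, "111111", b))
  Cc <- sigma_sq * (C - tcrossprod(c0))
  diag(Cc) <- diag(Cc) + cfg$jitter
  mu <- m0 + c0 * (1 - m0)
  Z <- outer(as.character(df$state), states, "==") * 1
  P <- solve(Cc) + crossprod(Z) / v_sq
  post_mean <- solve(P, solve(Cc, mu) + crossprod(Z, df$y) / v_sq)
  expect_lt(max(abs(colMeans(fit$draws$u) - post_mean)), 0.004)
  # and the draw-to-draw spread matches the closed-form posterior sd
  expect_lt(max(abs(apply(fit$draws$u, 2, sd) - sqrt(diag(solve(P))))), 0.004)
})

test_that("population mean utility applies the log-normal multiplier mean per draw", {
  tf <- tiny_fit(seed = 3)
  fit <- tf$fit
  # closed form: gamma0 = 0.1, tau^2 = 0.04 gives alpha_bar = e^0.12
  expect_equal(exp(0.1 + 0.04 / 2), exp(0.12))
  expect_equal(fit$draws$alpha_bar, exp(fit$draws$gamma0 + fit$draws$tau_sq / 2))

  pm <- population_mean_utility(fit, c(full_health_code(), fit$states[1:3]))
  expect_equal(pm$mean[1], 1)
  expect_equal(pm$sd[1], 0)
  ub <- 1 - fit$draws$alpha_bar * (1 - fit$draws$u[, 1])
  expect_equal(pm$mean[2], mean(ub))
  expect_equal(pm$sd[2], sd(ub))
})

test_that("GP prediction reproduces modelled states and matches the partition oracle", {
  states <- c("123432", "213243", "322221")
  fit <- structure(list(
    draws = list(u = matrix(c(0.82, 0.71, 0.55), 1), theta = matrix(0.6, 1),
                 sigma_sq = 0.05, alpha_bar = 1),
    states = states, levels = state_levels(states),
    system = sf6d_system(), roughness = default_roughness(),
    mean_basis = "intercept", config = mcmc_config(), model = "crude",
    donors = NULL, donor_weights = NULL, n_respondents = 2, n_obs = 6),
    class = "valuation_fit")

  new <- "645655"
  U <- sf6dvalue:::.posterior_u_draws(fit, c(states, new), method = "mean")
  expect_identical(unname(U[1, 1:3]), fit$draws$u[1, ])

  # brute-force joint-normal partition over (3 modelled, anchor, new)
  b <- default_roughness(); jit <- fit$config$jitter
  all5 <- c(states, "111111", new)
  K <- fit$draws$sigma_sq * kernel_matrix(all5, b, jitter = 0)
  m <- rep(0.6, 5)
  obs <- 1:4
  Koo <- K[obs, obs]; diag(Koo) <- diag(Koo) + fit$draws$sigma_sq * jit
  u_obs <- c(fit$draws$u[1, ], 1)
  cond_mean <- m[5] + K[5, obs] %*% solve(Koo, u_obs - m[obs])
  expect_equal(unname(U[1, 4]), drop(cond_mean), tolerance = 1e-10)

  # far-away limit: a state nearly uncorrelated with everything reverts to
  # the GP mean function
  far_fit <- fit
  far_fit$roughness <- rep(3, 6)
  Ufar <- sf6dvalue:::.posterior_u_draws(far_fit, "434343", method = "mean")
  expect_equal(unname(Ufar[1, 1]), 0.6, tolerance = 1e-3)
})

test_that("exported posterior covariance equals the empirical covariance of the draws", {
  tf <- tiny_fit(seed = 5)
  fit <- tf$fit
  cp <- export_posterior(fit)
  expect_identical(cp$states[1], full_health_code())
  expect_equal(cp$mean[1], 1)
  expect_equal(cp$sd[1], 0)
  idx <- match(fit$states, cp$states)
  expect_equal(cp$mean[idx], unname(colMeans(fit$draws$u)))
  expect_equal(unname(cp$cov[idx, idx]), unname(cov(fit$draws$u)))

  # permutation invariance: reordering states permutes mean and cov
  perm <- rev(fit$states)
  cp2 <- export_posterior(fit, states = perm)
  expect_equal(cp2$mean, cp$mean[match(perm, cp$states)])
  expect_equal(unname(cp2$cov),
               unname(cp$cov[match(perm, cp$states), match(perm, cp$states)]))
})

test_that("fit validates its inputs", {
  df <- data.frame(respondent_id = c("a", "a", "b", "b"),
                   state = c("111111", "123432", "111111", "123432"),
                   y = c(1, 0.5, 1, 0.6))
  expect_error(fit_crude(df), "anchored")
  df2 <- data.frame(respondent_id = c("a", "b"), state = c("123432", "123432"),
                    y = c(0.5, 0.6))
  expect_error(fit_crude(df2), "distinct states")
  df3 <- data.frame(respondent_id = c("a", "b", "a", "b"),
                    state = c("123432", "123432", "645655", "645655"),
                    y = c(0.5, 0.6, 0.2, 0.3))
  expect_error(fit_crude(df3, mean_basis = "linear"), "intercept")
})

test_that("Monte-Carlo error of reported population means is small at default settings", {
  sc <- tiny_scenario(seed = 8, n_states = 10L, n_resp = 25L, quota = 5L)
  truth <- quiet(sample_true_utilities(sc))
  vals <- generate_valuations(truth)
  fit <- quiet(fit_crude(vals$donor, config = mcmc_config(seed = 8)))
  ub <- 1 - fit$draws$alpha_bar * (1 - fit$draws$u)
  mcse <- apply(ub, 2, sf6dvalue:::.mcse_batch)
  expect_lt(max(mcse), 0.005)
})
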