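#' MCMC settings for the valuation models
#'
#' @param n_iterations total Gibbs sweeps.
#' @param n_burnin sweeps discarded before retention (must be smaller than
#'   \code{n_iterations}).
#' @param thin keep every \code{thin}-th post-burn-in sweep.
#' @param seed RNG seed; identical seed, data and config give identical
#'   draws.
#' @param proposal_sd_log_alpha,proposal_sd_log_sigma random-walk proposal
#'   standard deviations on the log respondent multipliers and on
#'   \eqn{\log\sigma^2}. During burn-in they are adapted towards a 20-50\%
#'   acceptance rate and then frozen.
#' @param jitter diagonal stabiliser for Gaussian-process covariance
#'   matrices.
#' @param prior_gamma0_sd standard deviation of the normal prior on the
#'   respondent-multiplier location \eqn{\gamma_0} (prior mean 0). The
#'   flat-prior limit leaves the posterior improper along the ridge where
#'   all multipliers shrink while all disutilities grow, so a proper
#'   location prior is required; the default 0.1 keeps the population
#'   median multiplier within about 20\% of 1, reflecting that adjusted
#'   standard-gamble data are already on the anchored utility scale.
#' @param adapt logical; adapt the proposal scales during burn-in.
#' @param fix optional named list pinning parameters for diagnostic runs:
#'   any of \code{alpha} (vector or single value recycled over
#'   respondents), \code{gamma0}, \code{tau_sq}, \code{v_sq},
#'   \code{sigma_sq}, \code{theta}. Pinned parameters are excluded from
#'   sampling.
#' @return An \code{"mcmc_config"} list.
#' @export
mcmc_config <- function(n_iterations = 10000L, n_burnin = 2000L, thin = 5L,
                        seed = 0L, proposal_sd_log_alpha = 0.1,
                        proposal_sd_log_sigma = 0.1, jitter = 1e-8,
                        prior_gamma0_sd = 0.1, adapt = TRUE, fix = list()) {
  if (n_burnin >= n_iterations) stop("'n_burnin' must be < 'n_iterations'")
  if (thin < 1L) stop("'thin' must be a positive integer")
  if (proposal_sd_log_alpha <= 0 || proposal_sd_log_sigma <= 0)
    stop("proposal standard deviations must be positive")
  if (jitter <= 0) stop("'jitter' must be positive")
  if (prior_gamma0_sd <= 0) stop("'prior_gamma0_sd' must be positive")
  structure(list(n_iterations = as.integer(n_iterations),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed),
                 proposal_sd_log_alpha = proposal_sd_log_alpha,
                 proposal_sd_log_sigma = proposal_sd_log_sigma,
                 jitter = jitter, prior_gamma0_sd = prior_gamma0_sd,
                 adapt = isTRUE(adapt), fix = fix),
            class = "mcmc_config")
}

# Conditioned GP prior pieces at a given sigma^2.
#
# The latent utility over the modelled states S plus the full-health
# anchor x0 is jointly normal with mean (a + B theta, a0 + b0' theta) and
# covariance blocks K = D + s2*C, k0 = d0 + s2*c0, k00 = d00 + s2 (D terms
# come from donor posteriors and vanish for the crude model). Conditioning
# on u(x0) = 1 gives a prior over S that stays linear in theta:
#   mean = Bt %*% theta + astar,  Bt = B - r b0',  astar = a + r (1 - a0),
#   cov  = K - k0 k0' / k00,      r = k0 / k00.
.gp_cov_cache <- function(pr, sigma_sq) {
  k0 <- pr$d0 + sigma_sq * pr$c0
  k00 <- pr$d00 + sigma_sq
  r <- k0 / k00
  Cc <- pr$D + sigma_sq * pr$C - tcrossprod(k0) / k00
  diag(Cc) <- diag(Cc) + pr$jitter
  ch <- tryCatch(chol(Cc), error = function(e) NULL)
  if (is.null(ch)) {
    diag(Cc) <- diag(Cc) + 1e4 * pr$jitter
    ch <- tryCatch(chol(Cc), error = function(e)
      stop("GP prior covariance is not positive definite even after ",
           "inflating the jitter; check for duplicate states or a ",
           "degenerate donor posterior"))
  }
  list(sigma_sq = sigma_sq, r = r,
       Bt = pr$B - tcrossprod(r, pr$b0),
       astar = pr$a + r * (1 - pr$a0),
       chol = ch, Ci = chol2inv(ch),
       logdet = 2 * sum(log(diag(ch))))
}

.gp_log_mvn <- function(u, mean, cache) {
  e <- u - mean
  q <- forwardsolve(t(cache$chol), e)
  -0.5 * cache$logdet - 0.5 * sum(q * q)
}

# Metropolis-within-Gibbs sampler for y_ij = 1 - alpha_j (1 - u(x_ij)) + eps.
#
# y        : adjusted values in [-1, 1]
# resp_idx : 1..J respondent index per observation
# state_idx: 1..S modelled-state index per observation
# pr       : prior pieces (B, b0, a, a0, D, d0, d00, C, c0, jitter)
# cfg      : mcmc_config
.run_gp_sampler <- function(y, resp_idx, state_idx, pr, cfg) {
  S <- nrow(pr$C); J <- max(resp_idx); n <- length(y); p <- ncol(pr$B)
  fix <- cfg$fix
  g0_sd <- cfg$prior_gamma0_sd %||% 0.1
  set.seed(cfg$seed)

  # initial values
  ybar <- as.numeric(tapply(y, state_idx, mean))
  u <- pmin(pmax(ybar, -1), 0.995)
  lam <- rep(0, J)                       # log respondent multipliers
  if (!is.null(fix$alpha)) lam <- log(rep(fix$alpha, length.out = J))
  alpha <- exp(lam)
  gamma0 <- fix$gamma0 %||% 0
  tau_sq <- fix$tau_sq %||% 0.04
  v_sq <- fix$v_sq %||% max(1e-4, stats::var(y - ybar[state_idx]))
  sigma_sq <- fix$sigma_sq %||% 0.04
  cache <- .gp_cov_cache(pr, sigma_sq)

  gls_theta <- function(cache, u, draw = TRUE) {
    W <- cache$Ci %*% cache$Bt
    V <- crossprod(cache$Bt, W)
    chV <- tryCatch(chol(V), error = function(e)
      stop("GP mean design is rank deficient for these states; use ",
           "mean_basis = \"intercept\" or value more states"))
    m <- chol2inv(chV) %*% crossprod(W, u - cache$astar)
    if (!draw) return(drop(m))
    drop(m + backsolve(chV, stats::rnorm(p)))
  }
  theta <- if (!is.null(fix$theta)) fix$theta else gls_theta(cache, u, draw = FALSE)

  keep <- seq.int(cfg$n_burnin + 1L, cfg$n_iterations, by = cfg$thin)
  n_keep <- length(keep)
  out <- list(u = matrix(NA_real_, n_keep, S),
              alpha = matrix(NA_real_, n_keep, J),
              theta = matrix(NA_real_, n_keep, p),
              gamma0 = numeric(n_keep), tau_sq = numeric(n_keep),
              v_sq = numeric(n_keep), sigma_sq = numeric(n_keep),
              alpha_bar = numeric(n_keep))
  s_a <- cfg$proposal_sd_log_alpha
  s_s <- cfg$proposal_sd_log_sigma
  s_k <- 0.05
  acc_a <- 0; acc_s <- 0; acc_k <- 0
  win_a <- 0; win_s <- 0; win_k <- 0; win_n <- 0
  d_obs <- 1 - y
  kslot <- 1L

  for (it in seq_len(cfg$n_iterations)) {
    ## (a) u | rest -- block multivariate-normal full conditional
    a_o <- alpha[resp_idx]
    w <- as.numeric(rowsum(a_o^2, state_idx, reorder = TRUE)) / v_sq
    h <- as.numeric(rowsum(a_o * (y - 1 + a_o), state_idx, reorder = TRUE)) / v_sq
    mu_pr <- drop(cache$Bt %*% theta) + cache$astar
    P <- cache$Ci
    diag(P) <- diag(P) + w
    chP <- chol(P)
    m <- backsolve(chP, forwardsolve(t(chP), drop(cache$Ci %*% mu_pr) + h))
    u <- m + backsolve(chP, stats::rnorm(S))

    ## (a') joint rescaling move along the alpha / (1 - u) ridge:
    ## alpha -> k alpha, (1 - u) -> (1 - u)/k, gamma0 -> gamma0 + log k
    ## leaves the likelihood and the multiplier prior invariant, so the
    ## Hastings ratio is the GP prior ratio times the Jacobian k^{-S};
    ## without it the scale direction mixes very slowly.
    if (is.null(fix$alpha) && is.null(fix$gamma0)) {
      lk <- stats::rnorm(1, 0, s_k)
      u_p <- 1 - (1 - u) / exp(lk)
      mu_pr <- drop(cache$Bt %*% theta) + cache$astar
      lr <- .gp_log_mvn(u_p, mu_pr, cache) - .gp_log_mvn(u, mu_pr, cache) -
        S * lk +
        stats::dnorm(gamma0 + lk, 0, g0_sd, log = TRUE) -
        stats::dnorm(gamma0, 0, g0_sd, log = TRUE)
      if (log(stats::runif(1)) < lr) {
        u <- u_p
        lam <- lam + lk
        alpha <- exp(lam)
        gamma0 <- gamma0 + lk
        win_k <- win_k + 1
        if (it > cfg$n_burnin) acc_k <- acc_k + 1
      }
    }

    z <- 1 - u
    z_o <- z[state_idx]

    ## (b) log alpha_j -- random-walk Metropolis, all respondents at once
    if (is.null(fix$alpha)) {
      Szz <- as.numeric(rowsum(z_o^2, resp_idx, reorder = TRUE))
      Sdz <- as.numeric(rowsum(d_obs * z_o, resp_idx, reorder = TRUE))
      lam_p <- lam + stats::rnorm(J, 0, s_a)
      al_p <- exp(lam_p)
      lp <- function(a, l) (2 * a * Sdz - a^2 * Szz) / (2 * v_sq) -
        (l - gamma0)^2 / (2 * tau_sq)
      acc <- log(stats::runif(J)) < lp(al_p, lam_p) - lp(alpha, lam)
      lam[acc] <- lam_p[acc]
      alpha <- exp(lam)
      win_a <- win_a + mean(acc)
      if (it > cfg$n_burnin) acc_a <- acc_a + mean(acc)
    }

    ## (c) respondent-effect location and variances (conjugate;
    ##     gamma0 carries a proper N(0, g0_sd^2) prior)
    if (is.null(fix$gamma0)) {
      prec <- J / tau_sq + 1 / g0_sd^2
      gamma0 <- stats::rnorm(1, (sum(lam) / tau_sq) / prec, sqrt(1 / prec))
    }
    if (is.null(fix$tau_sq))
      tau_sq <- 1 / stats::rgamma(1, J / 2, sum((lam - gamma0)^2) / 2)
    if (is.null(fix$v_sq)) {
      sse <- sum((d_obs - alpha[resp_idx] * z_o)^2)
      v_sq <- 1 / stats::rgamma(1, n / 2, sse / 2)
    }

    ## (d) GP mean coefficients -- normal full conditional (flat prior)
    if (is.null(fix$theta)) theta <- gls_theta(cache, u)

    ## (e) log sigma^2 -- random-walk Metropolis
    if (is.null(fix$sigma_sq)) {
      ls_p <- log(sigma_sq) + stats::rnorm(1, 0, s_s)
      cache_p <- .gp_cov_cache(pr, exp(ls_p))
      lt_cur <- .gp_log_mvn(u, drop(cache$Bt %*% theta) + cache$astar, cache) +
        0.5 * log(sigma_sq)
      lt_p <- .gp_log_mvn(u, drop(cache_p$Bt %*% theta) + cache_p$astar,
                          cache_p) + 0.5 * ls_p
      if (log(stats::runif(1)) < lt_p - lt_cur) {
        sigma_sq <- exp(ls_p)
        cache <- cache_p
        win_s <- win_s + 1
        if (it > cfg$n_burnin) acc_s <- acc_s + 1
      }
    }

    ## adapt proposal scales during burn-in (frozen afterwards)
    win_n <- win_n + 1
    if (cfg$adapt && it <= cfg$n_burnin && win_n == 50L) {
      s_a <- min(2, max(0.005, s_a * exp((win_a / win_n - 0.3))))
      s_s <- min(2, max(0.005, s_s * exp((win_s / win_n - 0.3))))
      s_k <- min(2, max(0.005, s_k * exp((win_k / win_n - 0.3))))
      win_a <- 0; win_s <- 0; win_k <- 0; win_n <- 0
    }

    if (kslot <= n_keep && it == keep[kslot]) {
      out$u[kslot, ] <- u
      out$alpha[kslot, ] <- alpha
      out$theta[kslot, ] <- theta
      out$gamma0[kslot] <- gamma0
      out$tau_sq[kslot] <- tau_sq
      out$v_sq[kslot] <- v_sq
      out$sigma_sq[kslot] <- sigma_sq
      out$alpha_bar[kslot] <- exp(gamma0 + tau_sq / 2)
      kslot <- kslot + 1L
    }
  }
  n_post <- cfg$n_iterations - cfg$n_burnin
  out$acceptance <- c(alpha = if (is.null(fix$alpha)) acc_a / n_post else NA,
                      sigma = if (is.null(fix$sigma_sq)) acc_s / n_post else NA,
                      rescale = if (is.null(fix$alpha) && is.null(fix$gamma0))
                        acc_k / n_post else NA)
  out$proposal_sd <- c(log_alpha = s_a, log_sigma = s_s, log_rescale = s_k)
  out
}

# Batch-means Monte-Carlo standard error of a chain mean.
.mcse_batch <- function(x, n_batches = 20L) {
  n <- length(x)
  b <- n %/% n_batches
  if (b < 2L) return(stats::sd(x) / sqrt(n))
  means <- colMeans(matrix(x[seq_len(b * n_batches)], nrow = b))
  stats::sd(means) / sqrt(n_batches)
}
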