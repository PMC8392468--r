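#' Fit the single-country ("crude") nonparametric Bayesian valuation model
#'
#' Models adjusted standard-gamble values as
#' \deqn{y_{ij} = 1 - \alpha_j \{1 - u(x_{ij})\} + \epsilon_{ij},}
#' where \eqn{u(x)} is the latent utility of state \eqn{x},
#' \eqn{\alpha_j \sim LN(\gamma_0, \tau^2)} is a respondent-specific
#' multiplier and \eqn{\epsilon_{ij} \sim N(0, v^2)}. The utility function
#' gets a Gaussian-process prior with linear mean
#' \eqn{\gamma + \beta^T (x - 1)} in the centred dimension levels and
#' covariance \eqn{\sigma^2 c(x, x')} (squared-exponential kernel,
#' \code{\link{kernel_correlation}}), conditioned on the anchor
#' \eqn{u(\mathrm{full\ health}) = 1}. Variance parameters carry the
#' standard noninformative priors
#' \eqn{p(\gamma, \tau^2, v^2, \sigma^2) \propto \tau^{-2} v^{-2} \sigma^{-1}}.
#'
#' Sampling is Metropolis-within-Gibbs: the utility vector is drawn as a
#' block from its multivariate-normal full conditional; each
#' \eqn{\log \alpha_j} and \eqn{\log \sigma^2} by random-walk Metropolis;
#' \eqn{v^2}, \eqn{\tau^2} from inverse-gamma full conditionals; and the
#' GP mean coefficients from their normal full conditional.
#'
#' @param data data frame with columns \code{respondent_id}, \code{state}
#'   (six-digit codes; full health must not appear, it is anchored) and
#'   \code{y} (adjusted values in \code{[-1, 1]}).
#' @param system a \code{\link{sf6d_system}} object.
#' @param roughness kernel roughness parameters (fixed, not sampled).
#' @param mean_basis \code{"linear"} (intercept + one slope per dimension,
#'   needs at least 8 distinct states) or \code{"intercept"}.
#' @param config an \code{\link{mcmc_config}}.
#' @return A \code{"valuation_fit"} object holding the retained draws
#'   (\code{$draws}: matrices \code{u}, \code{alpha}, \code{theta} and
#'   vectors \code{gamma0}, \code{tau_sq}, \code{v_sq}, \code{sigma_sq},
#'   \code{alpha_bar}), the modelled states and the sampler settings.
#' @seealso \code{\link{population_mean_utility}},
#'   \code{\link{predict_states}}, \code{\link{export_posterior}},
#'   \code{\link{fit_transfer}}
#' @export
fit_crude <- function(data, system = sf6d_system(),
                      roughness = default_roughness(system),
                      mean_basis = c("linear", "intercept"),
                      config = mcmc_config()) {
  mean_basis <- match.arg(mean_basis)
  prep <- .prepare_fit_data(data, system)
  pr <- .base_prior_pieces(prep$levels, mean_basis, roughness, config$jitter,
                          system)
  if (mean_basis == "linear" && length(prep$states) < ncol(pr$B) &&
      is.null(config$fix$theta))
    stop("only ", length(prep$states), " distinct states: too few for the ",
         "linear GP mean; use mean_basis = \"intercept\"")
  draws <- .run_gp_sampler(prep$y, prep$resp_idx, prep$state_idx, pr, config)
  structure(list(draws = draws, states = prep$states, levels = prep$levels,
                 system = system, roughness = roughness,
                 mean_basis = mean_basis, config = config, model = "crude",
                 donors = NULL, donor_weights = NULL,
                 n_respondents = prep$n_respondents, n_obs = length(prep$y)),
            class = "valuation_fit")
}

.prepare_fit_data <- function(data, system) {
  need <- c("respondent_id", "state", "y")
  if (!all(need %in% names(data)))
    stop("data needs columns: ", paste(need, collapse = ", "))
  if (any(is.na(data$y)) || any(!is.finite(data$y)))
    stop("'y' must be finite with no missing values")
  if (any(data$y < -1) || any(data$y > 1))
    warning("adjusted values outside [-1, 1]; real standard-gamble data ",
            "cannot produce these")
  states <- sort(unique(as.character(data$state)))
  if (full_health_code(system) %in% states)
    stop("full health is anchored at u = 1 and must not be a valued state")
  if (length(states) < 2L) stop("need at least 2 distinct states")
  resp <- factor(data$respondent_id)
  if (nlevels(resp) < 2L) stop("need at least 2 respondents")
  list(y = as.numeric(data$y),
       resp_idx = as.integer(resp),
       state_idx = match(as.character(data$state), states),
       states = states,
       levels = state_levels(states, system),
       n_respondents = nlevels(resp))
}

# Kernel-and-mean prior pieces common to both models; donor terms zero.
.base_prior_pieces <- function(levels, mean_basis, roughness, jitter, system) {
  S <- nrow(levels)
  Xc <- sweep(levels, 2L, rep(1, 6L))
  if (mean_basis == "linear") {
    B <- cbind(1, Xc)
    b0 <- c(1, rep(0, 6L))
  } else {
    B <- matrix(1, S, 1L)
    b0 <- 1
  }
  list(B = B, b0 = b0, a = rep(0, S), a0 = 0,
       D = matrix(0, S, S), d0 = rep(0, S), d00 = 0,
       C = kernel_matrix(levels, roughness, jitter = 0, system = system),
       c0 = exp(-as.numeric(Xc^2 %*% roughness)),
       jitter = jitter)
}

#' @export
print.valuation_fit <- function(x, ...) {
  cat(sprintf("Nonparametric Bayesian valuation fit (%s model)\n", x$model))
  cat(sprintf("  %d states, %d respondents, %d observations\n",
              length(x$states), x$n_respondents, x$n_obs))
  cat(sprintf("  %d retained draws (of %d iterations, burn-in %d, thin %d)\n",
              nrow(x$draws$u), x$config$n_iterations, x$config$n_burnin,
              x$config$thin))
  acc <- x$draws$acceptance
  cat(sprintf("  acceptance: log-alpha %.2f, log-sigma %.2f\n",
              acc["alpha"], acc["sigma"]))
  invisible(x)
}

#' @export
summary.valuation_fit <- function(object, probs = c(0.025, 0.975), ...) {
  d <- object$draws
  pars <- cbind(gamma0 = d$gamma0, tau_sq = d$tau_sq, v_sq = d$v_sq,
                sigma_sq = d$sigma_sq, alpha_bar = d$alpha_bar, d$theta)
  colnames(pars)[6:ncol(pars)] <-
    if (object$mean_basis == "linear")
      c("mean_intercept", paste0("mean_slope_", 1:6)) else "mean_intercept"
  q <- t(apply(pars, 2L, stats::quantile, probs = probs))
  data.frame(parameter = colnames(pars), mean = colMeans(pars),
             sd = apply(pars, 2L, stats::sd), q, check.names = FALSE,
             row.names = NULL)
}

#' Posterior population mean utilities
#'
#' The population mean utility of a state is
#' \eqn{\bar u(x) = 1 - \bar\alpha \{1 - u(x)\}}, where
#' \eqn{\bar\alpha = \exp(\gamma_0 + \tau^2/2)} is the population mean of
#' the log-normal respondent multipliers. Both factors are evaluated per
#' retained draw, so the reported standard deviation carries the joint
#' posterior uncertainty. States never valued are first predicted by GP
#' conditioning (\code{\link{predict_states}}).
#'
#' @param fit a \code{\link{fit_crude}} / \code{\link{fit_transfer}} result.
#' @param states character vector of six-digit codes.
#' @param seed RNG seed for GP prediction at unvalued states.
#' @return Data frame with columns \code{state}, \code{mean}, \code{sd}
#'   (shape of a value-set summary table).
#' @export
population_mean_utility <- function(fit, states, seed = 1L) {
  U <- .posterior_u_draws(fit, states, method = "sample", seed = seed)
  ub <- 1 - fit$draws$alpha_bar * (1 - U)
  full <- states == full_health_code(fit$system)
  m <- colMeans(ub); s <- apply(ub, 2L, stats::sd)
  m[full] <- 1; s[full] <- 0
  data.frame(state = states, mean = m, sd = s, row.names = NULL)
}

#' Predict utilities at new states by Gaussian-process conditioning
#'
#' For every retained draw, the utilities at the requested states are
#' completed from the joint normal prior given that draw's utilities at
#' the modelled states, the full-health anchor, the GP mean coefficients
#' and \eqn{\sigma^2}. By default a draw from the conditional distribution
#' is taken, so reported standard deviations include the GP interpolation
#' uncertainty; \code{method = "mean"} propagates the conditional mean
#' only.
#'
#' @param fit a fitted valuation model.
#' @param new_states character vector of codes (modelled states reproduce
#'   their retained draws exactly; full health is the constant 1).
#' @param method \code{"sample"} (default) or \code{"mean"}.
#' @param seed RNG seed used for \code{method = "sample"}.
#' @return A \code{\link{country_posterior}} over \code{new_states} (the
#'   latent \eqn{u}, not the population mean \eqn{\bar u}).
#' @export
predict_states <- function(fit, new_states, method = c("sample", "mean"),
                           seed = 1L) {
  method <- match.arg(method)
  U <- .posterior_u_draws(fit, new_states, method = method, seed = seed)
  country_posterior(new_states, colMeans(U), stats::cov(U))
}

#' Export a fitted posterior as a donor prior bundle
#'
#' Collects the posterior mean vector and covariance matrix of the latent
#' utilities \eqn{u} (not \eqn{\bar u}) over a set of states, in the form
#' consumed by \code{\link{fit_transfer}} as an informative prior. The
#' full-health anchor is always included with mean 1 and variance 0.
#'
#' @param fit a fitted valuation model.
#' @param states codes to cover; default: full health plus every modelled
#'   state. States outside the modelled set are filled in by GP
#'   conditioning.
#' @param seed RNG seed for GP prediction at unmodelled states.
#' @return A \code{\link{country_posterior}}.
#' @export
export_posterior <- function(fit, states = NULL, seed = 1L) {
  if (is.null(states)) states <- c(full_health_code(fit$system), fit$states)
  predict_states(fit, states, method = "sample", seed = seed)
}

#' Posterior summary of a country's utilities, usable as a donor prior
#'
#' @param states character vector of six-digit codes.
#' @param mean posterior mean utilities.
#' @param cov posterior covariance matrix (symmetric positive
#'   semidefinite).
#' @return A \code{"country_posterior"} list with \code{states},
#'   \code{mean}, \code{cov} and \code{sd = sqrt(diag(cov))}.
#' @export
country_posterior <- function(states, mean, cov) {
  states <- as.character(states)
  S <- length(states)
  if (anyDuplicated(states)) stop("duplicate states in posterior bundle")
  if (length(mean) != S) stop("'mean' length must match 'states'")
  cov <- as.matrix(cov)
  dimnames(cov) <- NULL
  if (!all(dim(cov) == S)) stop("'cov' must be ", S, " x ", S)
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    stop("'cov' must be symmetric")
  v <- diag(cov)
  if (any(v < -1e-12)) stop("'cov' has negative variances")
  structure(list(states = states, mean = unname(as.numeric(mean)),
                 cov = cov, sd = sqrt(pmax(v, 0))),
            class = "country_posterior")
}

#' @export
print.country_posterior <- function(x, ...) {
  cat(sprintf("Country posterior over %d states (mean utility %.3f-%.3f)\n",
              length(x$states), min(x$mean), max(x$mean)))
  invisible(x)
}

# Draw matrix (retained draws x states) of latent utilities at arbitrary
# states: modelled states are copied, full health is 1, others are
# completed by per-draw GP conditioning on (modelled states, anchor).
.posterior_u_draws <- function(fit, states, method = "sample", seed = 1L) {
  states <- as.character(states)
  d <- fit$draws
  n_keep <- nrow(d$u)
  U <- matrix(NA_real_, n_keep, length(states))
  colnames(U) <- states
  fh <- full_health_code(fit$system)
  idx <- match(states, fit$states)
  U[, !is.na(idx)] <- d$u[, idx[!is.na(idx)], drop = FALSE]
  U[, states == fh] <- 1
  new <- states[is.na(idx) & states != fh]
  if (!length(new)) return(U)
  if (anyDuplicated(new)) stop("duplicate states requested")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }

  # joint set: modelled states + anchor (observed) then new states
  S_obs <- length(fit$states)
  lev_all <- rbind(fit$levels, rep(1L, 6L), state_levels(new, fit$system))
  obs_i <- seq_len(S_obs + 1L)
  new_i <- S_obs + 1L + seq_along(new)
  C_all <- kernel_matrix(lev_all, fit$roughness, jitter = 0,
                         system = fit$system)
  Xc <- sweep(lev_all, 2L, rep(1, 6L))
  B_all <- if (fit$mean_basis == "linear") cbind(1, Xc) else
    matrix(1, nrow(lev_all), 1L)
  a_all <- rep(0, nrow(lev_all))
  D_all <- matrix(0, nrow(lev_all), nrow(lev_all))
  if (!is.null(fit$donors)) {
    codes_all <- c(fit$states, fh, new)
    agg <- .aggregate_donors(fit$donors, codes_all, fit$donor_weights)
    a_all <- agg$mean
    D_all <- agg$cov
  }
  jit <- fit$config$jitter

  if (is.null(fit$donors)) {
    # sigma^2 scales the whole covariance, so the conditioning weights
    # A = C_no C_oo^{-1} are draw-independent
    Coo <- C_all[obs_i, obs_i]
    diag(Coo) <- diag(Coo) + jit
    A <- C_all[new_i, obs_i, drop = FALSE] %*% chol2inv(chol(Coo))
    Schur <- C_all[new_i, new_i, drop = FALSE] -
      A %*% t(C_all[new_i, obs_i, drop = FALSE])
    Schur <- (Schur + t(Schur)) / 2
    diag(Schur) <- diag(Schur) + jit
    chS <- chol(Schur)
    for (t in seq_len(n_keep)) {
      th <- d$theta[t, ]
      m_all <- drop(B_all %*% th)
      u_obs <- c(d$u[t, ], 1)
      cm <- m_all[new_i] + drop(A %*% (u_obs - m_all[obs_i]))
      U[t, new] <- if (method == "mean") cm else
        cm + sqrt(d$sigma_sq[t]) * drop(t(chS) %*% stats::rnorm(length(new)))
    }
  } else {
    for (t in seq_len(n_keep)) {
      th <- d$theta[t, ]
      s2 <- d$sigma_sq[t]
      K <- D_all + s2 * C_all
      m_all <- a_all + drop(B_all %*% th)
      Koo <- K[obs_i, obs_i]
      diag(Koo) <- diag(Koo) + jit
      A <- K[new_i, obs_i, drop = FALSE] %*% chol2inv(chol(Koo))
      u_obs <- c(d$u[t, ], 1)
      cm <- m_all[new_i] + drop(A %*% (u_obs - m_all[obs_i]))
      if (method == "mean") {
        U[t, new] <- cm
      } else {
        Schur <- K[new_i, new_i, drop = FALSE] -
          A %*% t(K[new_i, obs_i, drop = FALSE])
        Schur <- (Schur + t(Schur)) / 2
        diag(Schur) <- diag(Schur) + jit
        U[t, new] <- cm + drop(t(chol(Schur)) %*% stats::rnorm(length(new)))
      }
    }
  }
  U
}
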