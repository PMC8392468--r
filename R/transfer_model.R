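# Sum donor posterior means / covariances over a set of states, in the
# order requested. Every donor must cover every state.
.aggregate_donors <- function(donors, states, weights = NULL) {
  if (inherits(donors, "country_posterior")) donors <- list(donors)
  if (!length(donors)) stop("need at least one donor posterior")
  if (is.null(weights)) weights <- rep(1, length(donors))
  if (length(weights) != length(donors) || any(weights < 0))
    stop("'weights' must be one non-negative value per donor")
  S <- length(states)
  m <- rep(0, S)
  V <- matrix(0, S, S)
  for (k in seq_along(donors)) {
    dk <- donors[[k]]
    if (!inherits(dk, "country_posterior"))
      stop("donors must be country_posterior objects")
    idx <- match(states, dk$states)
    if (anyNA(idx))
      stop("donor ", k, " does not cover state(s) ",
           paste(states[is.na(idx)], collapse = ", "),
           "; export its posterior at those states first ",
           "(export_posterior / predict_states)")
    m <- m + weights[k] * dk$mean[idx]
    V <- V + weights[k] * dk$cov[idx, idx, drop = FALSE]
  }
  list(mean = m, cov = V)
}

#' Assemble the informative cross-country prior
#'
#' The transfer model gives the target country's utility function a
#' Gaussian-process prior whose mean is the summed donor posterior means
#' plus a country offset,
#' \eqn{E\{u(x)\} = \sum_k E\{u_k(x)\} + \gamma + \beta^T x,}
#' and whose covariance adds a fresh GP layer to the summed donor
#' posterior covariances,
#' \eqn{\sum_k \mathrm{cov}\{u_k(x), u_k(x')\} + \sigma^2 c(x, x').}
#' With a single donor this is the two-country informative prior; the
#' offsets let the target population disagree systematically with the
#' donors, dimension by dimension.
#'
#' @param donors a \code{\link{country_posterior}} or list of them; each
#'   must cover every target state.
#' @param target_states character vector of codes.
#' @param system a \code{\link{sf6d_system}} object.
#' @param roughness kernel roughness parameters.
#' @param offset_intercept,offset_slopes the offset \eqn{\gamma} and
#'   \eqn{\beta} (slopes apply to centred levels \eqn{x_d - 1}); both
#'   default to zero. In \code{\link{fit_transfer}} these are sampled, not
#'   fixed.
#' @param sigma_sq fresh GP variance \eqn{\sigma^2}.
#' @param weights optional per-donor weights (default all 1; non-default
#'   weighting is experimental).
#' @return A \code{"transfer_prior"} list with the evaluated prior
#'   \code{mean} and \code{cov} over \code{target_states} and the donor
#'   aggregates (\code{donor_mean}, \code{donor_cov}).
#' @export
build_transfer_prior <- function(donors, target_states,
                                 system = sf6d_system(),
                                 roughness = default_roughness(system),
                                 offset_intercept = 0,
                                 offset_slopes = rep(0, 6L),
                                 sigma_sq = 0.04, weights = NULL) {
  if (sigma_sq < 0) stop("'sigma_sq' must be non-negative")
  agg <- .aggregate_donors(donors, target_states, weights)
  L <- state_levels(target_states, system)
  Xc <- sweep(L, 2L, rep(1, 6L))
  mean <- unname(agg$mean + offset_intercept + drop(Xc %*% offset_slopes))
  cov <- unname(agg$cov + sigma_sq * kernel_matrix(L, roughness, jitter = 0,
                                                   system = system))
  structure(list(states = as.character(target_states), mean = mean,
                 cov = cov, donor_mean = agg$mean, donor_cov = agg$cov,
                 offset_intercept = offset_intercept,
                 offset_slopes = offset_slopes, sigma_sq = sigma_sq,
                 roughness = roughness),
            class = "transfer_prior")
}

#' Fit the transfer model: target-country data with donor priors
#'
#' Identical sampler to \code{\link{fit_crude}}, except that the GP prior
#' on the target utility function embeds the donor posterior(s) via
#' \code{\link{build_transfer_prior}}: the sampled GP mean coefficients
#' become the cross-country offsets \eqn{(\gamma, \beta)} around the
#' summed donor means, and the sampled \eqn{\sigma^2} scales only the
#' fresh kernel layer added on top of the fixed donor covariance
#' (two-stage plug-in: donor bundles are never re-estimated). The anchor
#' \eqn{u(\mathrm{full\ health}) = 1} is imposed by conditioning, so each
#' donor bundle must cover full health as well as every valued state
#' (\code{\link{export_posterior}} includes it automatically).
#'
#' @inheritParams fit_crude
#' @param donors a \code{\link{country_posterior}} or list of them.
#' @param weights optional per-donor weights (default all 1).
#' @return A \code{"valuation_fit"} with \code{model = "transfer"}; the
#'   \code{theta} draws are the offsets \eqn{(\gamma, \beta)}.
#' @export
fit_transfer <- function(data, donors, system = sf6d_system(),
                         roughness = default_roughness(system),
                         mean_basis = c("linear", "intercept"),
                         config = mcmc_config(), weights = NULL) {
  mean_basis <- match.arg(mean_basis)
  if (inherits(donors, "country_posterior")) donors <- list(donors)
  prep <- .prepare_fit_data(data, system)
  pr <- .base_prior_pieces(prep$levels, mean_basis, roughness, config$jitter,
                          system)
  if (mean_basis == "linear" && length(prep$states) < ncol(pr$B) &&
      is.null(config$fix$theta))
    stop("only ", length(prep$states), " distinct states: too few for the ",
         "linear offset basis; use mean_basis = \"intercept\"")
  fh <- full_health_code(system)
  agg <- .aggregate_donors(donors, c(prep$states, fh), weights)
  S <- length(prep$states)
  pr$a <- agg$mean[seq_len(S)]
  pr$a0 <- agg$mean[S + 1L]
  pr$D <- agg$cov[seq_len(S), seq_len(S), drop = FALSE]
  pr$d0 <- agg$cov[seq_len(S), S + 1L]
  pr$d00 <- agg$cov[S + 1L, S + 1L]
  draws <- .run_gp_sampler(prep$y, prep$resp_idx, prep$state_idx, pr, config)
  structure(list(draws = draws, states = prep$states, levels = prep$levels,
                 system = system, roughness = roughness,
                 mean_basis = mean_basis, config = config,
                 model = "transfer", donors = donors,
                 donor_weights = weights,
                 n_respondents = prep$n_respondents, n_obs = length(prep$y)),
            class = "valuation_fit")
}
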