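#' Default generative parameters for synthetic valuation studies
#'
#' Ground-truth values used by \code{\link{simulation_scenario}}: a linear
#' utility surface anchored at 1 for full health whose per-level
#' decrements take the pits state to about 0.33, so simulated observed
#' means span roughly 0.32-0.95; a GP fluctuation layer
#' (\eqn{\sigma^2 = 0.01}) around that surface; log-normal respondent
#' multipliers with \eqn{\gamma_0 = 0}, \eqn{\tau^2 = 0.04}; observation
#' noise \eqn{v^2 = 0.01}; and modest cross-country offsets.
#'
#' @return Named list of truth parameters (override any element via the
#'   \code{truth} argument of \code{\link{simulation_scenario}}).
#' @export
default_truth <- function() {
  list(gp_intercept = 1,
       gp_slopes = -c(0.030, 0.020, 0.020, 0.035, 0.025, 0.025),
       sigma_sq = 0.01,
       gamma0 = 0, tau_sq = 0.04, v_sq = 0.01,
       transfer_gamma = -0.05,
       transfer_beta = c(0.010, -0.005, 0.005, -0.010, 0.005, -0.005),
       transfer_sigma_sq = 0.01)
}

#' Define a synthetic two-country valuation scenario
#'
#' Describes a donor and a target valuation study with exactly the
#' statistical structure the models assume: true utilities drawn from the
#' anchored GP, log-normal respondent multipliers, additive normal noise,
#' balanced round-robin state allocation, and completely-at-random
#' missingness.
#'
#' @param donor_states,target_states character vectors of codes (full
#'   health must not appear).
#' @param n_donor_respondents,n_target_respondents respondents per country.
#' @param donor_quota,target_quota values elicited per respondent.
#' @param truth named list overriding \code{\link{default_truth}} entries.
#' @param missing_rate_donor,missing_rate_target per-value missingness
#'   probabilities in \code{[0, 1)}.
#' @param seed integer seed governing truth and data generation.
#' @param clip clip generated values to \code{[-1, 1]} (the elicitation
#'   instrument cannot produce values outside it); disable only for exact
#'   conjugacy checks.
#' @param system a \code{\link{sf6d_system}} object.
#' @return A \code{"simulation_scenario"} list.
#' @seealso \code{\link{canonical_scenario}} for the canonical
#'   249-state / 49-state two-study layout.
#' @export
simulation_scenario <- function(donor_states, target_states,
                                n_donor_respondents, n_target_respondents,
                                donor_quota, target_quota,
                                truth = list(),
                                missing_rate_donor = 0,
                                missing_rate_target = 0,
                                seed = 1L, clip = TRUE,
                                system = sf6d_system()) {
  tr <- utils::modifyList(default_truth(), truth)
  if (tr$sigma_sq < 0 || tr$tau_sq < 0 || tr$v_sq < 0 ||
      tr$transfer_sigma_sq < 0)
    stop("truth variances must be non-negative")
  if (missing_rate_donor < 0 || missing_rate_donor >= 1 ||
      missing_rate_target < 0 || missing_rate_target >= 1)
    stop("missing rates must lie in [0, 1)")
  fh <- full_health_code(system)
  for (st in list(donor_states, target_states)) {
    if (fh %in% st) stop("full health is anchored, not valued")
    invisible(lapply(unique(st), parse_state_code, system = system))
  }
  if (donor_quota > length(donor_states) ||
      target_quota > length(target_states))
    stop("quota cannot exceed the number of states in the design")
  structure(list(system = system,
                 donor_states = as.character(donor_states),
                 target_states = as.character(target_states),
                 n_donor_respondents = as.integer(n_donor_respondents),
                 n_target_respondents = as.integer(n_target_respondents),
                 donor_quota = as.integer(donor_quota),
                 target_quota = as.integer(target_quota),
                 truth = tr,
                 missing_rate_donor = missing_rate_donor,
                 missing_rate_target = missing_rate_target,
                 seed = as.integer(seed), clip = isTRUE(clip)),
            class = "simulation_scenario")
}

#' The canonical two-study layout
#'
#' A donor study of 249 states valued by 611 eligible respondents (six
#' values each, missingness 148/3666) and a target study of 49 states
#' valued by 126 respondents (eight values each, missingness 16/1008) --
#' the sample sizes of the large UK SF-6D valuation survey and the
#' Lebanese pilot it informs. State lists are sampled without replacement
#' from the full descriptive system with the pits state always included.
#' \code{scale} shrinks respondent and state counts proportionally
#' (rounded) for desk-speed runs; quotas are capped at the number of
#' states.
#'
#' @param scale positive scaling factor for both state and respondent
#'   counts.
#' @param seed integer seed (state selection, truth and data).
#' @param truth named list overriding \code{\link{default_truth}}.
#' @param system a \code{\link{sf6d_system}} object.
#' @return A \code{\link{simulation_scenario}}.
#' @export
canonical_scenario <- function(scale = 1, seed = 2021L, truth = list(),
                               system = sf6d_system()) {
  if (scale <= 0) stop("'scale' must be positive")
  n_d_states <- max(2L, round(249 * scale))
  n_t_states <- max(2L, round(49 * scale))
  n_d_resp <- max(2L, round(611 * scale))
  n_t_resp <- max(2L, round(126 * scale))
  q_d <- min(6L, n_d_states)
  q_t <- min(8L, n_t_states)
  all <- enumerate_states(system)
  pool <- setdiff(all, c(full_health_code(system), pits_code(system)))
  set.seed(seed)
  donor <- c(pits_code(system), sample(pool, n_d_states - 1L))
  target <- c(pits_code(system), sample(pool, n_t_states - 1L))
  simulation_scenario(donor_states = donor, target_states = target,
                      n_donor_respondents = n_d_resp,
                      n_target_respondents = n_t_resp,
                      donor_quota = q_d, target_quota = q_t,
                      truth = truth,
                      missing_rate_donor = 148 / 3666,
                      missing_rate_target = 16 / 1008,
                      seed = seed, system = system)
}

# One draw of an anchored GP: joint normal over the given levels plus the
# full-health anchor, conditioned on the anchor value 1.
.draw_anchored_gp <- function(levels, mean, anchor_mean, sigma_sq, roughness,
                              system, jitter = 1e-8) {
  if (sigma_sq == 0) return(mean)
  Xc <- sweep(levels, 2L, rep(1, 6L))
  c0 <- exp(-as.numeric(Xc^2 %*% roughness))
  Cc <- kernel_matrix(levels, roughness, jitter = 0, system = system) -
    tcrossprod(c0)
  diag(Cc) <- diag(Cc) + jitter
  cm <- mean + c0 * (1 - anchor_mean)
  drop(cm + sqrt(sigma_sq) * t(chol(Cc)) %*% stats::rnorm(nrow(levels)))
}

#' Draw ground-truth utilities and respondent multipliers
#'
#' The donor utility surface is one draw from the anchored GP around the
#' linear truth mean, evaluated over the union of donor and target states
#' (the union is needed to link the two countries). The target surface is
#' the donor truth plus the cross-country offsets plus a fresh anchored
#' GP fluctuation -- exactly the structure the transfer prior assumes.
#' Respondent multipliers are drawn log-normal per country.
#'
#' @param scenario a \code{\link{simulation_scenario}}.
#' @return A \code{"ground_truth"} list: \code{u_donor} (named, over the
#'   state union), \code{u_target} (named, over the target states),
#'   \code{alpha_donor}, \code{alpha_target}, and the scenario.
#' @export
sample_true_utilities <- function(scenario) {
  tr <- scenario$truth
  sys <- scenario$system
  set.seed(scenario$seed)
  union_states <- union(scenario$donor_states, scenario$target_states)
  L_u <- state_levels(union_states, sys)
  Xc_u <- sweep(L_u, 2L, rep(1, 6L))
  m_donor <- tr$gp_intercept + drop(Xc_u %*% tr$gp_slopes)
  u_donor <- .draw_anchored_gp(L_u, m_donor, tr$gp_intercept, tr$sigma_sq,
                               default_roughness(sys), sys)
  names(u_donor) <- union_states
  if (any(u_donor < -1 | u_donor > 1))
    warning("true donor utilities outside [-1, 1]; pathological scenario")

  L_t <- state_levels(scenario$target_states, sys)
  Xc_t <- sweep(L_t, 2L, rep(1, 6L))
  m_target <- u_donor[scenario$target_states] + tr$transfer_gamma +
    drop(Xc_t %*% tr$transfer_beta)
  u_target <- .draw_anchored_gp(L_t, m_target, 1 + tr$transfer_gamma,
                                tr$transfer_sigma_sq,
                                default_roughness(sys), sys)
  names(u_target) <- scenario$target_states

  alpha_donor <- stats::rlnorm(scenario$n_donor_respondents,
                               tr$gamma0, sqrt(tr$tau_sq))
  alpha_target <- stats::rlnorm(scenario$n_target_respondents,
                                tr$gamma0, sqrt(tr$tau_sq))
  structure(list(u_donor = u_donor, u_target = u_target,
                 alpha_donor = alpha_donor, alpha_target = alpha_target,
                 scenario = scenario),
            class = "ground_truth")
}

.generate_country <- function(states, u, alpha, quota, v_sq, missing_rate,
                              clip, prefix) {
  S <- length(states)
  J <- length(alpha)
  resp <- rep(seq_len(J), each = quota)
  sidx <- ((rep(seq_len(J) - 1L, each = quota)) * quota +
             rep(seq_len(quota) - 1L, J)) %% S + 1L
  y <- 1 - alpha[resp] * (1 - u[states][sidx]) +
    stats::rnorm(length(resp), 0, sqrt(v_sq))
  clipped <- 0
  if (clip) {
    clipped <- mean(y < -1 | y > 1)
    y <- pmin(pmax(y, -1), 1)
  }
  keep <- stats::runif(length(y)) >= missing_rate
  df <- data.frame(respondent_id = sprintf("%s%04d", prefix, resp[keep]),
                   state = states[sidx[keep]], y = y[keep])
  attr(df, "clipped_fraction") <- clipped
  df
}

#' Generate standard-gamble valuation records from ground truth
#'
#' Produces per-country long-format adjusted records
#' \eqn{y = 1 - \alpha_j\{1 - u(x)\} + \epsilon}, clipped to
#' \code{[-1, 1]} when the scenario says so, with states allocated to
#' respondents in a balanced round-robin and values removed completely at
#' random at the scenario's missing rates.
#'
#' @param truth a \code{\link{sample_true_utilities}} result.
#' @param scenario the matching \code{\link{simulation_scenario}}
#'   (defaults to the one recorded in \code{truth}).
#' @return List with data frames \code{donor} and \code{target}
#'   (\code{respondent_id, state, y}; each carries a
#'   \code{"clipped_fraction"} attribute) and \code{clipped_fraction}.
#' @export
generate_valuations <- function(truth, scenario = truth$scenario) {
  if (!inherits(truth, "ground_truth")) stop("'truth' must be a ground_truth")
  tr <- scenario$truth
  set.seed(scenario$seed + 1L)
  donor <- .generate_country(scenario$donor_states, truth$u_donor,
                             truth$alpha_donor, scenario$donor_quota,
                             tr$v_sq, scenario$missing_rate_donor,
                             scenario$clip, "d")
  target <- .generate_country(scenario$target_states, truth$u_target,
                              truth$alpha_target, scenario$target_quota,
                              tr$v_sq, scenario$missing_rate_target,
                              scenario$clip, "t")
  list(donor = donor, target = target,
       clipped_fraction = c(donor = attr(donor, "clipped_fraction"),
                            target = attr(target, "clipped_fraction")))
}
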