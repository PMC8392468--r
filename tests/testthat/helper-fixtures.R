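# Shared fixtures built in code: small scenarios and quick fits.

quiet <- function(expr) suppressWarnings(expr)

# A compact two-country scenario with exact model structure (no clipping),
# sized for fast MCMC in tests.
tiny_scenario <- function(seed = 1L, n_states = 12L, n_resp = 20L,
                          quota = 4L, clip = FALSE) {
  all <- setdiff(enumerate_states(), full_health_code())
  set.seed(seed)
  states <- c(pits_code(), sample(setdiff(all, pits_code()), n_states - 1L))
  simulation_scenario(donor_states = states,
                      target_states = states[seq_len(max(2L, n_states %/% 2))],
                      n_donor_respondents = n_resp,
                      n_target_respondents = n_resp,
                      donor_quota = quota,
                      target_quota = min(quota, max(2L, n_states %/% 2L)),
                      seed = seed, clip = clip)
}

tiny_fit <- function(seed = 1L, n_iterations = 600L, n_burnin = 200L,
                     mean_basis = "linear", ...) {
  sc <- tiny_scenario(seed)
  truth <- quiet(sample_true_utilities(sc))
  vals <- generate_valuations(truth)
  cfg <- mcmc_config(n_iterations = n_iterations, n_burnin = n_burnin,
                     thin = 2L, seed = seed, ...)
  fit <- quiet(fit_crude(vals$donor, config = cfg, mean_basis = mean_basis))
  list(fit = fit, truth = truth, vals = vals, scenario = sc)
}

# Raw standard-gamble records for one respondent; pits question included.
raw_records <- function(id, states, sg, pits_sg) {
  data.frame(respondent_id = id,
             state = c(states, pits_code()),
             sg = c(sg, pits_sg),
             is_pits = c(rep(FALSE, length(states)), TRUE))
}
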