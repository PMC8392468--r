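#' Predicted-vs-observed utility table
#'
#' One row per health state: the observed mean valuation and a model's
#' posterior mean and standard deviation. This is the common currency of
#' the evaluation battery (\code{\link{rmse}}, \code{\link{bland_altman}},
#' \code{\link{compare_models}}).
#'
#' @param state six-digit codes (unique).
#' @param observed_mean,post_mean values in \code{[-1, 1]}.
#' @param post_sd non-negative posterior standard deviations (optional).
#' @return A data frame of class \code{"prediction_table"}.
#' @export
prediction_table <- function(state, observed_mean, post_mean,
                             post_sd = NA_real_) {
  state <- as.character(state)
  if (anyDuplicated(state)) stop("duplicate states in prediction table")
  n <- length(state)
  if (length(observed_mean) != n || length(post_mean) != n)
    stop("column lengths differ")
  if (any(observed_mean < -1 | observed_mean > 1) ||
      any(post_mean < -1 | post_mean > 1))
    stop("mean utilities must lie in [-1, 1]")
  if (!all(is.na(post_sd)) && any(post_sd < 0, na.rm = TRUE))
    stop("'post_sd' must be non-negative")
  structure(data.frame(state = state, observed_mean = observed_mean,
                       post_mean = post_mean,
                       post_sd = rep_len(post_sd, n)),
            class = c("prediction_table", "data.frame"))
}

#' Root-mean-square prediction error
#'
#' @param table a \code{\link{prediction_table}} (the full-health row, if
#'   present, is included like any other).
#' @return \eqn{\sqrt{\mathrm{mean}\{(post - observed)^2\}}}.
#' @export
rmse <- function(table) {
  if (nrow(table) < 1L) stop("empty prediction table")
  sqrt(mean((table$post_mean - table$observed_mean)^2))
}

#' Bland-Altman agreement between observed and predicted mean utilities
#'
#' Differences are taken as observed minus predicted, so a positive mean
#' bias means the model under-predicts. The 95\% limits of agreement are
#' \eqn{\mathrm{bias} \pm 1.96 \, s_d} with \eqn{s_d} the sample standard
#' deviation of the differences; their width \eqn{3.92 s_d} is the
#' headline precision figure.
#'
#' @param table a \code{\link{prediction_table}} with at least two rows.
#' @return An \code{"agreement_report"} list: \code{rmse},
#'   \code{mean_bias}, \code{diff_sd}, \code{loa_low}, \code{loa_high},
#'   \code{loa_range}, \code{n}.
#' @export
bland_altman <- function(table) {
  if (nrow(table) < 2L) stop("need at least two rows for agreement limits")
  d <- table$observed_mean - table$post_mean
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(rmse = rmse(table), mean_bias = bias, diff_sd = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 loa_range = 2 * 1.96 * s, n = nrow(table)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Agreement (observed - predicted), n =", x$n, "\n")
  cat(sprintf("  RMSE        %.4f\n", x$rmse))
  cat(sprintf("  mean bias   %.4f\n", x$mean_bias))
  cat(sprintf("  diff sd     %.4f\n", x$diff_sd))
  cat(sprintf("  95%% LoA     [%.4f, %.4f]  (range %.4f)\n",
              x$loa_low, x$loa_high, x$loa_range))
  invisible(x)
}

#' Monotonicity audit over adjacent state pairs
#'
#' A value set should be monotone: improving a single dimension by one
#' level must not lower the predicted utility. The audit samples
#' \code{n_pairs} states without replacement, pairs each with one of its
#' \code{\link{adjacent_states}} chosen uniformly, and counts a violation
#' when the dominating state (the lower level in the one differing
#' dimension) has a strictly lower predicted value; ties are not
#' violations.
#'
#' @param predict function taking a character vector of codes and
#'   returning predicted values (vectorised).
#' @param system a \code{\link{sf6d_system}} object.
#' @param n_pairs number of primary states to sample (at most
#'   \code{state_count(system)}).
#' @param seed RNG seed; fixed seed gives an identical report.
#' @return A \code{"monotonicity_report"}: \code{n_pairs},
#'   \code{n_violations}, \code{violation_rate}, \code{seed}.
#' @export
monotonicity_audit <- function(predict, system = sf6d_system(),
                               n_pairs = 10000L, seed = 1L) {
  all <- enumerate_states(system)
  if (n_pairs > length(all))
    stop("cannot sample ", n_pairs, " states without replacement from ",
         length(all))
  set.seed(seed)
  primary <- sample(all, n_pairs)
  partner <- vapply(primary, function(s) {
    nb <- adjacent_states(s, system)
    nb[sample.int(length(nb), 1L)]
  }, character(1L), USE.NAMES = FALSE)
  vp <- predict(primary)
  vq <- predict(partner)
  Lp <- state_levels(primary, system)
  Lq <- state_levels(partner, system)
  # the pair differs in exactly one dimension by one level
  primary_dominates <- rowSums(Lp) < rowSums(Lq)
  v_dom <- ifelse(primary_dominates, vp, vq)
  v_oth <- ifelse(primary_dominates, vq, vp)
  viol <- v_dom < v_oth
  structure(list(n_pairs = as.integer(n_pairs),
                 n_violations = as.integer(sum(viol)),
                 violation_rate = mean(viol), seed = as.integer(seed)),
            class = "monotonicity_report")
}

#' @export
print.monotonicity_report <- function(x, ...) {
  cat(sprintf("Monotonicity audit: %d / %d adjacent pairs violated (%.1f%%)\n",
              x$n_violations, x$n_pairs, 100 * x$violation_rate))
  invisible(x)
}

#' Cost-per-QALY impact of a utility difference
#'
#' Illustrates why small utility differences matter: for a treatment
#' extending life by \code{years} at a given \code{cost}, QALYs gained are
#' utility times years and cost per QALY is cost divided by QALYs. A
#' utility estimate of 0.54 instead of 0.50 for one added life-year at
#' a cost of 10,000 moves the cost per QALY from 20,000 to about 18,519 --
#' across a typical funding threshold.
#'
#' @param utility_a,utility_b utilities in \code{(0, 1]} under two
#'   estimates.
#' @param years life-years gained (> 0).
#' @param cost treatment cost (>= 0).
#' @return List: \code{qalys_a}, \code{qalys_b}, \code{cost_per_qaly_a},
#'   \code{cost_per_qaly_b}.
#' @export
qaly_cost_illustration <- function(utility_a, utility_b, years, cost) {
  for (u in c(utility_a, utility_b))
    if (is.na(u) || u <= 0 || u > 1)
      stop("utilities must lie in (0, 1]")
  if (years <= 0) stop("'years' must be positive")
  if (cost < 0) stop("'cost' must be non-negative")
  qa <- utility_a * years
  qb <- utility_b * years
  list(qalys_a = qa, qalys_b = qb,
       cost_per_qaly_a = cost / qa, cost_per_qaly_b = cost / qb)
}

#' Consolidated comparison of several models on the same states
#'
#' @param tables named list of \code{\link{prediction_table}}s sharing one
#'   state set.
#' @return List with \code{agreement} (one row per model: n, rmse, bias,
#'   diff sd, limits of agreement), \code{figure1} (per model, states
#'   sorted by predicted mean, with observed values and errors) and
#'   \code{figure3} (observed-vs-predicted scatter data).
#' @export
compare_models <- function(tables) {
  if (!length(tables) || is.null(names(tables)) || any(names(tables) == ""))
    stop("'tables' must be a non-empty named list")
  ref <- sort(tables[[1L]]$state)
  for (tb in tables)
    if (!identical(sort(tb$state), ref))
      stop("all prediction tables must cover the same states")
  agreement <- do.call(rbind, lapply(names(tables), function(nm) {
    a <- bland_altman(tables[[nm]])
    data.frame(model = nm, n = a$n, rmse = a$rmse, mean_bias = a$mean_bias,
               diff_sd = a$diff_sd, loa_low = a$loa_low,
               loa_high = a$loa_high, loa_range = a$loa_range)
  }))
  figure1 <- do.call(rbind, lapply(names(tables), function(nm) {
    tb <- tables[[nm]]
    o <- order(tb$post_mean)
    data.frame(model = nm, rank = seq_len(nrow(tb)), state = tb$state[o],
               predicted = tb$post_mean[o], observed = tb$observed_mean[o],
               error = tb$observed_mean[o] - tb$post_mean[o])
  }))
  figure3 <- do.call(rbind, lapply(names(tables), function(nm) {
    tb <- tables[[nm]]
    data.frame(model = nm, state = tb$state, observed = tb$observed_mean,
               predicted = tb$post_mean)
  }))
  rownames(agreement) <- rownames(figure1) <- rownames(figure3) <- NULL
  list(agreement = agreement, figure1 = figure1, figure3 = figure3)
}

#' Published posterior-estimate table for the two-country case study
#'
#' The packaged fixture transcribes the published per-state summary of a
#' 49-state target valuation study: observed mean utilities, the donor
#' (UK) posterior means and sds used as the informative prior, and the
#' posterior means and sds from the crude and the informative-prior
#' models. (The published table carries 50 states plus full health.)
#'
#' @return Data frame with columns \code{state}, \code{observed_mean},
#'   \code{uk_mean}, \code{uk_sd}, \code{crude_mean}, \code{crude_sd},
#'   \code{model1_mean}, \code{model1_sd}.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1.csv", package = "sf6dvalue",
                      mustWork = TRUE)
  utils::read.csv(path, colClasses = c(state = "character"))
}
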