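#' Write / read a country-posterior bundle as plain CSV
#'
#' A bundle is a directory with \code{mean.csv} (\code{state,mean}) and
#' \code{cov.csv} (covariance matrix with state headers); plain text so
#' bundles survive any transport.
#'
#' @param posterior a \code{\link{country_posterior}}.
#' @param dir bundle directory (created if needed).
#' @return The directory (write) or a \code{country_posterior} (read).
#' @export
write_country_posterior <- function(posterior, dir) {
  if (!inherits(posterior, "country_posterior"))
    stop("'posterior' must be a country_posterior")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_atomic(data.frame(state = posterior$states, mean = posterior$mean),
                file.path(dir, "mean.csv"))
  cov <- as.data.frame(posterior$cov)
  names(cov) <- posterior$states
  .write_atomic(cov, file.path(dir, "cov.csv"))
  invisible(dir)
}

#' @rdname write_country_posterior
#' @export
read_country_posterior <- function(dir) {
  m <- utils::read.csv(file.path(dir, "mean.csv"),
                       colClasses = c(state = "character"))
  cov <- as.matrix(utils::read.csv(file.path(dir, "cov.csv"),
                                   check.names = FALSE))
  country_posterior(m$state, m$mean, cov)
}

.write_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE, eol = "\n")
  file.rename(tmp, path)
  invisible(path)
}

.write_json_atomic <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

.write_manifest <- function(out, command, config) {
  .write_json_atomic(list(command = command, config = config,
                          seed = config$seed,
                          package = "sf6dvalue",
                          package_version =
                            as.character(utils::packageVersion("sf6dvalue")),
                          r_version = R.version.string),
                     file.path(out, "manifest.json"))
}

#' Recompute the published-table evaluation metrics
#'
#' Reads the packaged fixture (\code{\link{table1_fixture}}), builds
#' prediction tables for the crude and the informative-prior model, and
#' recomputes RMSE, Bland-Altman agreement and the sorted
#' predicted/observed orderings -- no model fitting involved.
#'
#' @param out optional output directory; when given, writes
#'   \code{agreement.json}, \code{figure1_data.csv},
#'   \code{figure3_data.csv} and a manifest.
#' @return (Invisibly when writing) the \code{\link{compare_models}}
#'   result.
#' @export
reproduce_table1 <- function(out = NULL) {
  t1 <- table1_fixture()
  tabs <- list(
    crude = prediction_table(t1$state, t1$observed_mean, t1$crude_mean,
                             t1$crude_sd),
    model1 = prediction_table(t1$state, t1$observed_mean, t1$model1_mean,
                              t1$model1_sd))
  cmp <- compare_models(tabs)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    ag <- cmp$agreement
    .write_json_atomic(lapply(stats::setNames(seq_len(nrow(ag)), ag$model),
                              function(i) as.list(ag[i, -1L])),
                       file.path(out, "agreement.json"))
    .write_atomic(cmp$figure1, file.path(out, "figure1_data.csv"))
    .write_atomic(cmp$figure3, file.path(out, "figure3_data.csv"))
    .write_manifest(out, "reproduce-table1", list(seed = NA))
    return(invisible(cmp))
  }
  cmp
}

.resolve_config <- function(config, defaults = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$seed)) cfg$seed <- 0L
  cfg
}

.mcmc_from_config <- function(cfg) {
  mc <- cfg$mcmc %||% list()
  do.call(mcmc_config, utils::modifyList(list(seed = cfg$seed), mc))
}

#' Run a pipeline stage end to end
#'
#' Thin orchestration over the package functions so a whole analysis can
#' be driven from a flat configuration (a named list or a YAML file).
#' Commands:
#' \describe{
#'   \item{simulate}{generate a two-country synthetic study
#'     (\code{scenario}: arguments for
#'     \code{\link{canonical_scenario}}); writes \code{donor.csv},
#'     \code{target.csv}, \code{truth.json}.}
#'   \item{fit-crude}{fit \code{\link{fit_crude}} to \code{data} (an
#'     adjusted CSV path); writes \code{posterior_summary.csv}
#'     (\code{state,post_mean,post_sd}) and a donor bundle under
#'     \code{donor_posterior/}.}
#'   \item{fit-transfer}{as fit-crude plus \code{donors}: bundle
#'     directories; also writes \code{prior_diagnostics.csv} (per-state
#'     donor mean/sd and prior sd).}
#'   \item{evaluate}{compare \code{predictions} to \code{observed} (CSV
#'     paths with \code{state,mean} columns); writes
#'     \code{agreement.json}.}
#'   \item{reproduce-table1}{see \code{\link{reproduce_table1}}.}
#' }
#' Every run writes a \code{manifest.json} with the fully resolved
#' configuration, so defaults never hide a value.
#'
#' @param command one of the stages above.
#' @param config named list or YAML path; \code{seed} defaults to 0.
#' @param out output directory.
#' @return Invisibly, the stage's main result object.
#' @export
run_pipeline <- function(command = c("simulate", "fit-crude",
                                     "fit-transfer", "evaluate",
                                     "reproduce-table1"),
                         config = list(), out) {
  command <- match.arg(command)
  cfg <- .resolve_config(config)
  if (command == "reproduce-table1") return(reproduce_table1(out))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  res <- switch(command,
    "simulate" = {
      sc_args <- cfg$scenario %||% list()
      sc_args$seed <- sc_args$seed %||% cfg$seed
      sc <- do.call(canonical_scenario, sc_args)
      truth <- sample_true_utilities(sc)
      vals <- generate_valuations(truth)
      .write_atomic(vals$donor, file.path(out, "donor.csv"))
      .write_atomic(vals$target, file.path(out, "target.csv"))
      .write_json_atomic(list(u_donor = as.list(truth$u_donor),
                              u_target = as.list(truth$u_target),
                              truth = sc$truth,
                              clipped_fraction =
                                as.list(vals$clipped_fraction)),
                         file.path(out, "truth.json"))
      vals
    },
    "fit-crude" = ,
    "fit-transfer" = {
      data <- utils::read.csv(cfg$data, colClasses = c(state = "character"))
      mc <- .mcmc_from_config(cfg)
      fit <- if (command == "fit-crude") {
        fit_crude(data, config = mc,
                  mean_basis = cfg$mean_basis %||% "linear")
      } else {
        donors <- lapply(cfg$donors, read_country_posterior)
        fit_transfer(data, donors, config = mc,
                     mean_basis = cfg$mean_basis %||% "linear",
                     weights = cfg$donor_weights)
      }
      ps <- population_mean_utility(fit, fit$states)
      names(ps) <- c("state", "post_mean", "post_sd")
      .write_atomic(ps, file.path(out, "posterior_summary.csv"))
      write_country_posterior(export_posterior(fit),
                              file.path(out, "donor_posterior"))
      if (command == "fit-transfer") {
        agg <- .aggregate_donors(fit$donors, fit$states, fit$donor_weights)
        prior_sd <- sqrt(diag(agg$cov) +
                           mean(fit$draws$sigma_sq) *
                             (1 + fit$config$jitter))
        .write_atomic(data.frame(state = fit$states,
                                 donor_mean = agg$mean,
                                 donor_sd = sqrt(diag(agg$cov)),
                                 prior_sd = prior_sd),
                      file.path(out, "prior_diagnostics.csv"))
      }
      fit
    },
    "evaluate" = {
      pred <- utils::read.csv(cfg$predictions,
                              colClasses = c(state = "character"))
      obs <- utils::read.csv(cfg$observed,
                             colClasses = c(state = "character"))
      i <- match(obs$state, pred$state)
      if (anyNA(i)) stop("predictions missing for some observed states")
      # predictions can stray marginally outside the instrument's scale on
      # very small fits; evaluate them at the scale's bounds
      tb <- prediction_table(obs$state, obs$mean,
                             pmin(1, pmax(-1, pred$mean[i])))
      rep <- bland_altman(tb)
      .write_json_atomic(unclass(rep), file.path(out, "agreement.json"))
      rep
    })
  .write_manifest(out, command, cfg)
  invisible(res)
}
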