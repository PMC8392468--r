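#' Chain a standard-gamble value onto the full-health/death scale
#'
#' All but one standard-gamble question value a state against full health
#' and the pits state, yielding a raw value \code{sg} on \code{[0, 1]}
#' relative to those anchors. Chaining through the respondent's own pits
#' valuation \code{P} places it on the conventional scale where death is 0
#' and full health is 1:
#' \deqn{SG_{ADJ} = SG + (1 - SG) \cdot P.}
#' With \code{P} in \code{[-1, 1]} the result always lies in
#' \code{[-1, 1]}; states worse than death get negative values.
#'
#' @param sg raw standard-gamble indifference value(s) in \code{[0, 1]}.
#' @param pits_value the respondent's (truncated) pits valuation in
#'   \code{[-1, 1]}.
#' @return Adjusted utility value(s) in \code{[-1, 1]}.
#' @examples
#' adjust_sg(0.5, 0.3222)  # 0.6611
#' @export
adjust_sg <- function(sg, pits_value) {
  if (any(is.na(sg)) || any(sg < 0) || any(sg > 1))
    stop("'sg' values must lie in [0, 1]")
  if (any(is.na(pits_value)) || any(pits_value < -1) || any(pits_value > 1))
    stop("'pits_value' must lie in [-1, 1]")
  sg + (1 - sg) * pits_value
}

#' Truncate a raw pits-state valuation at -1
#'
#' Respondents who judge the pits state worse than death can produce raw
#' valuations below -1; these are floored at -1 (worst possible on the
#' adjusted scale). Values already in \code{[-1, 1]} pass through.
#'
#' @param raw_pits raw pits valuation(s); must not exceed 1.
#' @return Value(s) in \code{[-1, 1]}.
#' @export
truncate_pits_value <- function(raw_pits) {
  if (any(is.na(raw_pits))) stop("missing pits value")
  if (any(raw_pits > 1)) stop("pits valuation above 1 is not possible")
  pmax(raw_pits, -1)
}

#' Inclusion and missingness bookkeeping for a valuation study
#'
#' @param n_contacted respondents contacted.
#' @param n_excluded respondents removed before analysis.
#' @param quota standard-gamble values expected per eligible respondent
#'   (including the pits question).
#' @param n_missing values missing among eligible respondents.
#' @return An \code{"inclusion_report"} list with \code{n_eligible},
#'   \code{n_expected_values} and \code{n_observed} filled in.
#' @examples
#' # the two study layouts the model was designed around:
#' inclusion_report(836, 225, 6, 148)$n_observed   # 3518
#' inclusion_report(170, 44, 8, 16)$n_observed     # 992
#' @export
inclusion_report <- function(n_contacted, n_excluded, quota, n_missing) {
  for (v in c(n_contacted, n_excluded, quota, n_missing))
    if (length(v) != 1L || is.na(v) || v < 0 || v != round(v))
      stop("inclusion counts must be single non-negative integers")
  if (n_excluded > n_contacted)
    stop("cannot exclude more respondents than were contacted")
  n_eligible <- n_contacted - n_excluded
  n_expected <- n_eligible * quota
  if (n_missing > n_expected)
    stop("more values missing than expected")
  structure(list(n_respondents_contacted = as.integer(n_contacted),
                 n_excluded = as.integer(n_excluded),
                 n_eligible = as.integer(n_eligible),
                 quota = as.integer(quota),
                 n_expected_values = as.integer(n_expected),
                 n_missing = as.integer(n_missing),
                 n_observed = as.integer(n_expected - n_missing)),
            class = "inclusion_report")
}

#' @export
print.inclusion_report <- function(x, ...) {
  cat("Valuation study inclusion report\n")
  cat(sprintf("  contacted   %6d\n", x$n_respondents_contacted))
  cat(sprintf("  excluded    %6d\n", x$n_excluded))
  cat(sprintf("  eligible    %6d  (quota %d values each)\n",
              x$n_eligible, x$quota))
  cat(sprintf("  expected    %6d\n", x$n_expected_values))
  cat(sprintf("  missing     %6d\n", x$n_missing))
  cat(sprintf("  observed    %6d\n", x$n_observed))
  invisible(x)
}

#' Build an adjusted valuation dataset from raw standard-gamble records
#'
#' Takes one row per elicited value (respondent, state, raw \code{sg},
#' pits flag), truncates each respondent's pits valuation at -1, chains
#' all their other values through it via \code{\link{adjust_sg}}, and
#' drops missing values (complete-case). A respondent whose pits
#' valuation is absent or missing cannot be placed on the death/full
#' health scale and is excluded. The pits question itself enters the
#' output with \code{y} equal to the truncated pits value, so the pits
#' state is modelled like any other state.
#'
#' @param records data frame with columns \code{respondent_id},
#'   \code{state} (six-digit code), \code{sg} (raw value; \code{NA} =
#'   missing; the pits row carries the raw pits valuation, which may be
#'   below -1 before truncation), \code{is_pits} (logical).
#' @param quota expected number of values per eligible respondent,
#'   including the pits question.
#' @param n_contacted total respondents contacted (defaults to the number
#'   of distinct ids in \code{records}); upstream exclusions are the
#'   difference between this and the ids present plus pits-failure
#'   exclusions found here.
#' @param system a \code{\link{sf6d_system}} object used to validate codes.
#' @return List with \code{data} (data frame \code{respondent_id, state,
#'   y}) and \code{report} (an \code{\link{inclusion_report}}).
#' @export
build_dataset <- function(records, quota, n_contacted = NULL,
                          system = sf6d_system()) {
  need <- c("respondent_id", "state", "sg", "is_pits")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  if (nrow(records) == 0L) {
    rep0 <- inclusion_report(n_contacted %||% 0L, n_contacted %||% 0L,
                             quota, 0L)
    return(list(data = data.frame(respondent_id = character(0L),
                                  state = character(0L),
                                  y = numeric(0L)),
                report = rep0))
  }
  invisible(lapply(unique(records$state), parse_state_code, system = system))
  ids <- unique(records$respondent_id)
  if (is.null(n_contacted)) n_contacted <- length(ids)

  out <- vector("list", length(ids))
  excluded <- 0L
  observed_rows <- 0L
  for (k in seq_along(ids)) {
    rec <- records[records$respondent_id == ids[k], , drop = FALSE]
    if (nrow(rec) > quota)
      stop("respondent ", ids[k], " has more records than the quota")
    pits <- rec[rec$is_pits, , drop = FALSE]
    if (nrow(pits) > 1L)
      stop("respondent ", ids[k], " has more than one pits question")
    if (nrow(pits) == 0L || is.na(pits$sg)) {
      excluded <- excluded + 1L
      next
    }
    p <- truncate_pits_value(pits$sg)
    oth <- rec[!rec$is_pits & !is.na(rec$sg), , drop = FALSE]
    y <- c(p, if (nrow(oth)) adjust_sg(oth$sg, p))
    st <- c(pits$state, oth$state)
    observed_rows <- observed_rows + length(y)
    out[[k]] <- data.frame(respondent_id = ids[k], state = st, y = y)
  }
  data <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(data))
    data <- data.frame(respondent_id = character(0L),
                       state = character(0L), y = numeric(0L))
  rownames(data) <- NULL
  n_excluded <- excluded + (n_contacted - length(ids))
  n_eligible <- n_contacted - n_excluded
  n_missing <- n_eligible * quota - observed_rows
  list(data = data,
       report = inclusion_report(n_contacted, n_excluded, quota, n_missing))
}

#' Read / write long-format valuation CSV files
#'
#' Raw files carry \code{respondent_id,state,sg,is_pits} (empty \code{sg}
#' = missing); adjusted files carry \code{respondent_id,state,y}. State
#' codes are kept as character so leading digits are never dropped.
#'
#' @param path file path.
#' @return \code{read_sg_csv}: a data frame in the raw schema.
#' @export
read_sg_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(state = "character"),
                        stringsAsFactors = FALSE)
  if ("is_pits" %in% names(df)) df$is_pits <- as.logical(df$is_pits)
  df
}

#' @rdname read_sg_csv
#' @param data data frame to write.
#' @export
write_valuation_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
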