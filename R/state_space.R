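#' Define a multi-level health-state descriptive system
#'
#' A descriptive system assigns each of six health dimensions an ordered set
#' of severity levels; a health state picks one level per dimension and is
#' written as a six-digit code (level of dimension 1 first). The default is
#' the SF-6D: 6, 4, 5, 6, 5 and 5 levels on physical functioning, role
#' limitation, social functioning, pain, mental health and vitality, giving
#' \code{6*4*5*6*5*5 = 18000} states. State \code{"111111"} is full health
#' and the all-worst state (\code{"645655"} for the SF-6D) is the "pits".
#'
#' @param levels_per_dimension integer vector of six level counts, each in
#'   \code{[2, 9]} (codes are single digits).
#' @param dimension_names character vector of six dimension labels.
#' @return An object of class \code{"valuation_system"}.
#' @examples
#' sys <- sf6d_system()
#' state_count(sys)   # 18000
#' pits_code(sys)     # "645655"
#' @export
sf6d_system <- function(levels_per_dimension = c(6L, 4L, 5L, 6L, 5L, 5L),
                        dimension_names = c("physical functioning",
                                            "role limitation",
                                            "social functioning",
                                            "pain",
                                            "mental health",
                                            "vitality")) {
  lv <- as.integer(levels_per_dimension)
  if (length(lv) != 6L || anyNA(lv))
    stop("'levels_per_dimension' must be six integers")
  if (any(lv < 2L))
    stop("every dimension needs at least 2 levels")
  if (any(lv > 9L))
    stop("level counts above 9 cannot be written as single-digit codes")
  if (length(dimension_names) != 6L)
    stop("'dimension_names' must have six entries")
  structure(list(levels_per_dimension = lv,
                 dimension_names = as.character(dimension_names)),
            class = "valuation_system")
}

#' @export
print.valuation_system <- function(x, ...) {
  cat("Health-state descriptive system (6 dimensions,",
      format(state_count(x), big.mark = ","), "states)\n")
  for (d in 1:6)
    cat(sprintf("  %-22s %d levels\n", x$dimension_names[d],
                x$levels_per_dimension[d]))
  invisible(x)
}

#' Number of distinct states in a descriptive system
#'
#' @param system a \code{\link{sf6d_system}} object.
#' @return Integer: the product of the per-dimension level counts (18,000
#'   for the default SF-6D).
#' @export
state_count <- function(system = sf6d_system()) {
  as.integer(prod(system$levels_per_dimension))
}

#' Parse a six-digit state code into dimension levels
#'
#' @param code a six-character digit string such as \code{"645655"}.
#' @param system a \code{\link{sf6d_system}} object.
#' @return Integer vector of six 1-based levels.
#' @examples
#' parse_state_code("645655")  # the SF-6D pits state
#' @export
parse_state_code <- function(code, system = sf6d_system()) {
  if (length(code) != 1L || is.na(code))
    stop("'code' must be a single string")
  code <- as.character(code)
  if (!grepl("^[0-9]{6}$", code))
    stop("malformed state code '", code, "': need exactly 6 digits")
  lv <- as.integer(strsplit(code, "")[[1L]])
  ld <- system$levels_per_dimension
  bad <- which(lv < 1L | lv > ld)
  if (length(bad)) {
    d <- bad[1L]
    stop(sprintf("level %d out of range [1, %d] on dimension %d (%s)",
                 lv[d], ld[d], d, system$dimension_names[d]))
  }
  lv
}

#' Convert dimension levels back to a six-digit code
#'
#' @param levels integer vector (or 6-column matrix) of 1-based levels.
#' @param system a \code{\link{sf6d_system}} object.
#' @return Character code(s); inverse of \code{\link{parse_state_code}}.
#' @export
levels_to_code <- function(levels, system = sf6d_system()) {
  m <- if (is.matrix(levels)) levels else matrix(levels, nrow = 1L)
  if (ncol(m) != 6L) stop("'levels' must have six columns")
  if (any(m < 1L) || any(m > rep(system$levels_per_dimension, each = nrow(m))))
    stop("levels out of range for this system")
  apply(m, 1L, paste0, collapse = "")
}

#' Level matrix for a vector of state codes
#'
#' Vectorised companion to \code{\link{parse_state_code}}.
#'
#' @param codes character vector of six-digit codes.
#' @param system a \code{\link{sf6d_system}} object.
#' @return Integer matrix, one row per code, six columns.
#' @export
state_levels <- function(codes, system = sf6d_system()) {
  m <- t(vapply(codes, parse_state_code, integer(6L), system = system))
  dimnames(m) <- list(codes, NULL)
  m
}

#' @rdname sf6d_system
#' @export
full_health_code <- function(system = sf6d_system()) {
  levels_to_code(rep(1L, 6L), system)
}

#' @rdname sf6d_system
#' @export
pits_code <- function(system = sf6d_system()) {
  levels_to_code(system$levels_per_dimension, system)
}

#' Enumerate every state of a descriptive system
#'
#' @param system a \code{\link{sf6d_system}} object.
#' @return Character vector of all codes, in odometer order (dimension 6
#'   varies fastest); length equals \code{state_count(system)}.
#' @export
enumerate_states <- function(system = sf6d_system()) {
  g <- expand.grid(rev(lapply(system$levels_per_dimension, seq_len)),
                   KEEP.OUT.ATTRS = FALSE)
  levels_to_code(as.matrix(g[, 6:1]), system)
}

#' States adjacent to a given state
#'
#' Two states are adjacent when they differ in exactly one dimension by
#' exactly one level. Under the default SF-6D every state has between 6
#' (corner states such as full health or the pits) and 12 (all-interior
#' states) neighbours.
#'
#' @param state a six-digit code.
#' @param system a \code{\link{sf6d_system}} object.
#' @return Character vector of adjacent state codes.
#' @export
adjacent_states <- function(state, system = sf6d_system()) {
  lv <- parse_state_code(state, system)
  ld <- system$levels_per_dimension
  out <- character(0L)
  for (d in 1:6) {
    for (step in c(-1L, 1L)) {
      new <- lv[d] + step
      if (new >= 1L && new <= ld[d]) {
        nb <- lv
        nb[d] <- new
        out <- c(out, levels_to_code(nb, system))
      }
    }
  }
  out
}

#' Default kernel roughness parameters
#'
#' The squared-exponential kernel (see \code{\link{kernel_correlation}})
#' uses one decay rate \eqn{b_d} per dimension. The default
#' \eqn{b_d = 2.5/(l_d-1)^2} makes the correlation between the two extreme
#' levels of any single dimension equal to \eqn{e^{-2.5} \approx 0.08},
#' encoding a belief that the utility surface deviates only moderately
#' from an additive linear form.
#'
#' @param system a \code{\link{sf6d_system}} object.
#' @return Numeric vector of six positive roughness parameters.
#' @export
default_roughness <- function(system = sf6d_system()) {
  2.5 / (system$levels_per_dimension - 1)^2
}

.as_levels <- function(x, system) {
  if (is.character(x)) parse_state_code(x, system) else as.numeric(x)
}

#' Kernel correlation between two health states
#'
#' Computes \eqn{c(x, x') = \exp\{-\sum_d b_d (x_d - x'_d)^2\}}, the prior
#' correlation between the utilities of two states under the
#' Gaussian-process model. Similar states (small level differences) are
#' highly correlated; the correlation is 1 when \code{x == x2} and decays
#' with every additional level of separation.
#'
#' @param x,x2 six-digit codes or length-6 level vectors.
#' @param b roughness parameters (see \code{\link{default_roughness}}).
#' @param system a \code{\link{sf6d_system}} object (used only to parse
#'   codes).
#' @return A correlation in \code{(0, 1]}.
#' @examples
#' b <- default_roughness()
#' kernel_correlation("111111", "611111", b)  # exp(-2.5) ~= 0.08
#' @export
kernel_correlation <- function(x, x2, b = default_roughness(system),
                               system = sf6d_system()) {
  if (any(b <= 0)) stop("roughness parameters must be positive")
  lx <- .as_levels(x, system)
  ly <- .as_levels(x2, system)
  exp(-sum(b * (lx - ly)^2))
}

#' Kernel correlation matrix over a set of states
#'
#' Assembles the squared-exponential correlation matrix for a list of
#' states and stabilises it by adding a small jitter to the diagonal
#' (nearby states make the raw matrix numerically singular).
#'
#' @param states character vector of codes, or a numeric level matrix with
#'   six columns.
#' @param b roughness parameters.
#' @param jitter non-negative value added to the diagonal (default
#'   \code{1e-8}).
#' @param system a \code{\link{sf6d_system}} object.
#' @return Symmetric positive-definite matrix with \code{1 + jitter} on
#'   the diagonal.
#' @export
kernel_matrix <- function(states, b = default_roughness(system),
                          jitter = 1e-8, system = sf6d_system()) {
  if (any(b <= 0)) stop("roughness parameters must be positive")
  if (jitter < 0) stop("'jitter' must be non-negative")
  L <- if (is.matrix(states)) states else state_levels(states, system)
  if (nrow(L) < 1L) stop("need at least one state")
  Q <- matrix(0, nrow(L), nrow(L))
  for (d in 1:6) Q <- Q + b[d] * outer(L[, d], L[, d], "-")^2
  C <- exp(-Q)
  diag(C) <- diag(C) + jitter
  if (is.character(states)) dimnames(C) <- list(states, states)
  C
}
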