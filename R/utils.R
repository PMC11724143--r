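#' Derive a reproducible sub-stream seed
#'
#' Deterministically maps a master seed plus an arbitrary sequence of string
#' or numeric labels (iteration number, purpose tag, drug name, ...) to a
#' 31-bit integer seed. Used throughout the simulation engine so that every
#' random draw belongs to a named sub-stream of the master seed: the same
#' (master seed, labels) pair always yields the same stream, and streams
#' with different labels are effectively independent.
#'
#' @param master integer master seed.
#' @param ... labels (character or numeric) identifying the sub-stream.
#' @return a positive integer < 2^31 suitable for [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647  # 2^31 - 1, prime
  labels <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                         character(1)), collapse = "|")
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(labels)) {
    h <- (h * 131 + code) %% m
  }
  # final scramble so consecutive masters do not give consecutive seeds
  h <- (h * 48271) %% m
  as.integer(max(1, h))
}

#' Sample from a normal distribution truncated to an interval
#'
#' Inverse-CDF sampler. Degenerate case sd = 0 returns the (clamped) mean.
#'
#' @param n number of draws.
#' @param mean,sd normal parameters before truncation.
#' @param lower,upper truncation bounds.
#' @param u optional uniforms in (0,1) to drive the draws (length n);
#'   supplying them allows common-random-number coupling across calls.
#' @return numeric vector of length n within \[lower, upper\].
#' @keywords internal
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf, u = NULL) {
  if (sd < 0) stop("sd must be non-negative")
  if (sd == 0) {
    return(rep(min(max(mean, lower), upper), n))
  }
  if (is.null(u)) u <- stats::runif(n)
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(p_lo + u * (p_hi - p_lo), mean, sd)
}

#' Location parameter for a truncated normal with a required mean
#'
#' Solves for the pre-truncation location mu such that a Normal(mu, sd)
#' truncated to \[lower, upper\] has the requested mean. Used so that the
#' age distributions reproduce the published stratum means exactly despite
#' truncation to a plausible age range.
#'
#' @keywords internal
trunc_norm_location <- function(target_mean, sd, lower, upper) {
  if (sd == 0) return(target_mean)
  trunc_mean <- function(mu) {
    a <- (lower - mu) / sd
    b <- (upper - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / (stats::pnorm(b) - stats::pnorm(a))
  }
  stats::uniroot(function(mu) trunc_mean(mu) - target_mean,
                 interval = c(target_mean - 4 * sd, target_mean + 4 * sd),
                 tol = 1e-10)$root
}

#' Draw a categorical variable with stratum-specific probabilities
#'
#' @param strat logical vector: TRUE rows use `p_true`, FALSE rows `p_false`.
#' @param p_true,p_false named probability vectors over the same categories.
#' @return character vector of sampled category labels.
#' @keywords internal
sample_cat_by_stratum <- function(strat, p_true, p_false) {
  stopifnot(identical(names(p_true), names(p_false)))
  n <- length(strat)
  u <- stats::runif(n)
  cum_t <- cumsum(p_true / sum(p_true))
  cum_f <- cumsum(p_false / sum(p_false))
  idx <- ifelse(strat,
                findInterval(u, c(0, cum_t), rightmost.closed = TRUE),
                findInterval(u, c(0, cum_f), rightmost.closed = TRUE))
  names(p_true)[pmin(idx, length(p_true))]
}

#' @keywords internal
sample_bern_by_stratum <- function(strat, p_true, p_false) {
  stats::runif(length(strat)) < ifelse(strat, p_true, p_false)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
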