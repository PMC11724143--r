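#' Constant-hazard medication persistence model
#'
#' Treatment discontinuation is modelled as an exponential time-to-event
#' process parameterized by the fraction of patients still on therapy at
#' 1 year: the discontinuation hazard is \code{lambda = -log(p1)} per year,
#' so the persistence curve is \code{S(t) = exp(-lambda * t) = p1^t}. A
#' 1-year persistence of 0.5 therefore means half of patients have stopped
#' therapy by 1 year (median discontinuation time = 1 year) and patients
#' remain able to discontinue at the same constant hazard thereafter.
#'
#' @param p1 fraction persisting at 1 year, in (0, 1]. \code{p1 = 1} means
#'   patients never discontinue.
#' @return an object of class \code{"persistence_model"} with fields
#'   \code{p1} and \code{lambda} (per year).
#' @examples
#' m <- persistence_model(0.5)
#' persistence_fraction(m, 2)   # 0.25
#' @export
persistence_model <- function(p1) {
  if (!is.numeric(p1) || length(p1) != 1 || p1 <= 0 || p1 > 1) {
    stop("p1 must be a single number in (0, 1]")
  }
  structure(list(p1 = p1, lambda = -log(p1)), class = "persistence_model")
}

#' @export
print.persistence_model <- function(x, ...) {
  if (x$lambda == 0) {
    cat("Persistence model: full persistence (never discontinues)\n")
  } else {
    cat(sprintf("Persistence model: %.0f%% persisting at 1 year (hazard %.4f / year)\n",
                100 * x$p1, x$lambda))
  }
  invisible(x)
}

#' Sample treatment discontinuation times
#'
#' @param model a [persistence_model()].
#' @param n number of draws.
#' @param seed optional integer seed for reproducibility.
#' @param u optional uniforms in (0, 1) driving the draws via the quantile
#'   function; sharing them across models couples discontinuation times
#'   monotonically (common random numbers).
#' @return numeric vector of discontinuation times in years; \code{Inf}
#'   when the patient never discontinues.
#' @export
sample_discontinuation_time <- function(model, n = 1, seed = NULL, u = NULL) {
  stopifnot(inherits(model, "persistence_model"))
  if (model$lambda == 0) return(rep(Inf, n))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(u)) u <- stats::runif(n)
  stats::qexp(u, rate = model$lambda)
}

#' Fraction of patients still on therapy at time t
#'
#' Closed-form companion of [sample_discontinuation_time()]:
#' \code{S(t) = exp(-lambda * t)}.
#'
#' @param model a [persistence_model()].
#' @param t time in years (>= 0; vectorized).
#' @export
persistence_fraction <- function(model, t) {
  stopifnot(inherits(model, "persistence_model"))
  if (any(t < 0)) stop("t must be non-negative")
  exp(-model$lambda * t)
}
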