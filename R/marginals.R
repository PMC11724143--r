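#' Default cohort marginal distributions
#'
#' Returns the configuration describing the joint distribution of baseline
#' characteristics used by [generate_cohort()]. The defaults encode the
#' published baseline-characteristics table of a UK primary-care population
#' of 1 108 055 adults qualifying for dual antihypertensive therapy
#' (2005-2019): marginal prevalences of ASCVD and diabetes, and
#' ASCVD-stratum-conditional distributions of age, sex, smoking, coronary
#' heart disease / cerebrovascular disease / peripheral arterial disease
#' history, heart failure, atrial fibrillation, CKD stage, clinic SBP and
#' DBP categories, baseline antihypertensive treatments, and index period.
#'
#' Categorical probabilities are given per ASCVD stratum (`ascvd`,
#' `non_ascvd`); small rounding slack in printed percentages is
#' renormalized by [validate_marginals()].
#'
#' @return a validated marginals configuration list.
#' @export
default_marginals <- function() {
  m <- list(
    ascvd_prevalence = 172722 / 1108055,
    diabetes_prevalence = 152666 / 1108055,
    age = list(
      ascvd = list(mean = 71.0, sd = 12.4),
      non_ascvd = list(mean = 60.2, sd = 13.6),
      range = c(18, 100)
    ),
    sex_male = list(ascvd = 0.580, non_ascvd = 0.498),
    smoking = list(
      ascvd = c(current = 0.292, ex = 0.452, never = 0.256),
      non_ascvd = c(current = 0.270, ex = 0.360, never = 0.369)
    ),
    # history of coronary heart disease: trichotomy (ASCVD components are
    # zero by definition outside the ASCVD stratum)
    chd = list(
      ascvd = c(prior_mi = 0.232, chd_no_mi = 0.465, none = 0.303),
      non_ascvd = c(prior_mi = 0, chd_no_mi = 0, none = 1)
    ),
    cbvd = list(
      ascvd = c(prior_stroke = 0.241, cbvd_no_stroke = 0.034, none = 0.725),
      non_ascvd = c(prior_stroke = 0, cbvd_no_stroke = 0, none = 1)
    ),
    pad = list(ascvd = 0.187, non_ascvd = 0),
    heart_failure = list(ascvd = 0.111, non_ascvd = 0.011),
    atrial_fibrillation = list(ascvd = 0.122, non_ascvd = 0.025),
    ckd = list(
      ascvd = c("<=II" = 0.776, "III" = 0.177, "IV" = 0.012, "V" = 0.035),
      non_ascvd = c("<=II" = 0.925, "III" = 0.065, "IV" = 0.003, "V" = 0.007)
    ),
    sbp_category = list(
      bins = data.frame(label = c("140-149", "150-159", "160-169", ">=170"),
                        lower = c(140, 150, 160, 170),
                        upper = c(150, 160, 170, 200),
                        stringsAsFactors = FALSE),
      ascvd = c("140-149" = 0.404, "150-159" = 0.280,
                "160-169" = 0.171, ">=170" = 0.145),
      non_ascvd = c("140-149" = 0.262, "150-159" = 0.295,
                    "160-169" = 0.220, ">=170" = 0.223)
    ),
    dbp_category = list(
      ascvd = c("<70" = 0.089, "70-79" = 0.237, "80-89" = 0.371,
                "90-99" = 0.208, "100-109" = 0.075, ">=110" = 0.020),
      non_ascvd = c("<70" = 0.028, "70-79" = 0.111, "80-89" = 0.287,
                    "90-99" = 0.318, "100-109" = 0.192, ">=110" = 0.064)
    ),
    treatments = list(
      ascvd = c(ACEi = 0.195, ARB = 0.051, CCB = 0.146,
                thiazide = 0.082, beta_blocker = 0.209, other = 0.010),
      non_ascvd = c(ACEi = 0.175, ARB = 0.039, CCB = 0.140,
                    thiazide = 0.060, beta_blocker = 0.051, other = 0.006)
    ),
    index_period = list(
      ascvd = c("2005-2009" = 0.310, "2010-2014" = 0.309, "2015-2019" = 0.381),
      non_ascvd = c("2005-2009" = 0.326, "2010-2014" = 0.305, "2015-2019" = 0.369)
    )
  )
  validate_marginals(m)
}

.categorical_dims <- c("smoking", "chd", "cbvd", "ckd", "dbp_category", "index_period")

#' Validate and canonicalize a marginals configuration
#'
#' Checks that every categorical dimension has probabilities summing to 1
#' (within 0.02, the slack implied by percentages printed to one decimal)
#' in both ASCVD strata, that all probabilities lie in \[0, 1\] and that
#' the SBP bins are well-formed; probabilities are renormalized to sum
#' exactly to 1. Throws a configuration error otherwise.
#'
#' @param m a marginals configuration list (see [default_marginals()]).
#' @return the canonicalized configuration.
#' @export
validate_marginals <- function(m) {
  need <- c("ascvd_prevalence", "diabetes_prevalence", "age", "sex_male",
            "smoking", "chd", "cbvd", "pad", "heart_failure",
            "atrial_fibrillation", "ckd", "sbp_category", "dbp_category",
            "treatments", "index_period")
  missing <- setdiff(need, names(m))
  if (length(missing)) {
    stop("marginals configuration is missing: ", paste(missing, collapse = ", "))
  }
  chk_prob <- function(p, what) {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
      stop("invalid probability in '", what, "'")
    }
  }
  chk_prob(m$ascvd_prevalence, "ascvd_prevalence")
  chk_prob(m$diabetes_prevalence, "diabetes_prevalence")
  for (s in c("ascvd", "non_ascvd")) {
    chk_prob(m$sex_male[[s]], paste0("sex_male$", s))
    chk_prob(m$pad[[s]], paste0("pad$", s))
    chk_prob(m$heart_failure[[s]], paste0("heart_failure$", s))
    chk_prob(m$atrial_fibrillation[[s]], paste0("atrial_fibrillation$", s))
    chk_prob(m$treatments[[s]], paste0("treatments$", s))
    if (m$age[[s]]$sd < 0) stop("age sd must be non-negative in stratum ", s)
    for (dim in c(.categorical_dims, "sbp_category")) {
      p <- m[[dim]][[s]]
      chk_prob(p, paste0(dim, "$", s))
      if (abs(sum(p) - 1) > 0.02) {
        stop("probabilities for '", dim, "' in stratum '", s,
             "' sum to ", format(sum(p)), ", not 1: configuration error")
      }
      m[[dim]][[s]] <- p / sum(p)
    }
  }
  bins <- m$sbp_category$bins
  if (is.list(bins) && !is.data.frame(bins)) {
    bins <- do.call(rbind, lapply(bins, function(b)
      data.frame(label = b$label, lower = b$lower, upper = b$upper,
                 stringsAsFactors = FALSE)))
    m$sbp_category$bins <- bins
  }
  if (!all(c("label", "lower", "upper") %in% names(m$sbp_category$bins)) ||
      any(m$sbp_category$bins$upper <= m$sbp_category$bins$lower)) {
    stop("sbp_category$bins must have label/lower/upper with upper > lower")
  }
  if (!identical(m$sbp_category$bins$label, names(m$sbp_category$ascvd))) {
    stop("sbp_category probabilities must be named by bin label, in bin order")
  }
  if (m$age$range[1] < 18) stop("age range must start at 18 or above")
  m
}

#' Read / write a marginals configuration as YAML
#'
#' @param path file path.
#' @rdname marginals_io
#' @export
read_marginals <- function(path) {
  if (!file.exists(path)) stop("marginals file not found: ", path)
  m <- yaml::read_yaml(path)
  # yaml drops names into lists; restore named numeric vectors
  restore <- function(x) {
    if (is.list(x) && length(x) && all(vapply(x, is.numeric, logical(1))) &&
        !is.null(names(x)) && all(lengths(x) == 1)) {
      unlist(x)
    } else x
  }
  for (dim in c(.categorical_dims, "treatments")) {
    m[[dim]] <- lapply(m[[dim]], restore)
  }
  m$sbp_category$ascvd <- restore(m$sbp_category$ascvd)
  m$sbp_category$non_ascvd <- restore(m$sbp_category$non_ascvd)
  m$age$range <- unlist(m$age$range)
  validate_marginals(m)
}

#' @param m a marginals configuration.
#' @rdname marginals_io
#' @export
write_marginals <- function(m, path) {
  m <- validate_marginals(m)
  m$sbp_category$bins <- lapply(seq_len(nrow(m$sbp_category$bins)), function(i)
    as.list(m$sbp_category$bins[i, ]))
  # yaml drops names from named numeric vectors; store them as maps
  to_map <- function(x) {
    if (is.numeric(x) && !is.null(names(x))) as.list(x)
    else if (is.list(x) && !is.data.frame(x)) lapply(x, to_map)
    else x
  }
  yaml::write_yaml(to_map(m), path, precision = 12)
  invisible(path)
}
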