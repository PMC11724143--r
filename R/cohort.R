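#' Generate a synthetic cohort of patients qualifying for dual therapy
#'
#' Samples `n` synthetic patients whose marginal and ASCVD-stratum-
#' conditional distributions follow the supplied configuration (by default
#' the published baseline table of the source population; see
#' [default_marginals()]). Sampling scheme: ASCVD and diabetes status are
#' drawn first from their marginal prevalences; age, sex, smoking,
#' comorbidities, CKD stage, SBP/DBP categories, baseline treatments and
#' index period are then drawn conditional on ASCVD status; dimensions are
#' otherwise independent. Ages are drawn from stratum-specific normal
#' distributions truncated to the configured range, with the location
#' solved so the truncated mean equals the printed stratum mean. Clinic SBP
#' is drawn uniformly within its category bin. Within the ASCVD stratum the
#' component histories (MI/CHD, stroke/CBVD, PAD) are redrawn until at
#' least one is present, so the ASCVD flag is always consistent with its
#' components.
#'
#' Eligibility at index requires clinic SBP >= 140 mmHg on blood-pressure-
#' lowering treatment or >= 150 mmHg untreated; untreated patients whose
#' sampled SBP category is 140-149 are therefore reassigned to a category
#' >= 150 (with stratum probabilities renormalized).
#'
#' @param n number of patients (>= 0).
#' @param marginals a marginals configuration, see [default_marginals()].
#' @param seed integer seed; the same (n, marginals, seed) always yields an
#'   identical cohort.
#' @return a data.frame of class \code{"bp_cohort"}, one row per patient,
#'   with columns id, age, sex, smoking, ascvd, diabetes, prior_mi,
#'   chd_no_mi, prior_stroke, cbvd_no_stroke, pad, heart_failure,
#'   atrial_fibrillation, ckd_stage, observed_sbp, sbp_category,
#'   dbp_category, baseline_treatments (";"-separated class labels, empty
#'   string if untreated) and index_period.
#' @examples
#' coh <- generate_cohort(500, seed = 1)
#' mean(coh$age)
#' @export
generate_cohort <- function(n, marginals = default_marginals(), seed = 1) {
  m <- validate_marginals(marginals)
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n != round(n)) {
    stop("n must be a single non-negative integer")
  }
  n <- as.integer(n)
  if (n == 0) return(empty_cohort())
  set.seed(as.integer(seed))

  ascvd <- stats::runif(n) < m$ascvd_prevalence
  diabetes <- stats::runif(n) < m$diabetes_prevalence

  # age: truncated normal per stratum, location matched to printed mean
  rng <- m$age$range
  loc_a <- trunc_norm_location(m$age$ascvd$mean, m$age$ascvd$sd, rng[1], rng[2])
  loc_n <- trunc_norm_location(m$age$non_ascvd$mean, m$age$non_ascvd$sd, rng[1], rng[2])
  age <- numeric(n)
  age[ascvd] <- rtrunc_norm(sum(ascvd), loc_a, m$age$ascvd$sd, rng[1], rng[2])
  age[!ascvd] <- rtrunc_norm(sum(!ascvd), loc_n, m$age$non_ascvd$sd, rng[1], rng[2])

  sex <- ifelse(sample_bern_by_stratum(ascvd, m$sex_male$ascvd, m$sex_male$non_ascvd),
                "male", "female")
  smoking <- sample_cat_by_stratum(ascvd, m$smoking$ascvd, m$smoking$non_ascvd)

  # ASCVD component histories; redraw inside the ASCVD stratum until at
  # least one component is present (flag/component consistency)
  chd <- sample_cat_by_stratum(ascvd, m$chd$ascvd, m$chd$non_ascvd)
  cbvd <- sample_cat_by_stratum(ascvd, m$cbvd$ascvd, m$cbvd$non_ascvd)
  pad <- sample_bern_by_stratum(ascvd, m$pad$ascvd, m$pad$non_ascvd)
  repeat {
    bad <- ascvd & chd == "none" & cbvd == "none" & !pad
    if (!any(bad)) break
    k <- sum(bad)
    chd[bad] <- sample_cat_by_stratum(rep(TRUE, k), m$chd$ascvd, m$chd$non_ascvd)
    cbvd[bad] <- sample_cat_by_stratum(rep(TRUE, k), m$cbvd$ascvd, m$cbvd$non_ascvd)
    pad[bad] <- sample_bern_by_stratum(rep(TRUE, k), m$pad$ascvd, m$pad$non_ascvd)
  }

  heart_failure <- sample_bern_by_stratum(ascvd, m$heart_failure$ascvd,
                                          m$heart_failure$non_ascvd)
  af <- sample_bern_by_stratum(ascvd, m$atrial_fibrillation$ascvd,
                               m$atrial_fibrillation$non_ascvd)
  ckd_stage <- sample_cat_by_stratum(ascvd, m$ckd$ascvd, m$ckd$non_ascvd)
  dbp_category <- sample_cat_by_stratum(ascvd, m$dbp_category$ascvd,
                                        m$dbp_category$non_ascvd)
  index_period <- sample_cat_by_stratum(ascvd, m$index_period$ascvd,
                                        m$index_period$non_ascvd)

  # baseline treatments: independent Bernoulli per class, stratum-conditional
  tx_classes <- names(m$treatments$ascvd)
  tx <- matrix(FALSE, n, length(tx_classes), dimnames = list(NULL, tx_classes))
  for (cl in tx_classes) {
    tx[, cl] <- sample_bern_by_stratum(ascvd, m$treatments$ascvd[[cl]],
                                       m$treatments$non_ascvd[[cl]])
  }
  treated <- rowSums(tx) > 0
  baseline_treatments <- apply(tx, 1, function(z)
    paste(tx_classes[z], collapse = ";"))

  # SBP category, honouring the eligibility rule for untreated patients
  sbp_category <- sample_cat_by_stratum(ascvd, m$sbp_category$ascvd,
                                        m$sbp_category$non_ascvd)
  bins <- m$sbp_category$bins
  lo150 <- bins$label[bins$lower >= 150]
  fix <- !treated & !(sbp_category %in% lo150)
  if (any(fix)) {
    p_a <- m$sbp_category$ascvd[lo150]
    p_n <- m$sbp_category$non_ascvd[lo150]
    sbp_category[fix] <- sample_cat_by_stratum(ascvd[fix], p_a / sum(p_a),
                                               p_n / sum(p_n))
  }
  bi <- match(sbp_category, bins$label)
  observed_sbp <- bins$lower[bi] + stats::runif(n) * (bins$upper[bi] - bins$lower[bi])

  structure(
    data.frame(
      id = seq_len(n),
      age = age,
      sex = sex,
      smoking = smoking,
      ascvd = ascvd,
      diabetes = diabetes,
      prior_mi = chd == "prior_mi",
      chd_no_mi = chd == "chd_no_mi",
      prior_stroke = cbvd == "prior_stroke",
      cbvd_no_stroke = cbvd == "cbvd_no_stroke",
      pad = pad,
      heart_failure = heart_failure,
      atrial_fibrillation = af,
      ckd_stage = ckd_stage,
      observed_sbp = observed_sbp,
      sbp_category = sbp_category,
      dbp_category = dbp_category,
      baseline_treatments = baseline_treatments,
      index_period = index_period,
      stringsAsFactors = FALSE
    ),
    class = c("bp_cohort", "data.frame")
  )
}

empty_cohort <- function() {
  structure(
    data.frame(id = integer(0), age = numeric(0), sex = character(0),
               smoking = character(0), ascvd = logical(0), diabetes = logical(0),
               prior_mi = logical(0), chd_no_mi = logical(0),
               prior_stroke = logical(0), cbvd_no_stroke = logical(0),
               pad = logical(0), heart_failure = logical(0),
               atrial_fibrillation = logical(0), ckd_stage = character(0),
               observed_sbp = numeric(0), sbp_category = character(0),
               dbp_category = character(0), baseline_treatments = character(0),
               index_period = character(0), stringsAsFactors = FALSE),
    class = c("bp_cohort", "data.frame")
  )
}

#' Does each patient's baseline regimen include a drug class?
#'
#' @param cohort a cohort data.frame.
#' @param class one of "ACEi", "ARB", "CCB", "thiazide", "beta_blocker",
#'   "other".
#' @return logical vector.
#' @export
has_treatment_class <- function(cohort, class) {
  vapply(strsplit(cohort$baseline_treatments, ";", fixed = TRUE),
         function(z) class %in% z, logical(1))
}

#' Write / read a cohort as CSV
#'
#' One row per patient, RFC 4180 quoting, UTF-8; byte-identical for
#' identical cohorts.
#'
#' @param cohort a cohort data.frame.
#' @param path file path.
#' @rdname cohort_io
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- names(empty_cohort())
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("cohort CSV is missing columns: ", paste(missing, collapse = ", "))
  }
  df$baseline_treatments[is.na(df$baseline_treatments)] <- ""
  structure(df[need], class = c("bp_cohort", "data.frame"))
}

#' Summarize a cohort in the layout of the published baseline table
#'
#' Means and SDs for age and category percentages for every generated
#' dimension, overall and within the ASCVD and diabetes strata (and their
#' complements), for direct comparison against the published table.
#'
#' @param cohort a non-empty cohort data.frame.
#' @return a data.frame with columns statistic, category, overall, ascvd,
#'   no_ascvd, diabetes, no_diabetes. Percentages are on the 0-100 scale.
#' @export
summarize_cohort <- function(cohort) {
  if (nrow(cohort) == 0) stop("cannot summarize an empty cohort")
  strata <- list(overall = rep(TRUE, nrow(cohort)),
                 ascvd = cohort$ascvd, no_ascvd = !cohort$ascvd,
                 diabetes = cohort$diabetes, no_diabetes = !cohort$diabetes)
  stat_row <- function(statistic, category, f) {
    vals <- vapply(strata, function(s) if (any(s)) f(s) else NA_real_, numeric(1))
    data.frame(statistic = statistic, category = category, t(vals),
               stringsAsFactors = FALSE)
  }
  pct <- function(flag) function(s) 100 * mean(flag[s])
  rows <- list(
    stat_row("n", "", function(s) sum(s)),
    stat_row("age", "mean", function(s) mean(cohort$age[s])),
    stat_row("age", "sd", function(s) stats::sd(cohort$age[s])),
    stat_row("sex", "male", pct(cohort$sex == "male"))
  )
  for (cat in c("current", "ex", "never")) {
    rows <- c(rows, list(stat_row("smoking", cat, pct(cohort$smoking == cat))))
  }
  for (v in c("prior_mi", "chd_no_mi", "prior_stroke", "cbvd_no_stroke",
              "pad", "heart_failure", "atrial_fibrillation",
              "ascvd", "diabetes")) {
    rows <- c(rows, list(stat_row(v, "yes", pct(cohort[[v]]))))
  }
  for (cat in unique(cohort$ckd_stage)) {
    rows <- c(rows, list(stat_row("ckd_stage", cat, pct(cohort$ckd_stage == cat))))
  }
  for (cat in sort(unique(cohort$sbp_category))) {
    rows <- c(rows, list(stat_row("sbp_category", cat, pct(cohort$sbp_category == cat))))
  }
  for (cat in sort(unique(cohort$dbp_category))) {
    rows <- c(rows, list(stat_row("dbp_category", cat, pct(cohort$dbp_category == cat))))
  }
  for (cl in c("ACEi", "ARB", "CCB", "thiazide", "beta_blocker", "other")) {
    rows <- c(rows, list(stat_row("treatment", cl, pct(has_treatment_class(cohort, cl)))))
  }
  for (cat in sort(unique(cohort$index_period))) {
    rows <- c(rows, list(stat_row("index_period", cat, pct(cohort$index_period == cat))))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.bp_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients (%.1f%% ASCVD, %.1f%% diabetes)\n",
              nrow(x), 100 * mean(x$ascvd), 100 * mean(x$diabetes)))
  if (nrow(x)) {
    cat(sprintf("  age %.1f (%.1f) years, male %.1f%%, mean clinic SBP %.1f mmHg\n",
                mean(x$age), stats::sd(x$age), 100 * mean(x$sex == "male"),
                mean(x$observed_sbp)))
  }
  invisible(x)
}
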