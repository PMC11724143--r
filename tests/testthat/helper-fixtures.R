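# Shared fixtures: built in code, deterministic.

# tiny effect table with exactly-known (sd = 0) and stochastic rows
fixture_effect_table <- function() {
  effect_table(data.frame(
    drug = c("drugA", "drugB", "drugC"),
    dose_mg = c(10, 5, 20),
    class = c("ARB", "CCB", "ACEi"),
    mean_delta_sbp = c(8.8, 8.8, 6.0),
    sd_delta_sbp = c(0, 0, 2.0),
    conventional = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  ))
}

fixture_effect_table_sd0 <- function() {
  tab <- fixture_effect_table()
  tab$sd_delta_sbp <- 0
  tab$conventional <- TRUE
  effect_table(tab)
}

# homogeneous single-stratum cohort for engine oracle checks
fixture_homogeneous_cohort <- function(n) {
  structure(data.frame(
    id = seq_len(n), age = rep(60, n), sex = "male", smoking = "never",
    ascvd = FALSE, diabetes = FALSE, prior_mi = FALSE, chd_no_mi = FALSE,
    prior_stroke = FALSE, cbvd_no_stroke = FALSE, pad = FALSE,
    heart_failure = FALSE, atrial_fibrillation = FALSE, ckd_stage = "<=II",
    observed_sbp = 160, sbp_category = "160-169", dbp_category = "80-89",
    baseline_treatments = "", index_period = "2010-2014",
    stringsAsFactors = FALSE), class = c("bp_cohort", "data.frame"))
}

fixture_homogeneous_risks <- function(n, h0) {
  data.frame(id = seq_len(n), h0 = h0, r0 = 1 - exp(-10 * h0))
}

# unit multipliers, used where closed forms assume no subgroup structure
unit_multipliers <- c(ascvd = 1, diabetes = 1)

# expensive shared objects for the acceptance checks, built once per run
.acc_cache <- new.env(parent = emptyenv())
acceptance_fixture <- function() {
  if (!is.null(.acc_cache$fx)) return(.acc_cache$fx)
  params <- calibrate_risk_params(0.224, dispersion = 0.8,
                                  n = 100000, seed = 101)
  cohort <- generate_cohort(100000, seed = 202)
  risks <- assign_untreated_risk(cohort, params, seed = 303)
  .acc_cache$fx <- list(params = params, cohort = cohort, risks = risks,
                        table = default_effect_table())
  .acc_cache$fx
}
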