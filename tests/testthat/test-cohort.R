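test_that("empty and invalid cohort requests", {
  expect_identical(nrow(generate_cohort(0)), 0L)
  expect_error(generate_cohort(-1), "non-negative")
  bad <- default_marginals()
  bad$smoking$ascvd <- c(current = 0.5, ex = 0.3, never = 0.3)
  expect_error(generate_cohort(10, bad), "configuration error")
  bad2 <- default_marginals()
  bad2$sex_male <- NULL
  expect_error(generate_cohort(10, bad2), "missing")
})

test_that("cohort generation is deterministic and CSV round-trips byte-identically", {
  a <- generate_cohort(400, seed = 5)
  b <- generate_cohort(400, seed = 5)
  expect_identical(a, b)
  c2 <- generate_cohort(400, seed = 6)
  expect_false(identical(a, c2))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort_csv(a, f1); write_cohort_csv(b, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_cohort_csv(f1)
  expect_equal(as.data.frame(back), as.data.frame(a), tolerance = 1e-12)
  unlink(c(f1, f2))
})

test_that("cohort rows satisfy the structural invariants", {
  coh <- generate_cohort(20000, seed = 17)
  expect_true(all(coh$age >= 18 & coh$age <= 100))
  # eligibility: >= 150 mmHg untreated, >= 140 mmHg on treatment
  untreated <- coh$baseline_treatments == ""
  expect_true(all(coh$observed_sbp[untreated] >= 150))
  expect_true(all(coh$observed_sbp >= 140 & coh$observed_sbp <= 200))
  # ASCVD flag holds iff at least one component history is present
  comp <- coh$prior_mi | coh$chd_no_mi | coh$prior_stroke |
    coh$cbvd_no_stroke | coh$pad
  expect_identical(coh$ascvd, comp)
  # SBP lies inside its category bin
  bins <- default_marginals()$sbp_category$bins
  bi <- match(coh$sbp_category, bins$label)
  expect_true(all(coh$observed_sbp >= bins$lower[bi] &
                    coh$observed_sbp <= bins$upper[bi]))
})

test_that("configured frequencies are recovered within sampling error", {
  n <- 50000
  coh <- generate_cohort(n, seed = 23)
  m <- default_marginals()
  # ~45 frequencies are checked simultaneously, so the per-check band uses
  # z = 4 (Bonferroni-style) rather than the 3 appropriate for one check
  within3se <- function(obs, p, n_eff) {
    abs(obs - p) < 4 * sqrt(p * (1 - p) / n_eff) + 1e-9
  }
  expect_true(within3se(mean(coh$ascvd), m$ascvd_prevalence, n))
  expect_true(within3se(mean(coh$diabetes), m$diabetes_prevalence, n))
  for (st in c(TRUE, FALSE)) {
    key <- if (st) "ascvd" else "non_ascvd"
    sub <- coh[coh$ascvd == st, ]
    k <- nrow(sub)
    expect_true(within3se(mean(sub$sex == "male"), m$sex_male[[key]], k))
    for (cat in names(m$smoking[[key]])) {
      expect_true(within3se(mean(sub$smoking == cat), m$smoking[[key]][[cat]], k))
    }
    for (cat in names(m$ckd[[key]])) {
      expect_true(within3se(mean(sub$ckd_stage == cat), m$ckd[[key]][[cat]], k))
    }
    for (cat in names(m$index_period[[key]])) {
      expect_true(within3se(mean(sub$index_period == cat),
                            m$index_period[[key]][[cat]], k))
    }
    for (cl in names(m$treatments[[key]])) {
      expect_true(within3se(mean(has_treatment_class(sub, cl)),
                            m$treatments[[key]][[cl]], k))
    }
    expect_true(within3se(mean(sub$heart_failure), m$heart_failure[[key]], k))
    # SBP categories follow the config among treated patients (the
    # eligibility rule reassigns only untreated patients out of 140-149)
    tr <- sub[sub$baseline_treatments != "", ]
    for (cat in names(m$sbp_category[[key]])) {
      expect_true(within3se(mean(tr$sbp_category == cat),
                            m$sbp_category[[key]][[cat]], nrow(tr)))
    }
  }
})

test_that("stratum age means match the configuration and mix to the overall mean", {
  coh <- generate_cohort(50000, seed = 29)
  m <- default_marginals()
  se_a <- m$age$ascvd$sd / sqrt(sum(coh$ascvd))
  se_n <- m$age$non_ascvd$sd / sqrt(sum(!coh$ascvd))
  expect_lt(abs(mean(coh$age[coh$ascvd]) - m$age$ascvd$mean), 3 * se_a)
  expect_lt(abs(mean(coh$age[!coh$ascvd]) - m$age$non_ascvd$mean), 3 * se_n)
  w <- mean(coh$ascvd)
  mix <- w * mean(coh$age[coh$ascvd]) + (1 - w) * mean(coh$age[!coh$ascvd])
  expect_equal(mix, mean(coh$age), tolerance = 1e-12)
})

test_that("cohort summary reproduces the table layout", {
  coh <- generate_cohort(30000, seed = 37)
  s <- summarize_cohort(coh)
  expect_true(all(c("statistic", "category", "overall", "ascvd", "no_ascvd",
                    "diabetes", "no_diabetes") %in% names(s)))
  age_mean <- s[s$statistic == "age" & s$category == "mean", ]
  expect_equal(age_mean$overall, mean(coh$age), tolerance = 1e-12)
  expect_equal(age_mean$ascvd, mean(coh$age[coh$ascvd]), tolerance = 1e-12)
  male <- s[s$statistic == "sex", ]
  expect_equal(male$overall, 100 * mean(coh$sex == "male"), tolerance = 1e-12)
  # single-patient cohort: percentages are 0 or 100
  one <- summarize_cohort(coh[1, ])
  pct_rows <- one[!(one$statistic %in% c("n", "age")), ]
  expect_true(all(pct_rows$overall %in% c(0, 100)))
  expect_error(summarize_cohort(generate_cohort(0)), "empty")
})

test_that("marginals round-trip through YAML", {
  m <- default_marginals()
  f <- tempfile(fileext = ".yaml")
  write_marginals(m, f)
  m2 <- read_marginals(f)
  expect_equal(m2$ascvd_prevalence, m$ascvd_prevalence, tolerance = 1e-9)
  expect_equal(m2$smoking$ascvd, m$smoking$ascvd, tolerance = 1e-9)
  expect_equal(m2$sbp_category$bins$lower, m$sbp_category$bins$lower)
  coh <- generate_cohort(200, m2, seed = 3)
  expect_identical(coh, generate_cohort(200, m, seed = 3))
  unlink(f)
})
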