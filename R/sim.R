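#' Simulation engine configuration
#'
#' @param n_sample patients sampled (without replacement) from the cohort
#'   per iteration. Default 100 000.
#' @param horizon_days simulation horizon in days. Default 3650
#'   (10 years of 365 days; one day is exactly 1/365 year).
#' @param step_days cycle length in days; the engine cycles daily.
#' @param iterations number of Monte Carlo iterations; the reported rate is
#'   the mean over iterations and the Monte Carlo standard error the
#'   between-iteration SE. Default 10.
#' @param master_seed integer master seed. Every random draw in the engine
#'   comes from a named sub-stream derived from it (see [derive_seed()]),
#'   so a run is fully reproducible from this one value.
#' @param common_random_numbers if TRUE (default) the uniform streams
#'   driving patient sampling, treatment-effect draws, discontinuation and
#'   daily event thresholds are shared across scenarios, so absolute risk
#'   reductions are low-variance paired differences.
#' @param risk_model a [risk_model_params()] object.
#' @return object of class \code{"engine_config"}.
#' @export
engine_config <- function(n_sample = 100000,
                          horizon_days = 3650,
                          step_days = 1,
                          iterations = 10,
                          master_seed = 1,
                          common_random_numbers = TRUE,
                          risk_model = risk_model_params()) {
  if (n_sample < 1) stop("n_sample must be positive")
  if (horizon_days < 1) stop("horizon_days must be positive")
  if (step_days != 1) stop("the engine cycles daily: step_days must be 1")
  if (horizon_days %% step_days != 0) stop("step_days must divide horizon_days")
  if (iterations < 1) stop("iterations must be positive")
  stopifnot(inherits(risk_model, "risk_model_params"))
  structure(list(n_sample = as.integer(n_sample),
                 horizon_days = as.integer(horizon_days),
                 step_days = as.integer(step_days),
                 iterations = as.integer(iterations),
                 master_seed = as.integer(master_seed),
                 common_random_numbers = isTRUE(common_random_numbers),
                 risk_model = risk_model),
            class = "engine_config")
}

#' Build a treatment scenario
#'
#' Resolves a configuration entry (name, drug/dose regimen, 1-year
#' persistence) against an effect table into a validated scenario object.
#'
#' @param entry a list with \code{name} (label), \code{drugs} (character
#'   vector of "drug dose" strings, empty for untreated), optional
#'   \code{p1} (1-year persistence, default 1) and optional \code{mode}
#'   ("fixed_regimen", the default, or "observed_timeline" with a
#'   \code{timeline} data.frame of per-patient treatment spells).
#' @param table an [effect_table()].
#' @return object of class \code{"bp_scenario"} with fields name, regimen
#'   (resolved effect-table rows), persistence, mode and timeline.
#' @export
build_scenario <- function(entry, table) {
  name <- entry$name %||% stop("scenario entry needs a name")
  mode <- entry$mode %||% "fixed_regimen"
  if (!mode %in% c("fixed_regimen", "observed_timeline")) {
    stop("unknown scenario mode '", mode, "'")
  }
  drugs <- entry$drugs %||% character(0)
  drugs <- unlist(drugs)
  regimen <- NULL
  if (length(drugs)) {
    rows <- lapply(drugs, function(d) {
      parts <- strsplit(trimws(d), "\\s+")[[1]]
      if (length(parts) != 2 || is.na(suppressWarnings(as.numeric(parts[2])))) {
        stop("scenario drug entry must be 'drug dose', got '", d, "'")
      }
      effect_entry(table, parts[1], as.numeric(parts[2]))
    })
    regimen <- do.call(rbind, rows)
    if (nrow(regimen) > 2) stop("regimens of more than two agents are not supported")
    if (all(c("ACEi", "ARB") %in% regimen$class)) {
      stop("concurrent ACEi and ARB regimens are excluded")
    }
  }
  timeline <- entry$timeline
  if (mode == "observed_timeline" && is.null(timeline)) {
    stop("observed_timeline scenarios need a 'timeline' data.frame")
  }
  structure(list(name = name,
                 regimen = regimen,
                 persistence = persistence_model(entry$p1 %||% 1),
                 mode = mode,
                 timeline = timeline),
            class = "bp_scenario")
}

#' @export
print.bp_scenario <- function(x, ...) {
  reg <- if (is.null(x$regimen) || nrow(x$regimen) == 0) "untreated" else
    paste(sprintf("%s %g mg", x$regimen$drug, x$regimen$dose_mg), collapse = " + ")
  cat(sprintf("Scenario '%s': %s, 1-year persistence %.0f%%%s\n",
              x$name, reg, 100 * x$persistence$p1,
              if (x$mode == "observed_timeline") " (observed timeline)" else ""))
  invisible(x)
}

#' Simulate event days under a piecewise-constant hazard with one change
#'
#' Exact inverse-transform counterpart of the daily cycle: the daily cycle
#' generates an event on day t with probability 1 - exp(-h(t)/365) given
#' survival to t, so the day of the event is the first day on which the
#' accumulated daily hazard exceeds a unit-exponential threshold
#' E = -log(U). This closed form is statistically identical to the daily
#' loop (see [simulate_event_day_daily()]) and is the engine's default.
#'
#' @param h_on hazard per year while on treatment (vectorized).
#' @param h_off hazard per year after discontinuation.
#' @param disc_day last day on treatment (Inf = never discontinues).
#' @param u uniforms in (0,1), one per patient.
#' @param horizon_days horizon; events after it are censored.
#' @return event day (integer in 1..horizon_days) or NA if censored.
#' @export
simulate_event_day <- function(h_on, h_off, disc_day, u, horizon_days) {
  E <- -log(u)
  r_on <- h_on / 365
  r_off <- h_off / 365
  day <- ifelse(r_on > 0, ceiling(E / r_on), Inf)
  off <- day > disc_day  # threshold not reached during the treated spell
  if (any(off)) {
    resid <- E[off] - disc_day[off] * r_on[off]
    day[off] <- disc_day[off] +
      ifelse(r_off[off] > 0, ceiling(resid / r_off[off]), Inf)
  }
  day <- pmax(day, 1)
  ifelse(day <= horizon_days, day, NA_real_)
}

#' Reference daily-cycle event simulation
#'
#' Literal day-by-day Bernoulli implementation of the simulation semantics:
#' each day the patient has event probability 1 - exp(-h(t)/365), with
#' h(t) = h_on up to the discontinuation day and h_off after. Quadratic in
#' horizon x patients, so intended for validating [simulate_event_day()]
#' at small scale, not for production runs.
#'
#' @inheritParams simulate_event_day
#' @return event day or NA if censored at the horizon.
#' @export
simulate_event_day_daily <- function(h_on, h_off, disc_day, horizon_days) {
  n <- length(h_on)
  day_out <- rep(NA_real_, n)
  pending <- seq_len(n)
  for (d in seq_len(horizon_days)) {
    h <- ifelse(d <= disc_day[pending], h_on[pending], h_off[pending])
    hit <- stats::runif(length(pending)) < 1 - exp(-h / 365)
    day_out[pending[hit]] <- d
    pending <- pending[!hit]
    if (!length(pending)) break
  }
  day_out
}

#' Kaplan-Meier cumulative event curve
#'
#' Product-limit estimate of the cumulative event probability, computed
#' with [survival::survfit()]. With administrative censoring only at the
#' horizon it coincides with the empirical cumulative incidence.
#'
#' @param event_days numeric vector of event days; NA means censored at
#'   the horizon.
#' @param horizon_days horizon in days.
#' @return data.frame with columns \code{day} and \code{estimate}
#'   (cumulative event percentage, monotone non-decreasing, starting at 0).
#' @export
km_curve <- function(event_days, horizon_days) {
  if (any(event_days > horizon_days, na.rm = TRUE) ||
      any(event_days < 0, na.rm = TRUE)) {
    stop("event days must lie in [0, horizon_days]")
  }
  status <- !is.na(event_days)
  time <- ifelse(status, event_days, horizon_days)
  fit <- survival::survfit(survival::Surv(time, status) ~ 1)
  data.frame(day = c(0, fit$time),
             estimate = 100 * (1 - c(1, fit$surv)))
}

#' Kaplan-Meier event rate at the horizon
#' @keywords internal
km_rate_at_horizon <- function(km) {
  km$estimate[nrow(km)]
}

#' Run one scenario on a cohort
#'
#' For each Monte Carlo iteration: samples \code{n_sample} patients without
#' replacement, draws each sampled patient's regimen delta SBP (one
#' truncated-normal draw per drug, additive), converts it to a relative
#' risk with the log-linear model, draws a discontinuation time from the
#' scenario's constant-hazard persistence model, and simulates the event
#' day under the piecewise-constant hazard h0 * RR while on treatment and
#' h0 after discontinuation. Rates are Kaplan-Meier estimates at the
#' horizon (equal to the empirical cumulative incidence under purely
#' administrative censoring), averaged over iterations.
#'
#' All draws come from sub-streams of \code{config$master_seed} keyed by
#' (purpose, iteration, drug) -- and by scenario name only when
#' \code{common_random_numbers} is off -- so runs are reproducible and
#' scenarios are coupled for low-variance risk differences.
#'
#' @param cohort a non-empty cohort data.frame.
#' @param risks data.frame from [assign_untreated_risk()] (columns id, h0,
#'   r0) covering every cohort id.
#' @param scenario a [build_scenario()] object.
#' @param table an [effect_table()]; only needed for observed-timeline
#'   scenarios.
#' @param config an [engine_config()].
#' @return object of class \code{"sim_result"}: scenario name, rate_10y
#'   (percent, at the horizon), mc_se (percent), iteration_rates, km
#'   (pooled Kaplan-Meier curve), n_sample, iterations, horizon_days.
#' @export
run_scenario <- function(cohort, risks, scenario, table = NULL, config) {
  stopifnot(inherits(scenario, "bp_scenario"), inherits(config, "engine_config"))
  if (nrow(cohort) == 0) stop("cohort is empty")
  if (config$n_sample > nrow(cohort)) {
    stop("n_sample (", config$n_sample, ") exceeds cohort size (", nrow(cohort), ")")
  }
  h0_all <- risks$h0[match(cohort$id, risks$id)]
  if (anyNA(h0_all)) stop("risks must cover every cohort id")
  master <- config$master_seed
  scen_tag <- if (config$common_random_numbers) "crn" else scenario$name
  horizon <- config$horizon_days
  n <- config$n_sample

  iter_rates <- numeric(config$iterations)
  pooled_days <- vector("list", config$iterations)
  for (i in seq_len(config$iterations)) {
    set.seed(derive_seed(master, "sample", i, scen_tag))
    idx <- sample.int(nrow(cohort), n)
    h0 <- h0_all[idx]

    if (scenario$mode == "fixed_regimen") {
      delta <- numeric(n)
      if (!is.null(scenario$regimen)) {
        for (k in seq_len(nrow(scenario$regimen))) {
          row <- scenario$regimen[k, ]
          set.seed(derive_seed(master, "delta", i, row$drug, row$dose_mg, scen_tag))
          delta <- delta + rtrunc_norm(n, row$mean_delta_sbp, row$sd_delta_sbp,
                                       lower = 0)
        }
      }
      rr <- rr_from_delta(delta, config$risk_model)
      if (scenario$persistence$lambda == 0) {
        disc_day <- rep(Inf, n)
      } else {
        set.seed(derive_seed(master, "disc", i, scen_tag))
        u_disc <- stats::runif(n)
        disc_day <- floor(365 * stats::qexp(u_disc, rate = scenario$persistence$lambda))
      }
      set.seed(derive_seed(master, "event", i, scen_tag))
      u_ev <- stats::runif(n)
      day <- simulate_event_day(h0 * rr, h0, disc_day, u_ev, horizon)
    } else {
      day <- simulate_iteration_timeline(cohort$id[idx], h0, scenario, table,
                                         config, i, scen_tag)
    }
    iter_rates[i] <- 100 * mean(!is.na(day))
    pooled_days[[i]] <- day
  }
  all_days <- unlist(pooled_days)
  km <- km_curve(all_days, horizon)
  structure(list(scenario = scenario$name,
                 rate_10y = mean(iter_rates),
                 mc_se = if (config$iterations > 1)
                   stats::sd(iter_rates) / sqrt(config$iterations) else NA_real_,
                 iteration_rates = iter_rates,
                 km = km,
                 n_sample = n,
                 iterations = config$iterations,
                 horizon_days = horizon),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Scenario '%s': 10-year event rate %.1f%% (MC SE %.2f), n=%d x %d iterations\n",
              x$scenario, x$rate_10y, x$mc_se, x$n_sample, x$iterations))
  invisible(x)
}

#' Event simulation for an observed-timeline scenario (per-patient spells)
#' @keywords internal
simulate_iteration_timeline <- function(ids, h0, scenario, table, config, iter,
                                        scen_tag) {
  if (is.null(table)) stop("observed_timeline scenarios need an effect table")
  tl <- scenario$timeline
  need <- c("id", "start_day", "end_day", "drug", "dose_mg")
  if (!all(need %in% names(tl))) {
    stop("timeline must have columns ", paste(need, collapse = ", "))
  }
  n <- length(ids)
  master <- config$master_seed
  horizon <- config$horizon_days
  alpha <- config$risk_model$alpha

  # one delta draw per (patient, drug in timeline)
  drug_keys <- unique(paste(tl$drug, tl$dose_mg))
  deltas <- matrix(0, n, length(drug_keys), dimnames = list(NULL, drug_keys))
  for (k in drug_keys) {
    parts <- strsplit(k, " ")[[1]]
    entry <- effect_entry(table, parts[1], as.numeric(parts[2]))
    set.seed(derive_seed(master, "delta", iter, entry$drug, entry$dose_mg, scen_tag))
    deltas[, k] <- rtrunc_norm(n, entry$mean_delta_sbp, entry$sd_delta_sbp, lower = 0)
  }
  set.seed(derive_seed(master, "event", iter, scen_tag))
  E <- -log(stats::runif(n))

  tl_by_id <- split(tl, tl$id)
  day_out <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    rows <- tl_by_id[[as.character(ids[j])]]
    if (is.null(rows) || nrow(rows) == 0) {
      d <- ceiling(E[j] * 365 / h0[j])
      day_out[j] <- if (is.finite(d) && d <= horizon) max(d, 1) else NA_real_
      next
    }
    bp <- sort(unique(pmin(pmax(c(1, rows$start_day, rows$end_day + 1), 1),
                           horizon + 1)))
    if (bp[length(bp)] <= horizon) bp <- c(bp, horizon + 1)
    seg_start <- bp[-length(bp)]
    seg_len <- diff(bp)
    rate <- vapply(seg_start, function(s) {
      active <- rows$start_day <= s & rows$end_day >= s
      d_sum <- sum(deltas[j, paste(rows$drug[active], rows$dose_mg[active])])
      h0[j] * exp(alpha * d_sum) / 365
    }, numeric(1))
    cum <- cumsum(seg_len * rate)
    hit <- which(cum >= E[j])
    if (length(hit)) {
      s <- hit[1]
      prev <- if (s == 1) 0 else cum[s - 1]
      day_out[j] <- seg_start[s] - 1 + ceiling((E[j] - prev) / rate[s])
    }
  }
  day_out
}

#' Absolute risk reduction between two simulation results
#'
#' @param reference,scenario [run_scenario()] results over the same
#'   horizon.
#' @return reference rate minus scenario rate, in percentage points
#'   (negative if the scenario does worse).
#' @export
arr <- function(reference, scenario) {
  stopifnot(inherits(reference, "sim_result"), inherits(scenario, "sim_result"))
  if (reference$horizon_days != scenario$horizon_days) {
    stop("cannot compare results over different horizons")
  }
  reference$rate_10y - scenario$rate_10y
}

#' Run all scenarios overall and within subgroups
#'
#' Runs every scenario on the full cohort and within each subgroup stratum
#' (flag true / false for each of \code{subgroups}), computing each
#' stratum's absolute risk reduction against its own untreated reference.
#' For subgroup strata smaller than \code{config$n_sample}, the per-
#' iteration sample is capped at the stratum size.
#'
#' @param cohort a cohort data.frame.
#' @param risks [assign_untreated_risk()] output for the cohort.
#' @param scenarios list of [build_scenario()] objects; must include one
#'   named \code{"untreated"} (the reference).
#' @param config an [engine_config()].
#' @param table an [effect_table()] (for observed-timeline scenarios).
#' @param subgroups logical cohort columns to stratify on.
#' @param out_dir optional directory; when given, writes
#'   \code{results.csv}, \code{km_curves.csv}, \code{summary.json} and
#'   \code{run_log.txt} there.
#' @return object of class \code{"bp_experiment"}: \code{results}
#'   (scenario x stratum table with rates, MC SEs and ARRs) and
#'   \code{km_curves}.
#' @export
run_experiment <- function(cohort, risks, scenarios, config, table = NULL,
                           subgroups = c("ascvd", "diabetes"),
                           out_dir = NULL) {
  names(scenarios) <- vapply(scenarios, function(s) s$name, character(1))
  if (!"untreated" %in% names(scenarios)) {
    stop("an 'untreated' reference scenario is required")
  }
  strata <- list(overall = rep(TRUE, nrow(cohort)))
  for (sg in subgroups) {
    if (!is.logical(cohort[[sg]])) stop("subgroup '", sg, "' is not a logical column")
    strata[[sg]] <- cohort[[sg]]
    strata[[paste0("no_", sg)]] <- !cohort[[sg]]
  }
  results <- list()
  km_all <- list()
  for (st in names(strata)) {
    keep <- strata[[st]]
    if (!any(keep)) next
    sub_cohort <- cohort[keep, , drop = FALSE]
    cfg <- config
    cfg$n_sample <- min(config$n_sample, nrow(sub_cohort))
    res <- lapply(scenarios, function(s)
      run_scenario(sub_cohort, risks, s, table, cfg))
    ref <- res[["untreated"]]
    for (s in names(res)) {
      r <- res[[s]]
      results[[length(results) + 1]] <- data.frame(
        scenario = s, stratum = st, n_sample = r$n_sample,
        iterations = r$iterations, rate_10y = r$rate_10y,
        mc_se = r$mc_se, arr = arr(ref, r), stringsAsFactors = FALSE)
      km_all[[length(km_all) + 1]] <- data.frame(
        scenario = s, stratum = st, r$km, stringsAsFactors = FALSE)
    }
  }
  out <- structure(list(results = do.call(rbind, results),
                        km_curves = do.call(rbind, km_all),
                        config = config),
                   class = "bp_experiment")
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

#' @export
print.bp_experiment <- function(x, ...) {
  cat("Microsimulation experiment (10-year Kaplan-Meier event rates)\n")
  df <- x$results
  df$rate_10y <- sprintf("%.1f", df$rate_10y)
  df$arr <- sprintf("%.1f", df$arr)
  df$mc_se <- sprintf("%.3f", df$mc_se)
  print(df, row.names = FALSE)
  invisible(x)
}

write_experiment <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$results, file.path(out_dir, "results.csv"), row.names = FALSE)
  utils::write.csv(x$km_curves, file.path(out_dir, "km_curves.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(config = list(n_sample = x$config$n_sample,
                       horizon_days = x$config$horizon_days,
                       iterations = x$config$iterations,
                       master_seed = x$config$master_seed,
                       common_random_numbers = x$config$common_random_numbers,
                       rrr_per_5mmhg = x$config$risk_model$rrr_per_5mmhg),
         results = x$results),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  writeLines(c(sprintf("bpmicrosim run %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               sprintf("master_seed: %d", x$config$master_seed),
               sprintf("n_sample: %d, horizon_days: %d, iterations: %d, crn: %s",
                       x$config$n_sample, x$config$horizon_days,
                       x$config$iterations, x$config$common_random_numbers),
               sprintf("rrr_per_5mmhg: %g", x$config$risk_model$rrr_per_5mmhg)),
             file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Read a scenario configuration file
#'
#' Parses a YAML configuration with \code{engine}, \code{risk_model},
#' \code{scenarios} and \code{subgroups} blocks (see
#' \code{inst/extdata/scenarios_default.yaml}) and resolves the scenarios
#' against an effect table.
#'
#' @param path YAML file.
#' @param table an [effect_table()].
#' @return list with \code{config} ([engine_config()]), \code{scenarios}
#'   (built scenarios) and \code{subgroups}.
#' @export
read_scenario_config <- function(path, table) {
  if (!file.exists(path)) stop("scenario config not found: ", path)
  cfg <- yaml::read_yaml(path)
  eng <- cfg$engine %||% list()
  rm_block <- cfg$risk_model %||% list()
  config <- engine_config(
    n_sample = eng$n_sample %||% 100000,
    horizon_days = eng$horizon_days %||% 3650,
    step_days = eng$step_days %||% 1,
    iterations = eng$iterations %||% 10,
    master_seed = eng$master_seed %||% 1,
    common_random_numbers = eng$common_random_numbers %||% TRUE,
    risk_model = risk_model_params(rm_block$rrr_per_5mmhg %||% 0.10))
  if (is.null(cfg$scenarios) || !length(cfg$scenarios)) {
    stop("scenario config must list at least one scenario")
  }
  scenarios <- lapply(cfg$scenarios, build_scenario, table = table)
  list(config = config,
       scenarios = scenarios,
       subgroups = unlist(cfg$subgroups %||% c("ascvd", "diabetes")))
}

#' Stylized clinical-practice treatment timeline (synthetic, smoke tests)
#'
#' Generates a deliberately stylized monotherapy-dominant timeline for an
#' observed-timeline scenario: a fraction of patients start a conventional
#' standard-dose monotherapy at day 1 and discontinue under a constant
#' hazard; the rest remain untreated. This is a synthetic stand-in for
#' real prescription histories, intended only to exercise the
#' observed-timeline code path.
#'
#' @param cohort a cohort data.frame.
#' @param table an [effect_table()].
#' @param seed integer seed.
#' @param p_treated fraction starting monotherapy.
#' @param p1 1-year persistence of the stylized spells.
#' @param horizon_days timeline horizon.
#' @return data.frame with columns id, start_day, end_day, drug, dose_mg.
#' @export
stylized_practice_timeline <- function(cohort, table, seed = 1,
                                       p_treated = 0.7, p1 = 0.5,
                                       horizon_days = 3650) {
  set.seed(as.integer(seed))
  conv <- table[table$conventional, ]
  mono_pool <- conv[!duplicated(conv$class), ]
  treated <- stats::runif(nrow(cohort)) < p_treated
  ids <- cohort$id[treated]
  if (!length(ids)) {
    return(data.frame(id = integer(0), start_day = integer(0),
                      end_day = integer(0), drug = character(0),
                      dose_mg = numeric(0)))
  }
  pick <- sample.int(nrow(mono_pool), length(ids), replace = TRUE)
  stop_t <- sample_discontinuation_time(persistence_model(p1), n = length(ids))
  data.frame(id = ids,
             start_day = 1L,
             end_day = pmin(horizon_days, pmax(1, floor(365 * stop_t))),
             drug = mono_pool$drug[pick],
             dose_mg = mono_pool$dose_mg[pick],
             stringsAsFactors = FALSE)
}
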