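# bpmicrosim

Patient-level Monte Carlo microsimulation of 10-year cardiovascular
outcomes under antihypertensive treatment strategies.

## What problem this addresses, and for whom

Hypertension guidelines recommend initiating treatment with *dual*
therapy (a renin–angiotensin blocker plus a calcium channel blocker), yet
clinical practice remains dominated by monotherapy, and roughly half of
patients discontinue therapy within a year. For researchers in
cardiovascular epidemiology and health policy, `bpmicrosim` quantifies
what that gap costs: it simulates, patient by patient and day by day, the
10-year incidence of a composite endpoint (non-fatal MI, non-fatal
stroke, non-fatal heart-failure hospitalization, or cardiovascular death)
in a population qualifying for dual blood-pressure-lowering therapy, under
untreated, monotherapy and dual-therapy scenarios at full or reduced
medication persistence.

Because the underlying UK primary-care population (1.1 million patients)
is proprietary, the package ships a synthetic cohort generator matched to
the published baseline characteristics — marginal prevalences,
ASCVD-stratum conditionals, blood-pressure categories — together with a
heterogeneous untreated-risk model calibrated to the published untreated
event rate, so every stage of the pipeline is runnable and testable
without data access.

## The model

For a patient with untreated 10-year risk $r_0$ (constant hazard
$h_0 = -\log(1-r_0)/10$) receiving a regimen that lowers systolic blood
pressure by a patient-specific $\Delta\mathrm{SBP}$ mmHg:

* **Risk modification (log-linear):**
  $RR = e^{\alpha\,\Delta\mathrm{SBP}}$, with
  $\alpha = \log(1 - \mathrm{RRR}_5)/5$ and the BPLTTC-based default
  $\mathrm{RRR}_5 = 0.10$, i.e. a 10% relative risk reduction per
  sustained 5 mmHg. Applied on the cumulative-hazard scale.
* **Treatment effects:** per-drug $\Delta\mathrm{SBP}$ is drawn from
  Normal(mean, sd) truncated at 0, additive over at most two agents, from
  a user-replaceable effect table (defaults: irbesartan, ramipril,
  amlodipine at standard/double doses).
* **Persistence:** discontinuation is exponential with
  $\lambda = -\log p_1$ ($p_1$ = fraction persisting at 1 year); after
  discontinuation the hazard reverts to $h_0$.
* **Untreated risk:** lognormal-hazard frailty
  $h_0 = e^z m$, $z \sim N(\mu, \sigma)$, with subgroup hazard
  multipliers $m$ (ASCVD, diabetes) and $\mu$ calibrated so the untreated
  10-year rate matches its published anchor (22.4%).
* **Event generation:** a daily cycle — event probability
  $1 - e^{-h(t)/365}$ on day $t$ — implemented by its exact
  inverse-transform equivalent, with Kaplan–Meier rates at 3650 days and
  absolute risk reductions (ARR) versus the untreated reference, under
  common random numbers.

## Worked example

```r
library(bpmicrosim)

params <- calibrate_risk_params(0.224, dispersion = 0.8, n = 100000, seed = 1)
cohort <- generate_cohort(100000, seed = 2)
risks  <- assign_untreated_risk(cohort, params, seed = 3)

table <- default_effect_table()
cfg <- engine_config(n_sample = 100000, iterations = 10, master_seed = 4)
scenarios <- list(
  build_scenario(list(name = "untreated", drugs = character(0)), table),
  build_scenario(list(name = "irbesartan_mono", drugs = "irbesartan 150"), table),
  build_scenario(list(name = "dual_p100",
                      drugs = c("irbesartan 150", "amlodipine 5")), table),
  build_scenario(list(name = "dual_p50",
                      drugs = c("irbesartan 150", "amlodipine 5"), p1 = 0.5), table))

experiment <- run_experiment(cohort, risks, scenarios, cfg, table)
print(experiment$results[experiment$results$stratum == "overall",
                         c("scenario", "rate_10y", "mc_se", "arr")],
      row.names = FALSE, digits = 3)
#>         scenario rate_10y  mc_se   arr
#>        untreated     22.6 0.0400 0.000
#>  irbesartan_mono     19.1 0.0290 3.518
#>        dual_p100     16.4 0.0261 6.191
#>         dual_p50     21.7 0.0335 0.837
```

Reading the output: on a cohort calibrated to a 22.4% untreated 10-year
event rate (here 22.6% on an independent seed, Monte Carlo SE 0.04),
irbesartan monotherapy with full persistence averts 3.5 events per 100
patients over 10 years, dual irbesartan + amlodipine averts 6.2, and the
same dual regimen with 50% one-year persistence keeps less than one
percentage point of that benefit — the attenuation pattern that motivates
single-pill combinations. `experiment$results` also contains the ASCVD
and diabetes strata, where the same regimen yields roughly two- to
three-fold larger ARRs because baseline risk, not the relative effect, is
what varies across subgroups.

A command-line front end wraps the same functions:

```sh
bpmicrosim generate  --n 100000 --out cohort.csv --seed 1
bpmicrosim calibrate --target 0.224 --out params.yaml --seed 1
bpmicrosim run --config inst/extdata/scenarios_default.yaml \
               --cohort cohort.csv --params params.yaml --out-dir results
```

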