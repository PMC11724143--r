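---
title: "Methods: microsimulation of cardiovascular outcomes under antihypertensive strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsimulation of cardiovascular outcomes under antihypertensive strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the model

`bpmicrosim` estimates how much 10-year cardiovascular risk is averted when
patients who qualify for dual blood-pressure-lowering therapy actually
receive it — and how much of that benefit survives realistic medication
persistence. The outcome is a composite endpoint (non-fatal myocardial
infarction, non-fatal stroke, non-fatal heart-failure hospitalization, or
cardiovascular death), summarized as 10-year Kaplan–Meier event rates per
treatment scenario and absolute risk reductions (ARR, percentage points)
against an untreated reference.

The causal chain the simulation implements is:

1. **Untreated (baseline) risk.** Each patient carries an untreated 10-year
   cumulative risk $r_0$, equivalently a constant yearly hazard
   $h_0 = -\log(1-r_0)/10$.
2. **Blood-pressure effect of therapy.** A regimen lowers clinic systolic
   blood pressure by a patient-specific amount $\Delta\mathrm{SBP}$ (mmHg),
   drawn per drug from a configurable effect table and summed over the (at
   most two) agents.
3. **Risk modification.** A log-linear model maps the pressure reduction to
   a relative risk, $RR = e^{\alpha\,\Delta\mathrm{SBP}}$ with
   $\alpha = \log(1-\mathrm{RRR}_5)/5$; the default
   $\mathrm{RRR}_5 = 0.10$ (10% relative risk reduction per 5 mmHg) follows
   the BPLTTC individual-patient meta-analysis. The relative effect is
   treated as constant over the horizon and across subgroups, consistent
   with the meta-analytic evidence of effect homogeneity.
4. **Persistence.** Discontinuation is a constant-hazard (exponential)
   process parameterized by the fraction persisting at one year:
   $\lambda = -\log(p_1)$, $S(t) = p_1^{\,t}$. After discontinuation the
   hazard reverts immediately to $h_0$ (no re-initiation, no residual
   effect — discontinuation is all the model describes, and adherence gaps
   within a persistence spell are deliberately out of scope).
5. **Event generation.** A daily-cycle Monte Carlo: on each day $t$ the
   surviving patient experiences the event with probability
   $1 - e^{-h(t)/365}$, where $h(t) = h_0 \cdot RR$ while on treatment and
   $h_0$ after.

## Exact inverse-transform equivalence

The daily cycle with per-day probability $1-e^{-h/365}$ gives survival
through day $d$ of exactly $e^{-\sum_{s\le d} h(s)/365}$, i.e. the hazard is
piecewise constant with (for a fixed regimen) a single change-point at
discontinuation. The engine therefore samples a unit-exponential threshold
$E = -\log U$ and solves for the first day on which the accumulated daily
hazard reaches $E$ — the distribution is identical to the day loop, not an
approximation. `simulate_event_day_daily()` keeps the literal loop, and the
test suite checks the two paths agree distributionally; the closed form is
what makes 100 000-patient × 10-iteration runs take seconds in R.

## Scales: why the relative risk acts on the hazard

Whether a relative "risk" reduction should multiply the cumulative
probability or the hazard is ambiguous in most reporting. We apply $RR$ on
the cumulative-hazard scale (proportional hazards). Reasons: risks stay in
$(0,1)$ for any $\Delta\mathrm{SBP}$; the back-transformation from observed
to untreated risk ($H_0 = H_{obs}/RR$, `untreated_risk_from_observed()`)
becomes exactly invertible, which the simulation requires for internal
consistency; and at the rates involved (≈ 2%/year) the numerical difference
from the probability scale is small. This is the single most consequential
modelling choice in the package; the parameterization is isolated in
`risk_model_params()` so a probability-scale variant can be swapped in
without touching the engine.

# The synthetic cohort

The source population is a proprietary UK primary-care linkage (1 108 055
adults qualifying for dual therapy, 2005–2019) for which only a published
baseline table and two subgroup columns exist. `generate_cohort()` emulates
exactly that printed information and nothing more:

* ASCVD status (prevalence 172 722/1 108 055 ≈ 15.6%) and diabetes
  (152 666/1 108 055 ≈ 13.8%) are drawn first, independently.
* Age, sex, smoking, component cardiovascular histories, heart failure,
  atrial fibrillation, CKD stage, SBP/DBP categories, baseline treatments
  and index period are drawn conditional on ASCVD status, using the two
  printed stratum columns; dimensions are otherwise independent.
* Ages come from stratum normals (ASCVD 71.0 (12.4); non-ASCVD 60.2 (13.6))
  truncated to [18, 100] years. Truncating a normal shifts its mean (by
  about −0.32 years in the ASCVD stratum), so the pre-truncation location
  is solved numerically so that the *truncated* mean equals the printed
  stratum mean.
* Clinic SBP is uniform within its printed category bin; the open-ended
  "≥170" bin is capped at 200 mmHg, the plausibility ceiling the study
  itself applies to reconstructed untreated SBP.
* Eligibility at index (SBP ≥140 mmHg on treatment, ≥150 mmHg untreated) is
  enforced by reassigning untreated patients out of the 140–149 bin; this
  slightly distorts the SBP marginal among untreated patients, an accepted
  cost of honouring the structural rule.
* Within the ASCVD stratum the component histories (MI/CHD, stroke/CBVD,
  PAD) are redrawn until at least one is present, so the flag is always
  consistent with its components. Rejection renormalizes the joint
  distribution and inflates the component prevalences by roughly 1/0.82;
  the components are structural detail, not calibration anchors.

What the generator does **not** emulate: inter-covariate correlations
beyond the printed ASCVD conditionals (in particular the diabetes-stratum
age profile), secular trends across index periods, and any real joint
distribution of treatments with blood pressure. Passing the cohort-fidelity
tests therefore shows the generator reproduces the published margins — not
that it reproduces the source population's joint structure.

## Heterogeneous untreated risk and calibration

The prior study estimated individual observed risk with a Cox model whose
coefficients are not published, so the true risk distribution is
unknowable here. The package instead assigns a lognormal constant-hazard
frailty: $h_0 = e^{z}\cdot m$, $z \sim N(\mu, \sigma)$, with multiplicative
subgroup hazard ratios $m$ (defaults: ASCVD 3.0, diabetes 1.8, chosen once
from the roughly threefold and near-twofold printed event-rate contrasts)
and dispersion $\sigma = 0.8$ by default, exposed as an explicit knob.
The lognormal is the standard frailty family when only a mean anchor is
known.

`calibrate_risk_params()` pins the one free parameter, $\mu$, so that the
population mean untreated 10-year risk equals the published untreated rate
(22.4%). The expectation is computed in closed form over a fixed set of
100 000 standardized frailty draws on a reference cohort, making the
objective smooth and strictly increasing in $\mu$; a bracketing root search
solves it to $10^{-6}$ and the evaluation trace is retained. With
$\sigma = 0$ and unit multipliers the solution reduces to the analytic
inverse $\mu = \log(-\log(1-r)/10)$, which the tests check, and a recovery
test confirms a known $\mu$ is re-estimated to within 1% from its own
implied rate.

An independent-seed evaluation (fresh cohort, fresh frailties, fresh event
stream) reproduces the target within Monte Carlo noise: the combined spread
of cohort composition, frailty sampling and event generation is about
0.09 percentage points at these sizes.

# The pharmacology layer

The effect table shipped in `inst/extdata/effect_table_default.csv` covers
irbesartan, ramipril and amlodipine at standard and double dose. The means
follow the published class-level placebo-adjusted estimates at standard
dose (ARB 10.3, ACEi 8.5, CCB 8.8 mmHg, about 20% more at double dose);
the per-patient standard deviations are nominal 2.0 mmHg values because the
original supplementary distribution table is not public. The table is
configuration: every analysis accepts a replacement CSV. Draws are normal
truncated below at zero (a prescribed antihypertensive never raises
modelled pressure), additive and independent across the two agents of a
combination, and a dose flagged non-conventional excludes the patient
rather than contributing an effect.

Untreated clinic SBP is reconstructed by adding back one sampled effect per
baseline ACEi/ARB/CCB class (thiazides and β-blockers are deliberately not
removed — only the three first-line classes are modelled), using the first
conventional entry of each class as its representative. The reconstruction
records its draws so it can be undone exactly, and the three eligibility
exclusions (non-conventional dose, reconstructed SBP outside 90–200 mmHg,
concurrent ACEi + ARB) are applied sequentially so the consort-style counts
always sum to the number removed. An optional scaling of efficacy with
pretreatment SBP is a known refinement; it is intentionally absent because
only distribution sampling is described for the source analysis.

# The engine, randomness, and outputs

Default problem sizes — chosen as the analysis conditions, and used
throughout the tests and the acceptance script — are 100 000 patients
sampled without replacement per iteration, a 3650-day horizon cycled daily
(one day = 1/365 year exactly), and 10 iterations whose mean and
between-iteration standard error are reported. Rates are Kaplan–Meier
estimates at the horizon (via `survival::survfit`); with administrative
censoring only at the horizon the product-limit estimate equals the
empirical cumulative incidence, which the tests assert exactly.

Every draw comes from a named sub-stream of a single master seed
(`derive_seed()` hashes (purpose, iteration, drug, …) into a 31-bit seed),
so runs are bit-reproducible. With common random numbers (default), the
sampling, effect, discontinuation and event-threshold streams are keyed
identically across scenarios: each simulated patient faces the same
exponential event threshold everywhere, so scenario contrasts are paired.
Because a shared irbesartan draw makes the dual-therapy
$\Delta\mathrm{SBP}$ at least the monotherapy one patient-by-patient, the
orderings rate(untreated) ≥ rate(mono) ≥ rate(dual) and
ARR($p_1{=}0.5$) ≤ ARR($p_1{=}1$) hold per run, not just in expectation —
the property the acceptance suite checks.

The "observed clinical practice" scenario needs per-patient prescription
histories, which only a data holder can supply; it is supported through an
`observed_timeline` mode consuming spell records (id, start day, end day,
drug, dose), simulated under the resulting multi-segment piecewise-constant
hazard. `stylized_practice_timeline()` generates a deliberately synthetic
monotherapy-dominant timeline so the code path stays exercised; its output
mimics no published quantity.

## Degenerate inputs and numerical conventions

* Risk draws whose 10-year probability underflows to 0 or rounds to 1 are
  rejected and redrawn (never clamped), with the count reported.
* All-zero effect-table SDs make the pharmacology layer fully
  deterministic, which the tests exploit for exact oracles.
* `p1 = 1` yields an infinite discontinuation time rather than a very
  large one; hazard 0 yields censoring at the horizon.
* Event days are integers in 1…3650; ties need no breaking because the
  product-limit estimator handles tied event days natively.
* Calibration tolerance is $10^{-6}$ on the rate; conversions between risk
  and hazard are exact inverses to machine precision and are tested to
  $10^{-12}$.

# Known limitations

Beyond the generator's marginal-only fidelity: competing non-cardiovascular
death is not simulated (censoring is administrative only); the relative
effect per mmHg, estimated at 4 years in the meta-analysis, is assumed
time-constant over 10 years; effects are outcome-aggregate (no
stroke-vs-MI distinction) and diastolic pressure plays no role; persistence
is covariate-free and re-initiation is not modelled. Published headline
rates for *treated* scenarios depend on the unavailable patient-level risk
distribution and supplementary effect tables, so this package's
corresponding numbers agree with them in structure (ordering, attenuation,
risk-gradient of ARR) rather than digit-for-digit — only the calibrated
untreated rate and the cohort margins are quantitative anchors.
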