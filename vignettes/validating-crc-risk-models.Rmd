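---
title: "Externally validating colorectal cancer risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Externally validating colorectal cancer risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(crcriskval)
```

## The problem

Risk-stratified screening for colorectal cancer (CRC) needs prediction
models that rank the general population by their probability of developing
the disease. Many such models have been published — logistic regressions,
Cox regressions, simple point scores, and expert-consensus relative-risk
products — but a model is only useful in a population where its
discrimination and calibration have been demonstrated. External validation
of a batch of heterogeneous published models against one cohort requires a
surprising amount of machinery: each model's functional form and covariate
coding must be reproduced exactly, cohort fields must be harmonized to the
models' covariate definitions, absolute risks stated over 10- or 20-year
horizons must be converted to a common 5-year horizon, and the same battery
of discrimination, threshold and calibration metrics must be applied per
model and per sex. This package packages that machinery, together with a
synthetic cohort generator so the whole pipeline is testable end-to-end
without access to restricted cohort data.

## Declarative model specifications

A published model is captured as a `model_spec()`: covariate definitions,
additive terms (coefficient x transformed covariate value), and the
baseline quantities its functional family needs.

* **logistic**: risk $= \mathrm{expit}(\beta_0 + \eta)$, with $\eta$ the
  linear predictor.
* **cox**: risk $= 1 - S_0(t)^{\exp(\eta - \bar\eta)}$, where $S_0(t)$ is
  the baseline survival at the model's native horizon and $\bar\eta$ the
  development-population mean linear predictor.
* **points**: integer point total mapped to risk through a non-decreasing
  step function.
* **rr_product**: risk $= \min(1,\; r_0 \prod_j RR_j)$, a product of
  per-factor relative risks scaling a baseline absolute risk $r_0$.

The cap at 1 and the configurable $r_0$ make the relative-risk engine
total: published consensus scores often omit the population-average
baseline, and leaving it configurable keeps the engine usable with a
user-supplied value. Transforms are limited to identity, log, centring,
scaling and level indicators, chained in listed order; this covers the
functional forms used by the published CRC models without introducing a
formula language.

Sex applicability is deliberately advisory: validation studies score
male-derived models on women to ask whether they transport, so a sex
mismatch sets a flag rather than blocking. An `applicable_age_range`, by
contrast, blocks scoring — it models published implementations that refuse
to compute risk outside their supported age window (50-89 years for one
family of models).

Specs round-trip losslessly through JSON or YAML files
(`read_model_spec()` / `write_model_spec()`), so coefficient sets
transcribed from original publications live in version-controllable text.
The fixture specs shipped in this package's tests are synthetic: they
exercise every functional family but reproduce no published coefficient
set.

## Harmonization, exclusions and missing data

`derive_variables()` applies declarative rules (`sum`, `any`, `threshold`,
`map`, `constant`) to raw fields — e.g. red meat as the sum of beef, pork
and lamb servings, then dichotomised at 3 times/week; current NSAID use as
a disjunction of questionnaire and medication-list sources (where one
`TRUE` source suffices even if the other is missing); a literature-mean
medication duration as a constant when the raw data carry none.

`apply_exclusions()` implements the closed-cohort definition: drop prior
CRC (ICD-9 153.0-153.9, 154.0/1/8; ICD-10 C18.0-C18.9, C19, C20, C21.8),
drop deaths recorded before baseline, and — in the closed cohort — drop
participants without five years of follow-up *except* those whose
follow-up ended by death, who are retained because excluding them would
misrepresent the clinical use of a score applied at baseline. Follow-up
ended by death is encoded in a `censor_reason` column, which makes the
retention rule testable. Step-by-step counts are attached as provenance.

Missing data are handled complete-case per model: `complete_case_mask()`
keeps exactly the participants with observed values for that model's
covariates, so the analysable `n` varies between models. The extreme-case
sensitivity analysis (`extreme_value_impute()`) codes factors with more
than 5% missingness to a distribution extreme — the nearest-rank 90th or
10th percentile for continuous factors, present or absent for dichotomous
ones. Nearest-rank is chosen because it is deterministic and matches an
independent sort-based oracle exactly. Because no direction rule per
factor is defensible a priori, the battery runs *both* directions and
reports both, bracketing the possible impact.

## Horizon conversion

Most published models state risk over 10 or 20 years; validation at 5
years requires conversion under an assumption about the hazard's shape.
Both implemented shapes work on the cumulative hazard
$H = -\log(1 - p)$:

* **constant**: $H_{t} = H_{T}\, t/T$ — appropriate when the observed
  incident rate is flat over follow-up;
* **doubling** (period $d$, default 5 years): hazard accrues like
  $2^{t/d} - 1$, so
  $H_t = H_T\,\frac{2^{t/d}-1}{2^{T/d}-1}$ — for $T = kd$ converted down
  to one period this is division by $2^k - 1$ (1/3 for 10 to 5 years,
  1/15 for 20 to 5).

"Risk doubles every 5 years" is interpreted on the hazard scale rather
than by halving probabilities because the hazard-scale rule keeps outputs
in $[0,1)$ for every input and agrees with linear halving to first order
at the sub-1% risks typical of 5-year CRC. Published validations do not
always print their conversion arithmetic, so the linear rule
($p_5 = p_{10}/2$, $p_5 = p_{10}/3$) is available behind
`method = "linear"`; neither is claimed to be "the" published arithmetic.
The continuous-compounding form extends the geometric block rule smoothly
to non-integer block counts, and makes conversions compose exactly
(20 to 10 to 5 equals 20 to 5 under both shapes, since the hazard ratios
multiply).

## Evaluation

* **AUC** (`auc()`): Mann-Whitney concordance with midrank tie handling;
  the confidence interval uses the DeLong placement-variance estimator,
  the standard for validation studies (Hanley-McNeil available for very
  small samples). Published reports rarely state their CI method; this
  choice is documented, not attributed.
* **Harrell's C** (`harrell_c()`): concordance over comparable pairs
  (shorter time is an event), score ties counting one half, for the
  open-cohort design. Computation delegates to
  `survival::concordance()`; the test suite holds it to an exhaustive
  pair-enumeration oracle.
* **Threshold metrics** (`threshold_metrics()`): the top fraction $q$ of
  scores is flagged and sensitivity, specificity, LR+, LR-, PPV and NPV
  are computed from the confusion matrix. Ties at the cutoff are resolved
  in stable participant order so that exactly `round(q * n)` participants
  are flagged — point-score models produce heavy ties, and without this
  policy "the top 10% of the population" would be unattainable.
* **Calibration** (`calibration_table()`): equal-count groups of predicted
  risk (default deciles; tied predictions stay together), observed versus
  expected events, and the Hosmer-Lemeshow statistic
  $\sum_g (O_g - E_g)^2 / (E_g(1 - \bar p_g))$. Degrees of freedom equal
  the number of groups: no parameters are estimated on the validation
  data, so the development-setting $g-2$ convention does not apply. This
  is a deliberate divergence and affects the p-value, not the statistic.
* **Age-rule comparator** (`age_rule_sensitivity()`): sensitivity and
  flagged fraction of "age at baseline $\ge$ cutoff", the fair comparison
  for a screening programme's age threshold.

Outcomes are binary at 5 years in the closed cohort; deaths within 5
years without CRC count as non-events.

## The pipeline and sensitivity battery

`run_validation()` wires the stages — exclusions, derivation, per-model
complete-case restriction, age-rule blocking, scoring, horizon conversion
under each configured assumption, and sex-stratified evaluation — into a
deterministic report with provenance (config hash, seed, exclusion flow).
`sensitivity_battery()` adds one report per toggle: extreme imputation in
both directions, term-set dropping (a set naming terms absent from every
model yields a `not_applicable` report, not an error), surveillance
exclusion (prior polyp / IBD codes), and the open-cohort design with
Harrell's C. Every non-base report carries per-model discrimination deltas
against base. Rounding (half-even; 1 decimal for percentages, 2 for AUC
and likelihood ratios) happens only at the report boundary in
`write_report()`; JSON output keeps full precision.

## The synthetic cohort generator

`generate_cohort()` emulates the UK Biobank-like validation population
that motivates the pipeline: ~373 000 adults with age truncated-normal
(mean 56.4, SD 8.1, window 40-70), 45.4% male, 10.8% family history of
CRC, never/former/current smoking near 54/35/11%, the observed
BMI-category mix, physical activity normal(28.3, 5.5) MET-h/day with
~12% missingness, and a 5-year incident CRC proportion of 0.46% with
events uniform over (0, 5] years (constant incidence over follow-up).
Category probabilities are the published marginals renormalised over
non-missing totals.

Outcomes are driven by a known generative model
(`default_true_model()`), a logistic model whose coefficients are the log
odds ratios implied by the published case versus non-case marginal
contrasts (for example, 5-year incidence of 0.57% in men versus 0.37% in
women gives a male log odds ratio of about 0.43; a case/non-case mean age
gap of 4.9 years against an age SD of 8.1 gives about 0.075 per year).
Risks are rescaled by a single multiplicative constant to hit the target
incidence — transparent and invertible, unlike an intercept shift, whose
meaning would depend on the functional form. These choices put the
generative score's AUC in the high 0.60s, the range reported for the best
published CRC models, without any tuning loop.

Factors are sampled independently except for declared age tilts (aspirin,
NSAID and former smoking rise with age on the logit scale), reflecting
that medication use is confounded with age; only marginals are published,
so any joint structure is a modelling choice and is configurable. A
configurable fraction of non-events is censored before 5 years, a share
of them by death, giving the closed-cohort retention rule positive test
cases. A truth side-channel (per-participant true risk, latent draw,
uncensored event time) supports oracle tests and is clearly test-only.

What the generator does *not* emulate: healthy-volunteer selection,
assessment-centre geography, within-follow-up ageing, and case-column
marginals beyond what the generative model induces. Passing recovery
tests on this cohort therefore demonstrates that the machinery is
correct, not that any particular published model is well calibrated in a
real population.

## Numerical and scale choices

Checks that need cohort-scale behaviour run at the sizes where the
properties they test are informative: threshold-metric properties on a
373 000-participant cohort at 0.46% incidence (matching the validation
population's scale), ranking recovery on five cohorts of 200 000,
Hosmer-Lemeshow calibration recovery over 50 cohorts of 20 000 (the
statistic should average about its degrees of freedom when predictions
come from the generative truth), and oracle equivalence for AUC and
Harrell's C on thousands of small randomized inputs where brute-force
pair enumeration is exact. Horizon conversions are held to independent
root-solving oracles at the printed precision.

Degenerate inputs are defined rather than left to chance: a risk of 1
cannot be horizon-converted (infinite hazard); a calibration group with
mean predicted risk of exactly 0 or 1 errors; `q = 1` flagging is allowed
as a permissive boundary (sensitivity 100%, specificity 0); point totals
below the lowest map threshold take the lowest mapped risk; an
all-constant factor imputes to that constant.

## Limitations

The package validates models; it does not refit them, and it ships no
published coefficient set — real specs are user-supplied files transcribed
from the original publications. Competing-risk adjustment,
age-conditional residual-lifetime risks, net reclassification and
decision-curve analysis are out of scope. The synthetic cohort is a
testbed, not a substitute for restricted cohort data: conclusions about
any real model require scoring it on the population of intended use.
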