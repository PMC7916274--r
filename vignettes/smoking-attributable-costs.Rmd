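---
title: "Estimating smoking-attributable medical expenditures from panel surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating smoking-attributable medical expenditures from panel surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Smoking damages health through many pathways, so disease-list
("epidemiological") costings systematically understate its medical bill. The
econometric alternative implemented here regresses individual health-care
use and spending on smoking status, holding sociodemographics and other risk
behaviors fixed, and asks the counterfactual question: *what would this
population have spent had every smoker never smoked?* The ratio of the
resulting cost difference to factual cost is the smoking-attributable
fraction (SAF); scaled to the national total health expenditure it yields
the smoking-attributable medical expenditure (SAME).

`samecost` implements this procedure for longitudinal (panel) survey data on
adults aged 45 and above, with three health-care service categories —
outpatient visits (1-month recall), inpatient hospitalizations (12-month
recall) and self-medication (1-month recall) — and ships a synthetic panel
generator with known ground truth so that every stage can be validated
without access to restricted survey microdata.

## The model

Medical spending is semicontinuous: most person-waves spend nothing, and
positive spending is heavily right-skewed. Both features are handled by a
two-part model estimated separately per service:

1. **Use equation (random-effects logit).** For person $i$ at wave $t$,
   $\Pr(D_{it} = 1 \mid x_{it}, \alpha_i) = \mathrm{logit}^{-1}(x_{it}'\gamma
   + \alpha_i)$, where $D_{it}$ indicates any use of the service in its
   recall window and $\alpha_i \sim N(0, \sigma_\alpha^2)$ is a
   time-invariant individual intercept capturing unobserved disease
   susceptibility. The marginal likelihood integrates $\alpha_i$ out by
   adaptive Gauss–Hermite quadrature.

2. **Cost equation (random-effects GLS).** Among users,
   $\ln E_{it} = x_{it}'\beta + \alpha_i' + u_{it}$, estimated by feasible
   GLS with Swamy–Arora variance components and cluster-robust (by person)
   standard errors. The logit coefficients are reported as adjusted odds
   ratios; the log-cost coefficients are semi-elasticities.

The covariate vector $x_{it}$ is identical in both equations: a five-level
smoking status (never; current light and current heavy, split at a smoking
index — cigarettes/day × years smoked — of 200; former smokers who quit
within versus beyond 5 years), sex, age group (45–54, 55–64, 65+),
urban/rural residency, education, marital status, a four-indicator poverty
flag, insurance, economic region, BMI class and drinking status, plus eight
smoking-by-age interaction products (`it1`–`it8`). Age matters doubly:
physical decline modifies how smoking translates into use and cost, which is
why the interactions enter rather than a purely additive age term.

### From fits to SAF

The fitted equations are combined into an expected cost per person-wave,
$\hat{E}[\text{cost}] = \hat{p}_{\text{use}} \times
\hat{E}[\text{cost}\mid\text{use}]$, evaluated twice: on the factual design
and on the never-smoker counterfactual in which the four smoking dummies
*and* all eight interaction columns are zeroed (former smokers are reset
too — the attributable fraction covers current and former smoking). Then

$$\mathrm{SAF} = \frac{\sum \hat{E}_{\text{factual}} -
\sum \hat{E}_{\text{counterfactual}}}{\sum \hat{E}_{\text{factual}}}.$$

Two prediction choices deserve attention because the model is nonlinear:

- **Random-intercept handling.** The default (`population_average`)
  integrates the use probability over $N(0, \hat\sigma_\alpha^2)$ by
  Gauss–Hermite quadrature, giving the population-averaged probability; the
  `zero_intercept` option evaluates at $\alpha = 0$ (the conditional-modal
  prediction many software defaults produce). The SAF is similar under
  both, but the population average is the quantity the aggregation step
  actually needs.
- **Retransformation.** Predicting currency costs from a log-scale
  regression requires a retransformation factor. The default is Duan's
  smearing estimator (the mean of exponentiated composite residuals), which
  is robust to non-normal errors; `normal_theory` uses
  $\exp((\hat\sigma_{\alpha'}^2 + \hat\sigma_u^2)/2)$. Because the same
  factor multiplies factual and counterfactual predictions, it cancels in
  the SAF exactly — a property the test suite asserts — so this choice only
  matters for absolute cost levels.

### From SAF to SAME

National totals come from the aggregation identity

$$\mathrm{SAME} = \mathrm{PV}\cdot\mathrm{QV}\cdot 12\cdot\mathrm{POP}\cdot
\mathrm{SAF}_v + \mathrm{PH}\cdot\mathrm{QH}\cdot\mathrm{POP}\cdot
\mathrm{SAF}_h + \mathrm{PM}\cdot\mathrm{QM}\cdot 12\cdot\mathrm{POP}\cdot
\mathrm{SAF}_m,$$

where PV/PH/PM are average expenditures per outpatient visit, per
hospitalization, and per month of positive self-medication; QV/QH/QM the
corresponding utilization rates per person per recall window; POP the 45+
population; and the factors of 12 annualize the 1-month windows. Survey
self-reports typically understate true spending, so the price terms are
rescaled by a calibration factor: the official all-age national health
expenditure times the 45+ spending share, divided by the national total the
raw survey averages imply. A factor above 1 means the survey undercounts.
(The package also exposes the inverted direction as an option, since either
convention appears in practice.) Per-smoker figures divide each service's
SAME by a service-specific smoker count where supplied.

## The synthetic panel generator

Restricted survey microdata cannot ship with a package, so `sim_config()` /
`simulate_panel()` generate a balanced three-wave panel that mimics the
analysis target:

- **Covariates.** Time-invariant sociodemographics drawn at the baseline
  prevalences of a weighted national 45+ panel (e.g. 44.6% male, 57.5%
  rural, 64.4% never smokers); age advances two years per wave and crosses
  group boundaries. Raw record fields (weight/height, deprivation
  indicators, drinking frequency, full smoking histories) are emitted so
  the measurement layer's deterministic coding is exercised end to end.
- **Smoking dynamics.** Status evolves as a near-absorbing chain: current
  smokers quit with probability 0.06 per wave; quitters age from the
  "quit < 5 years" class into "quit ≥ 5 years"; light smokers whose
  cumulative index crosses 200 become heavy. Never smokers stay never.
  This reproduces the drift toward more quitters seen in repeated waves of
  real aging cohorts.
- **Outcomes.** One normal random intercept per person per equation per
  service; Bernoulli use; conditional lognormal cost. The generating
  coefficient vectors are published-magnitude values (e.g. an adjusted
  odds ratio of 1.421 and a log-cost coefficient of 0.886 for recent
  quitters in the outpatient equations), so parameter recovery is tested
  against effects of realistic size, including near-null ones.
- **Variance components.** Surveys of this kind do not publish them, so
  they are fixed once at values realistic for skewed health-cost panel
  data: $\sigma_\alpha = 1.0$ (use), $\sigma_{\alpha'} = 0.8$ and
  $\sigma_u = 1.3$ (log cost). The implied within-person correlation of
  log costs is about 0.27, and the lognormal tail is heavy but finite.
- **Ground truth.** The bundle returned alongside the panel carries the
  realized design rows and an *analytic* true SAF: every person-wave is
  replayed under the counterfactual with the use probability integrated
  over the intercept distribution. The lognormal factor cancels in the
  ratio; the logit part does not, which is why the truth is computed by
  quadrature rather than in closed form.

What the generator does **not** emulate: multi-stage cluster sampling and
its weights (weights are drawn i.i.d. lognormal and used only in
descriptives), attrition and loss to follow-up, item nonresponse,
measurement error in self-reports, and dependence between the use and cost
random intercepts (an option exists in the design but the default is
independence). Passing tests on synthetic data therefore demonstrate
correctness of the estimation machinery under the model's own assumptions,
not robustness to these real-data complications.

## Numerical choices

- **Quadrature.** 15 adaptive Gauss–Hermite nodes by default for the logit
  likelihood (the convention of mature panel-logit implementations);
  prediction-time population averaging uses a 40-node rule. The test suite
  asserts the optimum moves by less than $10^{-3}$ when nodes double.
- **Optimization.** The logit marginal likelihood is maximized by
  `nloptwrap`/BOBYQA, which reaches the same optimum as slower
  derivative-free alternatives in roughly a third of the evaluations on
  this problem class. The optimizer's exit status is authoritative for the
  `converged` flag; post-hoc gradient heuristics are recorded as notes.
- **Variance components.** Swamy–Arora for the cost equation; a negative
  between-person variance estimate is clamped to zero (with a note), in
  which case FGLS collapses to pooled OLS exactly.
- **Rank deficiency.** Sparse cells (e.g. light smokers aged 65+ among
  inpatient users in a small sample) can zero out a design column. Aliased
  columns are dropped from estimation and reported as coefficient 0 with NA
  standard error, so counterfactual prediction remains well-defined; the
  affected columns are listed in the fit's notes.
- **Boundaries.** A smoking index of exactly 200 is classed heavy (the
  conservative side, making the partition total); "drinks more than once a
  month" is a strict inequality; the BMI normal range is inclusive at 18.5
  and 23.9.
- **Degenerate inputs.** Constant use outcomes, non-positive costs,
  missing CPI years, zero factual totals and non-positive weights all
  raise informative errors rather than propagating NaNs.

## Design decisions that were genuinely open

- **Subgroup SAFs** (by sex and residency) reuse the single pooled fit and
  restrict the prediction sums to the subgroup, rather than refitting per
  stratum. Pooled fits keep rare covariate cells estimable and keep the
  subgroup SAFs internally consistent with the overall one; per-stratum
  refits remain possible by filtering the panel upstream.
- **Model fitting is unweighted**; sampling weights enter only the
  descriptive tables. This mirrors standard practice when the estimand is
  the conditional model itself rather than a finite-population total, and
  it is stated prominently because it is easy to miss.
- **Wave indicators are excluded** from both equations by default: the
  specification conditions on age and smoking duration, which absorb the
  secular drift the waves would otherwise pick up; CPI deflation removes
  price-level drift. (Columns can be added to the design by callers who
  want them.)
- **Overall SAF across services** pools annualized totals (1-month-window
  services scaled by 12) so the pooled ratio weights services the way the
  national aggregation does.

## Problem sizes used by the validation suite

The package's tests validate on simulated panels of 120–5,000 individuals.
The oracle checks use deliberately tiny problems: a 20-individual panel for
the dense-integration check of the logit marginal likelihood (agreement to
$10^{-4}$), and a 6-observation unbalanced panel for the explicit
block-covariance GLS check (agreement to $10^{-8}$). Parameter-recovery
checks replicate 1,000-individual panels a dozen times and compare mean
estimates with generating values on the Monte-Carlo standard-error scale;
end-to-end SAF recovery replicates the full pipeline and compares against
the analytic truth the generator carries. These sizes were chosen so the
whole suite runs in minutes on a laptop while leaving the Monte-Carlo
bands tight enough to detect implementation bias.

## Known limitations

- SAF/SAME point estimates are reported without uncertainty intervals; a
  bootstrap over individuals is the natural extension point.
- The counterfactual assumes smoking status is exogenous given the
  covariates and the individual intercept; unmeasured time-varying
  confounders are outside the model.
- Secondhand-smoke costs and cessation-clinic costs are out of scope, so
  national totals produced by this procedure are conservative.
- The calibration factor rescales *levels* only; it cannot correct
  differential under-reporting across services or subgroups.
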