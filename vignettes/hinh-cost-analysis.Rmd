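---
title: "Methods: net-cost analysis of a Hospital in the Nursing Home program"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: net-cost analysis of a Hospital in the Nursing Home program}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hinhcost)
```

## The evaluation problem

A Hospital in the Nursing Home (HiNH) program places a small team of
ED-based nurses between residential aged care facilities (RACFs) and the
acute hospital system. It aims to avoid transfers that could be managed in
the facility and to shorten the hospital phase of those that do occur. The
economic question is whether the annual cost of running the program is
offset by the savings from reduced emergency department (ED) and inpatient
utilisation. `hinhcost` implements that evaluation as three linked stages —
effect estimation, a deterministic cost ledger, and a Monte Carlo
uncertainty analysis — plus a synthetic data generator that makes the whole
chain verifiable without hospital records.

All costs are Australian dollars per annum at a fixed price year; inputs
are assumed already price-indexed, and no inflation adjustment is applied
inside the package.

## Effect estimation

Utilisation is observed in a 2×2 pre-post controlled design: one
intervention and one control hospital, each with a pre and a post period.
Outcomes are modelled with generalized linear models containing the
hospital main effect `x1`, the period main effect `x2` and the program
indicator `x3`:

* **Rates** (ED presentations, admissions via ED): monthly counts, Poisson
  with log link and a `log(beds/1000)` offset, so `exp(β)` are rate ratios
  per 1,000 RACF beds per month. Rate models carry no patient-level
  covariates — they are fit at month level, where patient attributes do not
  exist as columns; confounder adjustment belongs to the episode-level LOS
  models.
* **Lengths of stay**: episode-level, gamma with log link, adjusted for age
  group, gender, triage category, diagnosis group, and attendance day and
  time. The gamma family matches the strictly positive, strongly
  right-skewed LOS distribution, and the log link keeps predictions
  positive and effects multiplicative. Dispersion is estimated by the
  Pearson method.

With two hospitals and two periods, a separate "program" regressor is
collinear with the design unless it is the interaction; `x3 = x1·x2` is
the only estimable encoding and is what `fit_rate_model()` /
`fit_los_model()` construct.

**Adjusted means** (`adjusted_means()`) use marginal standardization: every
observation is predicted as if it belonged to the target design cell,
holding its covariates at their observed values, and the predictions are
averaged on the response scale over the pooled covariate distribution.
"Adjusted for all other variables" admits several operationalisations;
standardization over the pooled distribution was chosen because it is fully
reproducible from the data and invariant to covariate reference coding
(tested property). Rate-model offsets are neutralized at 1,000 beds so the
means stay on the per-1,000-beds-per-month scale.

**With/without-program contrast** (`intervention_contrast()`): the
counterfactual "without" estimate is the intervention-hospital post-period
adjusted mean with `x3` forced to 0; the "with" estimate has `x3 = 1`;
their difference feeds the cost model. Interval estimates for these
response-scale quantities come from 10,000 multivariate-normal draws of
the coefficient vector (parametric simulation). The delta method was the
alternative; simulation was preferred because log-link predictions are
log-normal in the coefficients and their intervals visibly asymmetric.
The reported p-value is the Wald p-value of `β3`, which is exact for the
contrast because `with = without × exp(β3)`.

`residual_diagnostics()` returns standardized deviance residuals against
fitted values, histogram bins, normal Q–Q pairs and the deviance/df and
Pearson χ²/df ratios. Q–Q theoretical quantiles use average ranks, so tied
residuals share one plotting position. Note one distributional fact used
by the tests: for well-specified gamma data the *Pearson* residuals are
exactly score-centred at zero, while deviance residuals of skewed data sit
slightly left of zero (≈ −0.23 at shape 1), and deviance/df ≈ 1.15 rather
than 1 at shape 1; the test bands reflect this.

## The cost ledger

`net_cost()` evaluates the annual ledger

* `A = A1 + A2`: staffing (program nurses, time in kind) plus non-staff
  running costs (travel, administration/training, stationery, telephone,
  office space, equipment);
* `B = [(e·c + a·g)·k + (f·d + b·h)·l + (e·i)·m]·j·12`, split into avoided
  ED bed-hours (`e·c·k`), shortened ED stays (`a·g·k`), avoided admissions
  (`f·d·l`), shortened inpatient stays (`b·h·l`) and avoided ambulance
  transports (`e·i·m`), each scaled by thousands of catchment beds `j` and
  12 months;
* `C = A + B`; negative values are savings.

Parameter conventions worth noting:

* `j` is *thousands* of RACF beds (2.485 ⇒ 2,485 beds), multiplying
  per-1,000-bed monthly quantities.
* Equipment is annuitized: equivalent annual cost `= price / AF(L, r)`
  with `AF(L, r) = (1 − (1+r)^−L)/r` and `AF = L` at zero rate. Lives below
  one year are clamped to one year: the uncertainty range for the life
  starts at 0, where a literal annuity is undefined, and the clamp makes
  the "bought, used one year, discarded" baseline the worst case. Whether
  the original analysis annuitized or divided price by life is not
  documented; the annuity form is implemented because it is the standard
  equivalent-annual-cost treatment and coincides with price/L at zero rate.
* Amounts are double precision internally; reports round to whole dollars
  only at rendering, with a plain leading minus for savings.

At the packaged baseline configuration the ledger gives `A = 488,116`,
`B = −8,645,886` and `C = −8,157,770` AU$/yr. Recomputing `B` from a
configuration file necessarily uses rounded inputs; analyses that keep
more decimal places in `a–h` will differ from these components by a few
tenths of a percent.

## Probabilistic sensitivity analysis

`run_psa()` draws every uncertain parameter independently from its
assumption (`dist_spec()`), re-evaluates the ledger per trial and
summarizes the 10,000 net costs. Conventions, each a deliberate choice:

* **Counts (`a`, `b`): Poisson at the baseline mean.** A Poisson has no
  free variance, so the tabulated standard errors (which describe the GLM
  estimates) are ignored by this sampler; `count_sampler = "normal"`
  switches to normal(mean, s.e.) for users who prefer the estimator's
  sampling distribution.
* **LOS means (`c`, `d`): gamma by method of moments**, shape
  `(mean/se)²`, scale `se²/mean`.
* **Differences (`e`–`h`): normal, untruncated** — sign flips are real
  scenarios (the program might not save anything), and they produce the
  occasional positive net-cost draw.
* **Unit costs (`k`, `l`, `m`): triangular ±25%**; ambulance share `i`:
  uniform ±25%; equipment life uniform 0–10 years (clamped to ≥ 1 before
  annualization); discount rate uniform 0–0.05.
* **Quantiles**: linear interpolation between order statistics
  (`quantile()` type 7), so the reported 95% interval is exactly
  reproducible; `sd` uses the n−1 denominator.
* Independence between parameters is a documented simplification: `e` is
  statistically coupled to `a` (and `f` to `b`) in reality, and no
  correlation or copula structure is imposed.

`variance_contributions()` attributes output variance by the
spreadsheet-simulation convention: signed `ρ²` shares of the Spearman rank
correlations between each input's draws and the net-cost draws, summing
to 100% over varied inputs; constant inputs contribute 0 by convention.
The convention is a heuristic (it ignores interactions and is not a Sobol
decomposition) but matches how such charts are produced by the common
risk-analysis add-ins. At the packaged assumptions the ranking is: change
in inpatient LOS (`h`, ≈ +45%), change in admission rate (`f`, ≈ +22%),
then baseline inpatient LOS (`d`, ≈ −17%, negative because a longer
counterfactual stay raises the value of each avoided admission).

When the pipeline runs its estimation stage, `update_distribution_specs()`
re-centres the `a`–`h` assumptions on the fitted estimates and recovers
their standard errors from the simulation CI widths, so the PSA varies
around what was actually estimated rather than the file baselines.

## The synthetic data generator

`generator_config()` encodes the emulated study conditions; defaults are
the package's standing choices, fixed once:

| parameter | default | why |
|---|---|---|
| `months_per_period` | 3 | three-month evaluation windows per period |
| `beds_per_catchment` | 2,485 | matches `j = 2.485` thousand beds |
| reference-cell rates | 74.92 / 34.38 per 1,000 beds/mo | control-hospital pre-period adjusted means |
| reference-cell LOS | 4.19 / 86.24 h | same source cell |
| hospital ratios | 0.94, 1.17, 1.37, 1.10 | fitted hospital effects |
| period ratios | 0.90, 1.24, 2.28, 0.85 | fitted period effects |
| program ratios | 0.83, 0.53, 0.53, 0.81 | fitted program effects |
| `los_shape` | 1 | see below |
| covariate mix | 449-episode cohort margins | e.g. 62.6% female, 82.2% ATS 3–5 |

Counts per cell-month are Poisson with mean
`rate × ratios × beds/1000`; each episode then receives independent
covariates, a gamma ED LOS (scale = mean/shape), an admission flag with
per-cell probability `admission rate / presentation rate`, and — if
admitted — a gamma inpatient LOS. Monthly counts are the aggregation of
the same episode draw, so the two views are coherent and admissions can
never exceed presentations. The program ratios enter only the
intervention-hospital post-period cell.

Choices where the design was open:

* **LOS dispersion** is not documented anywhere; shape 1 (coefficient of
  variation 1) was fixed as the default because it reproduces "positive
  and highly right-skewed" LOS while keeping the gamma-GLM recovery
  problem honest.
* **Covariates are sampled independently** of each other and of the
  outcomes by default (only marginal frequencies are available to
  emulate); `covariate_los_effects` is an optional hook that multiplies
  LOS means per covariate level, used by the tests to make adjustment
  non-trivial.
* **Monthly counts are taken as Poisson** with no extra within-cell
  overdispersion, matching the estimation model's assumption; real
  monthly series may be overdispersed, which the generator does not
  emulate.

What passing tests therefore show: the estimation machinery recovers
multiplicative effects from data that obey its own distributional
assumptions, with nominal CI coverage. What they cannot show: robustness
to overdispersion, covariate–outcome confounding beyond the hook,
seasonal structure, or facility-level clustering — none of which the
generator produces.

## Problem sizes and numerical tolerances

The simulation-based checks use sizes chosen to make Monte Carlo error
negligible relative to the tested effect: law-of-large-numbers checks at
roughly 5,000–10,000 episodes with 3-standard-error bands; CI-coverage
checks over 200 replicates of ≈ 5,000 episodes (coverage bound 90% for a
nominal 95% interval, so binomial noise cannot fail a correct
implementation); distribution-sampler moment checks at 10⁵ draws; PSA
summaries at the full 10,000 trials. Exact identities (ledger sums,
exponentiation consistency, offset shifts, seed reproducibility) are
asserted to machine precision or written as `expect_identical`. The
annuity factor is cross-checked against brute-force discounted-payment
summation at 10⁻⁹ relative tolerance.

## Known limitations

* The healthcare-provider perspective only: no RACF bed costs (funded
  independently and unchanged by the program), no societal costs, no
  cost-effectiveness ratio.
* The DiD contrast is associational; with one hospital per arm,
  hospital-level shocks coincident with the program are indistinguishable
  from the program effect.
* PSA parameters are sampled independently (see above).
* The variance-contribution convention is a rank-correlation heuristic,
  not a variance decomposition with interaction terms.
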