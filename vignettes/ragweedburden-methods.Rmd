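---
title: "Methods behind ragweedburden: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind ragweedburden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ragweedburden)
```

This vignette is the package's own account of the science it implements: the
models and their assumptions, the parameters that matter, what the synthetic
generators do and do not emulate, and the choices made where the design was
genuinely open.

## The estimation chain

The package carries four strands to a common endpoint (patients and annual
costs, baseline and under beetle establishment):

1. **Spatial exposure.** Seasonal *Ambrosia* pollen integrals observed at
   monitoring stations are interpolated to a regular 10 × 10 km planar grid;
   sensitisation rates from two kinds of clinical studies are interpolated
   the same way and combined.
2. **Exposure–response.** A community-level panel of reimbursed allergy
   patients and local pollen integrals yields an elasticity via a log–log
   regression through the origin.
3. **Beetle phenology.** A growing-degree-day (GDD) model maps how many
   generations the beetle completes per season, and a generation-dependent
   policy converts voltinism into fractional pollen reduction.
4. **Field impact.** A beetle-exclusion experiment, analysed with an
   allometric raceme estimator and a random-intercept hurdle model, grounds
   the claim that the beetle suppresses pollen production at all.

## Spatial stages

**Interpolation.** Inverse-distance weighting with power 2 over the k = 12
nearest stations, on already-projected planar coordinates (metres); the CRS
string is metadata only. IDW was chosen because it is deterministic,
dependency-free, bounded by the data range, and reproduces the smooth maps
this kind of assessment uses; power and k are arguments, not constants. A
cell whose centre falls on a station (distance < cell/1000) takes the
station value exactly. Cells outside the stations' convex hull are
extrapolated by the same nearest-k rule — a modelling convenience, not a
claim about true pollen fields there. Kriging is deliberately out of scope:
with a few hundred irregular stations, variogram fitting would add estimator
variance without changing any downstream contract.

**Classification.** `natural_breaks()` is an exact Fisher–Jenks dynamic
programme (minimum within-class sum of squares). Ties are broken toward the
smaller left class so results are deterministic; the suite checks the
objective against exhaustive enumeration of all partitions for n ≤ 12.

**Grid conventions.** Row 1 is the northernmost row; the origin is the
top-left corner; nodata is `NA` and propagates through all raster algebra,
while "below exposure threshold" is the value 0 — excluded locations still
count (as zeros) in every aggregation. The plain-text gridded-CSV format
round-trips values, nodata and the grid definition bit-exactly.

**Exposure threshold.** Locations with a seasonal integral strictly below
10 grains/m³ contribute no patients. The strict `<` matters at the boundary:
a cell at exactly 10 is kept. The same threshold is re-applied after the
scenario reduction (a cell pushed below 10 grains/m³ by the beetle drops out
entirely), which is consistent with the baseline exclusion rule;
`reapply_threshold = FALSE` switches this off.

## The exposure–response model

With one averaged point per community (means over 2007–2015; communities
missing years average over the years they have),

$$\ln(\text{patients}_i) = \beta \, \ln(\text{pollen}_i) + \varepsilon_i ,$$

fitted without a constant: zero pollen must imply zero pollen-induced
patients, so the regression is forced through the origin and β is an
elasticity. The closed form is β̂ = Σxy/Σx² on logs, with the usual
no-intercept standard error (n − 1 df) and uncentred R². Pairs with
non-positive pollen or patients are excluded rather than pseudo-counted —
the log model is undefined there and invented offsets would leak into β —
and the exclusion count is reported on the fit object.

Two readings of β are exposed. The first-order reading (a 10 % pollen
decrease ⇒ 10β % fewer patients) is the familiar headline form. For the
large reductions a biocontrol scenario produces, the model's own exact
implication is the power law: patients scale by (1 − r)^β. The scenario
default is the power law, because it is what the fitted model says;
`projection = "first_order"` (floored at zero) is available for comparison.
A caveat the scale-invariance test documents: a no-intercept model is
sensitive to the units of y — rescaling all patient counts shifts β̂ by
Σ(x·ln c)/Σx² rather than leaving it untouched, which is inherent to
through-origin regression, not a defect.

## Health economics

Per-patient annual cost is `round_half_up(median treatment cost × (1 +
work-loss ratio))` — with the packaged reference inputs (median €565 across
the nine-country synthetic cost table; ratio 18.5 %) that is €670. Rounding
is half-up to the whole Euro for this one number only; aggregates stay
unrounded. Country totals are patients × cost × (PPPᵢ / PPP_ref); PPP_ref
defaults to the patient-weighted mean weight, so uniform weights reproduce
patients × cost exactly and rescaling all weights by any common factor
changes nothing. A named reference country can be selected instead. The
work-loss ratio is applied uniformly across countries.

## Beetle phenology and the reduction policy

GDD accumulate by the simple daily-average method, max(0, (tmin + tmax)/2 −
base), with base 13.3 °C — the standard entomological method at daily
resolution, and the accumulation is monotone in every temperature and
additive over windows. One generation requires 288.7 degree-days (egg to
adult emergence, estimated from field cohorts via
`estimate_generation_gdd()`); `generations()` floors the seasonal total by
that requirement, counting only completed generations. The default
accumulation window for voltinism mapping is the growing season (April 1 –
October 31), configurable because the appropriate window depends on the
climate fields used.

The reduction policy maps voltinism to seasonal pollen reduction: ≥ 3
generations → 0.86, 1–2 → 0.30, otherwise 0, applied only inside the joint
beetle × host-plant suitability masks. The 0.86 is the policy value for the
full observed impact in an area where the beetle is long established; the
package also computes the two data-level quantities that sit near it — the
drop in mean daily integrals between pre- and post-arrival periods
(`prepost_mean_drop()`; 46.2 → 7.5 grains/m³ gives 0.8377) and the
level-dependent empirical reduction curve, which is stronger than 0.9 early
in the cumulative season and levels out near 0.837 at the high range. The
curve's reading of "reduction at a cumulative pollen level" is one of
several possible interpretations; it is isolated behind
`empirical_reduction_curve()` so alternatives can be swapped without
touching anything else.

Scenario uncertainty bounds come from rerunning with lower/mean/upper
suitability-mask variants — coverage bounds in the spirit of
ensemble-confidence maps, not sampling confidence intervals.

## The field experiment: allometry and hurdle model

Per plot, total raceme length is estimated as r = n · m · e^{vβ+α} (n
plants, fraction m matured, v the mean log volume of matured plants, (α, β)
the site–treatment OLS of log raceme length on log volume from ~21
independently sampled plants), rescaled to cm of raceme per m². Plots with
no measured volumes borrow the site–treatment mean v; seasons with too few
mature plants for their own allometry borrow the most recent earlier year's
fit; empty plots are zero by construction. Exclusions (no plants at
baseline, grass-dominated blocks) are flags on input rows, not hard-coded
site names.

Because many plots produce no racemes at all, treatment effects are analysed
as a hurdle: a binomial-logit GLMM for raceme presence and a Poisson-log
GLMM for the positive densities, each with treatment fixed and a Gaussian
site random intercept, each tested against its null by a 1-df likelihood
ratio. The positive part rounds densities half-up to integer cm/m² so the
Poisson likelihood is well defined; overdispersion is reported, not
modelled. Fitted treatment values are reported at random effect zero, and
their product is the expected density per treatment; the percent production
reduction is 100(1 − E[control]/E[excluded]), with seasons of complete
control failure contributing 100 %.

The GLMM is fitted in-package: the random intercept is integrated by the
Laplace approximation (damped Newton for each site's conditional mode), and
L-BFGS-B maximises the marginal likelihood over the fixed effects and the
log of the random-effect SD (bounded in [1e-4, 50] — the lower bound is the
fixed-effects limit, where the fit provably coincides with a plain GLM; the
test suite pins this equivalence to 1e-6 and checks the free fit against
`lme4::glmer` on the same data). Complete separation is reported as a
flagged boundary fit rather than an error, because a season in which no
control plot produces racemes is a real outcome, not a failure mode.

A calibration note: the likelihood-ratio test in this design (3 sites, 14
plots per site–treatment, one site without the exclusion treatment) is close
to nominal at the experiment's own production probability (≈ 6 % rejection
at the 5 % level over 500 null replicates in the suite, where the null world
sets both treatments to the control probability), but ML GLMM likelihood
ratios with so few groups can exceed nominal levels at mid-range
probabilities. Inference from designs this small should lean on effect sizes
as much as p-values.

## Synthetic data: what it emulates, what it does not

Every generator is a pure function of a configuration and a master seed
(fixed per-generator offsets, so adding one generator never perturbs
another), and the defaults are the study conditions: 296 pollen stations, 50
overall + 80 conditional sensitisation studies, a 313-community × 9-year
panel with elasticity 0.84 and log-normal noise σ = 0.3, a 3-site × 14-plot
exclusion experiment with hurdle truth {0.26, 0.84, 260, 905}, voltinism
truth {13.3 °C, 288.7 GDD}, the {0.86, 0.30, 0} policy, and pre/post series
targeting 46.2 and 7.5 grains/m³ mean daily integrals. The spatial domain is
a 50 × 50 grid of 10 km cells — large enough for hot-spots, country
structure and threshold crossings, small enough that the full pipeline runs
in seconds.

Choices worth knowing about:

* **Mean-one noise.** Community patient noise is drawn with E[ε] = 1 (log
  mean −σ²/2), and community population is drawn so that log(scale ·
  pop/10⁵) is mean-zero noise independent of pollen. Both are needed for the
  averaging-then-log-fitting chain to stay centred on the true elasticity;
  with naive log-mean-zero noise, averaging in levels would bias β̂ upward
  by a Jensen term.
* **Cohort recording.** Adult emergence is recorded on the day whose
  cumulative GDD is closest to the true requirement, emulating
  visit-rounded field recording; first-crossing recording would bias the
  estimated per-generation GDD upward by about half a day's heat sum.
* **Pre/post series.** Both periods are rescaled to their target means
  after noise, so the configured 46.2 → 7.5 contrast is exact by
  construction; the level-dependent reduction shape (0.90 early, 0.837
  late) survives the rescaling.

What the generators do **not** emulate: real European geography and
coastlines (countries are Voronoi cells of random capitals), meteorological
pollen transport, spatial autocorrelation of sensitisation beyond smooth
trends, overdispersion in plot densities beyond the site intercept, age
structure, or temporal trends in sensitisation. Passing tests therefore
demonstrate that the estimation chain is correct and internally consistent
under its stated assumptions — not that those assumptions hold for any
particular real landscape, and not that the headline figures of any specific
real assessment are reproduced; those depend on restricted clinical and
aerobiological data this package does not ship.

## Problem sizes and numerical tolerances

The test suite runs the oracle-equivalence checks on small exact cases (IDW
vs brute force to 1e-10 on grids up to 10 × 10; Jenks vs exhaustive
enumeration up to n = 12, 4 classes; the no-intercept fit vs its closed form
to 1e-12; Laplace-with-zero-variance vs GLM to 1e-6), recovery experiments
at the study conditions (200 seeded elasticity panels for bias and coverage;
100 hurdle replicates; 500 null replicates for LRT calibration; 50 cohort
ladders), and the full pipeline on the 50 × 50 domain. These sizes were
chosen so every stochastic check has enough replication to be sharp while
the whole suite stays fast enough to run on every change.
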