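---
title: "Pediatric PBPK modelling of tirzepatide: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pediatric PBPK modelling of tirzepatide: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements: the
model structure and its assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the known limitations. It states no empirical result that the test suite
or `scripts/acceptance.R` do not themselves compute.

## Why a PBPK model

Tirzepatide is dosed once weekly by subcutaneous (SC) injection in adults;
no pediatric PK data exist, and recruiting children for PK studies is slow
and ethically constrained. A physiologically based model lets the drug-
specific parameters be fixed on adult data while the system-specific ones
(organ volumes, blood flows, glomerular filtration) are swapped for pediatric
values, so that pediatric exposure — and the dose that matches adult exposure
— can be projected before any trial is run.

## Model structure

The body is a flow-limited organ network: venous plasma → lung → arterial
plasma → eleven parallel tissues (adipose, bone, brain, gut, heart, kidney,
liver, muscle, skin, spleen, and a lumped rest compartment) returning to
venous plasma. Drug is restricted to plasma within blood, so perfusion uses
plasma flows, `Q_organ · (1 − hematocrit)`. The portal circulation is not
resolved (gut, spleen and liver are perfused in parallel): for an SC-dosed
peptide with no oral first pass, the lumping has no observable consequence at
the plasma level.

**Absorption.** A first-order SC depot, `dA_SC/dt = −Ka·A_SC`, initialised
(and incremented at each dose event) by `F · Dose`. Pre-systemic degradation
at the injection site is subsumed in F = 0.81.

**Distribution.** Organ:plasma partition coefficients come from a simplified
tissue-composition equation, `Kp = kp_scale · (f_water + f_lipid · 10^logP)`.
With log P = −6.8 the lipid term is negligible and Kp is essentially a damped
water fraction. The damping factor `kp_scale` (default 0.13) represents the
restricted extravascular access of a 4.8 kDa, 99 %-protein-bound peptide; its
default was anchored so the reference adult's Vss is near 8 L, the value
implied jointly by the labelled Vz/F (≈ 10 L with F = 0.81) and by
CL/F · t½ / ln 2 computed from the published adult PK parameters. This is the
one distribution constant the perfusion-limited structure cannot supply
mechanistically; it is a drug parameter, exposed in `drug_parameters()`, and
the calibration deliberately does not touch it so that clearance and volume
remain separately identified.

**Elimination.** Two linear pathways:

* a hypothetical peptidase expressed at 1 µmol/L in every organ, with
  intrinsic clearance `CLspec · 60 · [peptidase] · V_organ · fu · c_pept`
  (L/h) acting on the plasma-equivalent tissue concentration. The
  dimensionless calibration factor `c_pept` (default 1e-3) absorbs the
  permeability limitation: taken at face value, a ubiquitously expressed
  peptidase with the reported specific clearance would clear a perfusion-
  limited peptide orders of magnitude too fast. One scalar reconciles the
  reported in-vitro constant with the observed total clearance, which is the
  essence of middle-out modelling.
* renal elimination from arterial plasma at an operative clearance
  `cl_renal` (L/h). The published "renal clearance 0.12 1/min" constant has
  an ambiguous normalisation (per millilitre of kidney? of filtrate?), so it
  is stored verbatim but never used by the engine; instead `cl_renal` is set
  so that the urinary fraction of total elimination equals the reported 66 %.
  In a linear system that split is the ratio of effective clearances, so the
  constraint determines `cl_renal` given the peptidase pathway.

**Solution.** Every process is first order, so the model is `dx/dt = A x`
with dose events as depot increments. The default solver diagonalises `A`
once and evaluates the solution exactly on each inter-dose segment;
cumulative elimination integrates in closed form as `C A⁻¹ (x(t) − x(t₀))`.
This preserves mass balance and dose-proportionality to machine precision
and makes population sweeps cheap (a few milliseconds per simulation). A
conventional stiff solver (`lsoda`, rtol 1e-8, atol 1e-10 ng) is retained
behind the same interface and the test suite verifies the two routes agree
to better than 1e-6. The output grid is 0.5 h by default.

## Calibration ("middle-out")

Three parameters are estimated from the adult training data: Ka, the
peptidase factor `c_pept`, and `cl_renal`. The search is a seeded random
search — log-uniform draws of (Ka, c_pept) within bounds; at each draw
`cl_renal` is set by the urinary-fraction constraint (enforced on the
*simulated* split, iterated to within 0.005) — followed by a Nelder-Mead
polish of the best draw. The objective is the unweighted sum of squared log
ratios between simulated and target AUC(0–∞), Cmax and t½ after a single
5 mg dose. Log-scale residuals make the three targets commensurate; the
published work does not state its objective, and equal weights are the
neutral choice. Draws are sequential (one RNG call per draw), so enlarging
`n_samples` under the same seed revisits the same candidate prefix and the
best objective is non-increasing — a property the tests exercise.

Because AUC fixes total clearance and Vss is fixed by the physiology and
`kp_scale`, t½ is nearly determined once AUC is matched; Ka is identified
mainly through Cmax. This weak coupling is why the parameter-recovery
experiment (below) needs summary statistics that are not systematically
biased.

## Physiology and virtual populations

Reference anthropometry (median body weight and height by age and sex),
adult organ volumes, perfusion fractions and tissue composition are bundled
as in-code constants in ICRP/CDC style. They are representative approximate
values, not verbatim copies of any single reference table — the original
population tables behind the published analysis are in supplementary
material that is not publicly archived. Lean organ volumes scale
allometrically with body weight relative to the same-sex adult (exponents
0.85–1.05; brain ≈ 0.05, being nearly mature at age 10); adipose tissue is
the residual so that organ masses sum to body weight; cardiac output scales
as weight^0.75 with fixed perfusion fractions; plasma volume scales linearly.
Absolute GFR is body-surface-area-normalised (120 mL/min/1.73 m², Du Bois
BSA) — renal maturation is adult-like from age 10, so no ontogeny function
is applied. Tissue water fraction is modestly elevated before adulthood
(+8 % at age 10, fading linearly to the adult value at 18).

`build_individual()` is deterministic at the reference medians;
`sample_population()` adds log-normal anthropometry variability (body-weight
CV 10 %, height CV 3.3 %, truncated at 2.5 SD) with ages uniform over the
band and a single integer seed for the whole population. The three pediatric
bands are 10–12, 12–15 and 15–18 years, 50 females and 50 males each at full
scale.

**Obesity.** An obese individual is a normal-weight individual pushed above
the 95th BMI percentile of a bundled LMS-form growth reference (approximate
CDC-style coefficients, within ~0.5 kg/m² of the published curves over
10–18 y). The default target BMI is 115 % of the 95th-percentile curve
(drawn per individual with SD 6 %, truncated so every individual stays above
the threshold). Kidney and liver volumes grow to 115 % — reading the
published "increase of 115 %" as scaling *to* 115 %, consistent with the
modest lean-organ growth reported in obese-pediatric PBPK work — other lean
organs and plasma to 105 %, and the remaining excess weight goes to adipose
tissue, so mass balance is exact by construction. Blood flows rescale with
their organ volumes (raising cardiac output) and absolute GFR scales with
kidney volume. All factors are configurable in `obesity_scaling()`.

## Pediatric extrapolation and dose projection

`extrapolate()` keeps the calibrated drug parameters bit-identical, replaces
the physiology (which rescales peptidase clearance implicitly through organ
volumes), and rescales renal clearance by the GFR ratio with a unit fu ratio
(plasma protein binding is adult-like at 10+). `find_dose_band()` simulates
each individual at each candidate dose — 5, 4.375, 3.75, 3.125 and 2.5 mg,
i.e. 100 % down to 50 % of the adult reference dose — and qualifies a dose
when the population **mean** AUC(0–168 h) and mean Cmax both lie inside the
adult single-dose reference ranges (43459–63467 ng·h/mL and
305.7–488.3 ng/mL). The qualification statistic was a genuinely open design
point (the published analysis presents means ± SD but does not state its
rule); the mean-inside-range default matches that presentation, and a
fraction-of-individuals-inside-range alternative is available
(`statistic = "fraction"`). The recommendation is the contiguous band of
qualifying doses; if only the full adult dose qualifies, no adjustment is
recommended.

With the bundled physiology the projected bands rise monotonically with age
and weight class, healthy children (10–12 y) land at 2.5–3.125 mg, and obese
adolescents qualify at the full 5 mg dose. The obese-adolescent cell is the
one place our constructed obese physiology is less categorical than the
published table (which reports no adjustment outright): in our populations
4.375 mg also qualifies, its mean AUC sitting ~5 % inside the lower reference
bound. That cell is the most sensitive to the unpublished obese-population
scaling factors, and we report our result rather than tune the population
to reproduce it.

## Synthetic trials

`generate_trial()` produces trial-like observed datasets so calibration and
validation are testable without any external data: per-subject parameters
are drawn log-normally around the generating values (default CVs: Ka 25 %,
total clearance 25 %, distribution 20 % — applied to the partition scale so
the urinary split is preserved), observations are the model prediction at a
clinical sampling grid (0–672 h, 13 samples) times multiplicative log-normal
residual error (default 15 %), and the per-subject NCA table is summarised
with arithmetic means, as clinical PK tables are. The generator emulates
between-subject variability, residual assay noise and sparse sampling; it
does not emulate covariate effects, dropout or below-quantification
censoring, so passing tests say nothing about those features of real data.

Two estimator properties matter when using generated tables as calibration
targets. First, arithmetic means of log-normally distributed individual
parameters over-estimate the generating value by roughly `exp(σ²)` (Jensen);
geometric means do not. Second, the per-subject Cmax read off a sparse noisy
grid is the maximum of noisy points and is biased high in proportion to the
residual SD. Both are properties of the NCA summary, not of the calibrator,
so the parameter-recovery experiment in the test suite uses modest residual
error (5 %) and geometric-mean summaries; with those, all three parameters
are recovered within a few percent. The trial-emulation defaults themselves
(15 % residual, 25 % IIV) are unchanged and are exercised by their own
convergence tests.

## Numerical choices and degenerate inputs

* NCA: linear-up/log-down trapezoid; λz from the log-linear regression over
  the suffix of post-Tmax points maximising adjusted r² (≥ 3 points, all
  suffixes evaluated in one vectorised pass); AUC(0–∞) adds `C_last/λz`;
  Tmax is the grid argmax with ties broken to the earliest time. Profiles
  with no identifiable terminal decline raise a typed error rather than
  returning a value.
* A dose regimen may be empty (zero-exposure profile); duplicate or
  non-increasing event times are rejected.
* Mass balance is checked against either the pre- or post-dose bookkeeping
  at an event instant, since the two solver routes report different
  conventions at exactly those times.
* Problem sizes in the test suite are scaled for a routine run: populations
  of 20 per subgroup for the dose-band checks (100 per sex at full scale),
  5000 random-search draws for the recovery experiment, 400-subject trials
  for convergence checks. The full-scale settings are the documented
  defaults.

## Known limitations

* The organ tables, growth curves and BMI-LMS coefficients are approximate
  representative values; absolute organ-level predictions (e.g. kidney
  exposure) should not be over-interpreted. Plasma PK is insensitive to the
  details because calibration pins the observable kinetics.
* Distribution is effectively one-compartment at the plasma level (small,
  uniform-mechanism Kp); multi-phasic distribution kinetics, target-mediated
  disposition and immunogenicity-driven clearance changes are out of scope.
* The peptidase is hypothetical and its calibration factor is not a
  measurable biochemical quantity.
* Obese-population construction follows documented defaults where the
  original supplementary factors are unavailable; the obese-adolescent dose
  cell is sensitive to them (see above).
* The pediatric projections are unverifiable until pediatric PK data exist —
  the same caveat the underlying modelling approach always carries.
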