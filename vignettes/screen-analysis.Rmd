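---
title: "From raw plates to synergy surfaces: the screenfit methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw plates to synergy surfaces: the screenfit methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenfit)
```

screenfit analyses luminescence-based cell-viability screens of the kind run
against panels of patient-derived brain-tumor cell cultures: 384-well plates
read in relative light units (RLU), each carrying DMSO negative-control wells,
staurosporine positive-control wells, and compound wells laid out as
triplicate 10-point threefold dilution series. This vignette explains the
models and the numerical decisions behind each stage, and what the package's
synthetic-data validation does and does not demonstrate about real screens.

## Plate normalization and quality control

Raw RLU values are log2 transformed for single-agent screens (combination
screens are left on the linear scale) and converted per plate to percent
activity against the plate's own controls:

$$\mathrm{activity} = 100 \times
  \frac{\overline{\mathrm{neg}} - x}
       {\overline{\mathrm{neg}} - \overline{\mathrm{pos}}}$$

so 0% is the vehicle level and 100% the cytotoxic-control level. Activities
are deliberately *not* clamped to [0, 100]: overshoot carries information and
the fitting constraints below handle it. On the log2 scale this normalization
is invariant to any global multiplicative rescaling of the raw RLU (reader
gain, cell seeding density), which is the main reason for working on that
scale.

Plate quality is summarized by the z-prime factor,

$$z' = 1 - \frac{3\,\mathrm{sd}(\mathrm{neg}) + 3\,\mathrm{sd}(\mathrm{pos})}
                {|\overline{\mathrm{neg}} - \overline{\mathrm{pos}}|},$$

computed with the sample (n−1) standard deviation on the same transformed
scale used for normalization, so QC and normalization see the same data.
z' is at most 1; plates with coincident control means get an error-flagged
record rather than a number. `qc_filter()` excludes plates below a threshold,
0.5 by default — the classical screening cutoff for a robust assay window.
Whether and how failing plates should be excluded is a policy decision, so
the threshold is exposed rather than hard-coded.

## Dose–response fitting

Replicate (concentration, activity) points for one drug and cell line are
pooled — concatenated, never averaged — and fit with the log-logistic curve

$$f(x) = y_0 + \frac{y_{\mathrm{Fin}} - y_0}
                     {1 + e^{\,h(\ln x - \ln \mathrm{EC}_{50})}}$$

under two parameterizations: a three-parameter model with the zero-dose
baseline $y_0$ fixed at 0, and a four-parameter model with $y_0$ free. The
constraint boxes are: hill slope $h \in [-10, 0]$ (activity may only rise
with dose), $\mathrm{EC}_{50} \in [10^{-11}, 10^{-4}]$ M (roughly the tested
range), the three-parameter plateau $y_{\mathrm{Fin}}$ between 0 and the
maximum of the per-concentration median activities, and the four-parameter
$y_0, y_{\mathrm{Fin}}$ both between the minimum and maximum of those
medians. Medians, not means, anchor the boxes so single wild wells cannot
widen them.

Fitting is bounded least squares (`optim`, L-BFGS-B) from a deterministic
grid of starts: $h \in \{-0.5, -2, -8\}$ crossed with EC50 at the 25th, 50th
and 75th percentiles of the tested concentrations (nine starts). The best
converged start wins; a non-converged minimum is reported only when nothing
converged, and is flagged.

The two models are compared by the corrected Akaike information criterion in
its Gaussian least-squares form with the error variance profiled out,

$$\mathrm{AICc} = n \ln(\mathrm{RSS}/n) + 2k + \frac{2k(k+1)}{n-k-1},$$

and the lower value is selected; near-exact ties (within $10^{-9}$) go to the
simpler model.

**Failure to fit** is defined operationally: either no multi-start converges,
or the selected sigmoid's RSS exceeds 10 times the RSS of a smoothing spline
on the same points *and* the sigmoid's root-mean-square error exceeds 2%
activity. The second clause exists because an interpolating spline can have
an RSS orders of magnitude below an already near-perfect sigmoid; without an
absolute floor, flawless fits on noiseless data would be displaced. On
failure, a cross-validated cubic smoothing spline of activity against log10
concentration (`smooth.spline`) supplies the curve, evaluated flat outside
the observed range so the integration window is always covered; with fewer
than four distinct concentrations the dataset is marked unfit and gets no
AUC.

**AUC** is the trapezoid integral of the accepted curve over
$u = \log_{10} x$ between $10^{-11}$ and $10^{-4}$ M on a uniform 701-point
grid (100 points per decade; refining the grid tenfold moves the value by
less than 0.01%). Units are %-activity × decades: a curve pinned at 100%
across the 7-decade window scores 700. The AUC is reported unnormalized over
exactly this window regardless of the concentrations actually tested, so
values are comparable within a screen; no claim is made that they match any
external portal's scale. The reported EC50 is the fitted inflection
midpoint between $y_0$ and $y_{\mathrm{Fin}}$, even when the plateau stays
below 50% absolute activity — a definitional choice worth remembering when
comparing weak compounds.

## Sensitivity and selectivity profiling

Per-screen AUCs form a drugs × cell-lines matrix. Subtracting each drug's
median AUC across lines (its inherent potency) leaves the *normalized AUC*,
whose per-drug median is identically zero; each line's most selective drug is
the argmax of its column, with lexicographic tie-breaks, flagged.

A line that is more sensitive than the panel to nearly every drug usually
signals an assay artifact rather than biology. Such lines are flagged when
their median normalized AUC exceeds the median of the per-line medians by
more than $k$ scaled MADs ($k = 3$ by default, `stats::mad` with the
Gaussian consistency constant). In validation the false-flag rate is counted
per line (falsely flagged lines over lines tested), the usual false-positive
rate; at the 93 × 16 screen geometry it stays near 1–2%, well under 5%.
With fewer than three lines the rule is statistically meaningless and is
skipped with a warning.

"Most active" compounds for clustering are ranked by per-drug **median** AUC
across lines (mean available as an option), keeping `round(fraction × n)` of
them — 23 of 93 at the default 25%. Their AUC rows are z-scored with the
sample standard deviation and clustered two-ways with correlation distance
(1 − Pearson, pairwise-complete) and average linkage. Distance and linkage
are conventional choices, configurable; determinism is guaranteed by sorting
rows and columns by identifier before clustering. Z-scores are taken on raw
AUC rows by default (a `zscore_on = "normalized"` switch exists, since
median-centered rows differ from raw rows only by a shift that z-scoring
removes anyway — the switch matters only when missingness patterns differ).
Missing entries are excluded from medians, means and correlations, never
imputed.

## Combination response surfaces

Two-drug grids (normalized on the linear scale) are fit with a
kappa-parameterized combined-dose surface. With
$\sigma = \sqrt{n_A n_B}$ and scaled doses
$D_A = (a/\mathrm{EC}_{50,A})^{n_A/\sigma}$,
$D_B = (b/\mathrm{EC}_{50,B})^{n_B/\sigma}$:

$$E(a, b) = E_0 + (E_f - E_0)\,
   \frac{D^{\sigma}}{1 + D^{\sigma}}, \qquad
   D = D_A + D_B + \kappa \sqrt{D_A D_B}.$$

Two properties are the enforced contracts of this form: each zero-dose edge
reduces *exactly* to the corresponding single-agent Hill curve, and at
$\kappa = 0$ with equal slopes the iso-effect contours are the straight
Loewe-additivity lines between single-agent iso-effective doses. $\kappa > 0$
bows the isoboles inward (synergy), $\kappa < 0$ outward (antagonism);
$\kappa$ is constrained to $(-2, 100]$ because $-2$ is the algebraic limit
below which the combined dose can turn negative. The implementation uses a
single shared maximal effect $E_f$; surface variants with distinct per-drug
maxima are out of scope. Fitting is bounded least squares over
$(E_0, E_f - E_0, \log_{10}\mathrm{EC}_{50,A/B}, \ln n_{A/B}, \kappa)$,
initialized from independent Hill fits to the two single-agent edges crossed
with $\kappa \in \{-1, 0, 2\}$. Interaction class is the sign of the fitted
$\kappa$ with a ±0.1 additive dead zone, since a fitted zero is never exact.

Isoboles are traced analytically: at effect level $e$ the combined dose is
$D^* = (p/(1-p))^{1/\sigma}$ with $p = (e - E_0)/(E_f - E_0)$; sweeping drug
A's share from 0 to $D^*$, drug B's share is the positive root of a quadratic
in $\sqrt{D_B}$. For antagonistic surfaces the level set near the drug-A axis
is genuinely non-monotone; the tracer follows the positive-root branch.

The **index of achievable efficacy** asks how much of a capped dose window
reaches a minimal efficacy — by default a 50% effect at concentrations of at
most 1 µM. The surface is evaluated on a 201 × 201 log10-uniform grid
spanning four decades below the cap in each drug; with achieving fraction
$f$,

$$\mathrm{IAE} = \sqrt{\tfrac{1}{1-f}},$$

capped at 1000 when the whole window achieves the threshold. A combination
that never reaches the threshold scores exactly 1, matching the convention
that weakly efficacious combinations sit at the IAE floor. The window's
lower edge (four decades below the cap) is an operational choice: viability
effects at femtomolar doses are not biologically meaningful, and the IAE is
insensitive to extending the window downward because such cells never
achieve the threshold. The definition is symmetric under relabeling the two
drugs.

## What the synthetic screens emulate — and what they do not

The generator reproduces the assay geometry end to end: triplicate 10-point
threefold dilution series from a 35 µM top concentration, packed 35 series
per 384-well plate alongside 16 negative and 16 positive control wells
(columns 23–24); real plate maps vary, and this fixed layout is a documented
default. Ground-truth curves are sampled with log10 EC50 uniform in
[−9, −5.5], hill slope uniform in [−4, −0.5] and plateau uniform in
[30, 110]%, with $y_0 = 0$ except for designated baseline-shift records.
Control RLU means default to 10^6 (negative) and 10^5 (positive), a 10-fold
assay window. Noise is multiplicative log-normal on RLU with a 5% CV —
luminescence noise scales with signal — applied with unit mean. Compound-well
RLU is placed so the plate's own normalization returns the true activity
exactly at zero noise (a geometric interpolation between the control means on
the log2 scale, arithmetic on the linear scale), which gives the pipeline an
exact round-trip test at every stage: activity, EC50, AUC and $\kappa$ are
all recovered to floating tolerance from noiseless screens.

What the generator does **not** model: plate spatial artifacts (edge
evaporation, dispenser drift), well-to-well crosstalk, systematic passage or
batch effects, and any cell-line biology (mutation or methylation subgroups).
Passing the simulation suites therefore demonstrates that the estimators are
correct and well-conditioned under the stated noise model — not that real
plates are free of spatial structure, which would need dedicated corrections
that are deliberately out of scope here.

## Validation problem sizes and numerical tolerances

The packaged tests and the acceptance script use these designs, chosen to
exercise the study-scale geometry while staying quick to run:

* EC50 recovery: 100 triplicate 10-point curves at 5% CV, true EC50 in
  [10^−9, 10^−6] M; the median absolute log10 EC50 error is required to be
  ≤ 0.15 (observed ≈ 0.01).
* Model selection: 100 curves with a true 20% baseline, EC50 in
  [10^−8, 10^−6] M and slopes in [−4, −1] so the baseline is resolved within
  the tested window; the four-parameter model must win ≥ 95 times.
* Fit optimality: on 50 noiseless datasets the constrained optimizer must
  match or beat a 200 × 200 (hill, log10 EC50) grid search with the plateau
  profiled out at each node.
* AUC: trapezoid vs the closed-form logistic integral, 50 random parameter
  sets, within 0.1%.
* Synergy: noiseless $\kappa$ recovery within 0.05 for
  $\kappa \in \{-1, 0, 1, 3\}$; sign classification ≥ 90% correct over 100
  grids at 3% additive noise with $|\kappa| \ge 1$.
* Profiling: outlier power ≥ 95/100 at a +20% pan-sensitive shift and
  line-level false flags ≤ 5% over 200 exchangeable screens, both at the
  93 × 16 geometry.

## Known limitations

* AUC values are internally consistent but on a window-dependent scale; they
  are not numerically comparable to other pipelines without matching the
  integration window and normalization.
* The response surface assumes a shared maximal effect; strongly asymmetric
  maxima will surface as lack of fit rather than a parameter.
* Exposure-time differences between lines (e.g., a fast-growing line assayed
  for 3 rather than 7 days) receive no correction; consumers should carry
  exposure metadata alongside AUCs when comparing across lines.
* The bootstrap confidence interval for $\kappa$ is not implemented; the
  reported `rss` and the sign dead zone are the only uncertainty guards on
  interaction calls.
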