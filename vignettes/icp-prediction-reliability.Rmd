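---
title: "Per-case reliability of predicted intracranial pressure distributions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-case reliability of predicted intracranial pressure distributions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icpdx)
```

## The problem

Non-invasive estimation of intracranial pressure (ICP) from retinal
vascular pulsation imaging produces, for each examined case, not one
predicted value but a whole distribution of them: a gradient-boosting
regression emits one prediction per vascular data point in the image
field, independently for the arterial and the venous tree, so a single
case typically carries several hundred to a few thousand predicted ICP
values per vessel model. A global goodness-of-fit score (RMSE, MAE, $R^2$)
says nothing about whether *this* case's prediction can be trusted.

`icpdx` turns the shape of the per-case predictive distribution into
case-level reliability diagnostics. The central quantity is the definite
integral of the estimated probability density within $\pm 1$ cm water of
the predicted median,

$$\mathrm{DI_{ICP}} = 100 \int_{m-1}^{m+1} \hat f(x)\,dx \qquad
  m = \operatorname{median}(\text{predictions}),$$

in percent. A concentrated, right-skewed predictive distribution puts a
large share of its mass within that window; a distribution that has
degenerated toward uniform over a wide support — the signature of a
prediction no better than random — puts roughly $200/\text{width}$
percent there. The companion error measure is
$\mathrm{Diff_{ICPmd}} = |\mathrm{ICP}_{measured} - m|$, the absolute
difference between lumbar-puncture-measured ICP and the predicted median,
also in cm water.

Around the central statistic the package computes, per case and vessel:
sample moments (sd, skewness, non-excess kurtosis), Lilliefors
Kolmogorov–Smirnov and Anderson–Darling departures from normality,
Shannon entropy of the binned distribution, the two-sample
Kolmogorov–Smirnov concordance between the arterial and venous
distributions of the same case (tsKS), and a Cullen–Frey classification
of the distribution family. At cohort level it links all diagnostics to
$\mathrm{Diff_{ICPmd}}$ through Pearson correlations (discrete variables
integer-coded; a polychoric estimator is available for discrete pairs)
and per-predictor univariate F tests.

## Density estimation and integration

`estimate_pdf()` evaluates the exact Gaussian-kernel estimate (no binned
FFT approximation) on 512 equally spaced points spanning
$[\min - 4h, \max + 4h]$, with the normal-reference bandwidth
$h = 0.9\,\min(\mathrm{sd}, \mathrm{IQR}/1.34)\,n^{-1/5}$
(`stats::bw.nrd0`); the bandwidth is recorded in the returned object for
provenance. The grid extension of 4 bandwidths (rather than the common 3)
bounds the kernel mass truncated outside the grid by
$2\Phi(-4) \approx 6.3\times10^{-5}$ even in the worst case, so the
trapezoidal integral of every estimate over its own grid is 1 to within
$1.2\times10^{-4}$ — the defining normalization property of a density,
and a property the test suite checks on randomized inputs. In practice
the error is far smaller (order $10^{-6}$), because only boundary points
lose tail mass and the Euler–Maclaurin boundary terms nearly cancel.

`definite_integral()` integrates the linear interpolation of the grid by
the trapezoidal rule, clipping the interval to the grid support. Linear
interpolation makes the integral exactly additive over adjacent
subintervals (to floating-point rounding), which the suite asserts at
$10^{-12}$. The mode (`peak_density()`) is the grid abscissa of maximal
density, ties broken toward the smallest abscissa for determinism. The
median entering $\mathrm{DI_{ICP}}$ is always the raw-sample median
(mean-of-middle-two for even $n$), never read off the grid.

Not implemented by choice: adaptive or boundary-corrected kernel
estimators. For bounded-support cases (uniform-like degenerate
predictions) the Gaussian kernel smears mass across the support edges;
this slightly *raises* $\mathrm{DI_{ICP}}$ above the $200/\text{width}$
interior bound and is harmless for the diagnostic ordering the statistic
exists for.

## Moment and normality conventions

Kurtosis is **non-excess** ($m_4/m_2^2$, normal $=3$): the reference
cohort values near 3–8 and the reading "leptokurtic = kurtosis > 3" force
this convention. Skewness and kurtosis use $n$-denominator central
moments, while sd uses $n-1$; the mixed convention is deliberate and
documented here because it is the one the per-case tables were evidently
produced with. Quartiles are type-7 (linear interpolation). Under these
definitions every empirical distribution satisfies the Pearson bound
$\text{kurtosis} \ge 1 + \text{skew}^2$, which doubles as a property test.

The Kolmogorov–Smirnov normality statistic is the Lilliefors form
(normal CDF with mean and sd estimated from the sample), reported
without a p-value: it is used as a graded measure of departure from
normality of the distribution body, not as a test. The Anderson–Darling
statistic uses the standard sum with estimated parameters and **no**
small-sample correction factor, so values are comparable across the very
different per-case $n$ of a cohort (reference values run up to 38 at
$n \approx 2000$). Both are evaluated through the log-tail path of
`pnorm()` so extreme standardized values cannot overflow the logarithm.

## Concordance and entropy

The two-sample KS statistic is the supremum of the ECDF gap over the
pooled sample points, with the location of the maximal gap reported
(smallest achieving abscissa on ties). The asymptotic p-value uses the
Kolmogorov series with the effective size $n_{\mathrm{eff}} = n_1 n_2 /
(n_1+n_2)$ — the product of the two distributions' data-point counts
divided by their sum — and $\lambda = (\sqrt{n_{\mathrm{eff}}} + 0.12 +
0.11/\sqrt{n_{\mathrm{eff}}})\,D$, truncated when terms fall below
$10^{-10}$. No exact small-sample enumeration is provided: per-case
counts here start at 248.

Shannon entropy uses the plug-in estimator on 64 equal-width bins over
the sample range (last bin right-closed), in bits. The discretization is
a genuine free choice — the published per-case entropy values
(5.17–5.85 bits) are consistent with several bin counts — so `n_bins` is
a configuration knob, the default of 64 was fixed once as a power of two
giving a 6-bit ceiling well above the observed range, and the published
per-case entropies are treated as fixture data rather than re-derived.
Miller–Madow or kernel entropy corrections are out of scope.

## Cullen–Frey classification

A Cullen–Frey graph locates a sample by $(s^2, k)$ = (squared skewness,
kurtosis). Reference loci: normal $(0,3)$, uniform $(0,1.8)$, logistic
$(0,4.2)$, exponential $(4,9)$, the gamma line $k = 3 + 1.5 s^2$, the
lognormal curve $\big(s(w)^2, k(w)\big)$ with $s(w)=(e^w+2)\sqrt{e^w-1}$,
$k(w)=e^{4w}+2e^{3w}+3e^{2w}-3$, $w=\sigma^2$; and the beta family, which
occupies the *area* between the impossibility boundary $k = 1 + s^2$ and
the gamma line. Reading such a graph is visual; `classify_distribution()`
formalizes it deterministically: beta-region membership is tested first
(because beta is an area), then the nearest feature by Euclidean distance
wins, with a fixed tie-break priority. Two boundary decisions were open
and are resolved as follows:

* the gamma-line edge of the beta region is **exclusive** — a point
  exactly on $k = 3 + 1.5 s^2$ is gamma, not beta;
* an $s^2 > 0.05$ guard keeps near-symmetric samples out of the beta
  area; without it every uniform sample (locus $(0, 1.8)$, inside the
  region's closure) would be labelled beta. With the guard, the printed
  cautionary-case arterial moments (skew $-0.11$, kurtosis $1.83$; skew
  $0.02$, kurtosis $2.18$) classify as uniform, as published.

Because the exponential point lies exactly on the gamma line, and the
gamma line, lognormal curve and beta boundary all meet near the normal
point, single-sample classifications among those families are inherently
ambiguous; the self-consistency simulations therefore count a
classification as successful when the predicted family's locus passes
within 0.25 of the generating family's locus. Several published per-case
labels (e.g. a lognormal label at a point between the gamma and
lognormal loci) cannot be guaranteed by any pure nearest-locus rule and
are not targeted. No bootstrap cloud is drawn: classification is of the
single observed point.

## Cohort analyses

The published association table is labelled MANOVA, but its printed
values are exactly per-predictor univariate tests on the pooled
case-by-vessel rows: one-way ANOVA F for categorical predictors and
simple-regression F with df $(1, n-2)$ for continuous ones. The package
implements that reconstruction (`univariate_f()`); on the packaged
18-row fixture it reproduces the printed laterality F of 8.5062
(p = 0.01009, df 1, 16) and case-subtype F of 65.217 to printed
precision, and satisfies the internal identity $r^2 = F/(F + n - 2)$
against the numeric-coded laterality correlation of $-0.59$.

Correlations are Pearson on integer-coded variables by default (bilateral
laterality = 2, unilateral = 1, matching the published coding; the
$-0.59$ reproduces only under this treatment). The polychoric option
implements the two-step estimator — thresholds from marginal
proportions, then a 1-D likelihood search for the latent correlation on
$[-0.999, 0.999]$ with bivariate-normal rectangle probabilities computed
through the correlation-integral identity and `stats::integrate`.
Correlation standard errors are reported as the textbook
$\sqrt{(1-r^2)/(n-2)}$; the published $\pm 0.17$-style values at
$n = 18$ match no standard formula and are not targeted, and the same
holds for some published correlation p-values (a two-sided t test gives
$p \approx 0.027$ for $r = -0.5213$ at $n = 18$, not $< 0.004$).

Rank-sum comparisons use Mann–Whitney U with exact enumeration when the
combined sample is at most 12 without ties, otherwise the tie- and
continuity-corrected normal approximation, with Bonferroni correction
$\min(1, m\,p)$. The outlier rule flags a value when it lies more than
2 reference standard deviations from the reference mean.

## The synthetic cohort generator

Raw per-case prediction samples are not public, so the generator defines
the study conditions under which the pipeline is exercised end to end:

* **hold-out-like** cases: both vessels drawn from right-skewed families
  (lognormal, gamma or logistic), per-vessel medians within 3 cm water
  of the measured ICP, sd 5–9 cm water, 248–3617 samples per vessel,
  bilateral-dominant laterality — the regime of the seven
  external-validation cases, giving $\mathrm{DI_{ICP}}$ around 10–18%;
* **cautionary** cases: arterial distribution uniform over a 45–55 cm
  water support with its median displaced at least 15 cm water from a
  low measured ICP (8–12 cm water), venous moderately displaced,
  unilateral — the regime of the two degenerate cases, giving arterial
  $\mathrm{DI_{ICP}}$ below 5% and a uniform Cullen–Frey label.

Family parameters are solved from a target (median, sd): closed forms
for lognormal, uniform, logistic and normal; a monotone 1-D root solve
for the gamma shape; and for the scaled beta an asymmetric support
$[\text{median} - 2.5\,\mathrm{sd},\ \text{median} + 5\,\mathrm{sd}]$
(chosen once so the family is right-skewed like the predictive
distributions it stands in for) with $\alpha, \beta$ solved from the
target mean/sd on the unit interval. Every stochastic operation takes an
explicit seed; identical inputs give identical draws.

What the generator does *not* emulate: the boosting model itself, image
acquisition, raw pulse waveforms or the harmonic-regression fit
(harmonic coefficients are drawn directly from families matching the
published summary signs and dispersions). Passing synthetic tests
therefore demonstrates that the diagnostics separate the two regimes and
recover generating parameters under the stated conditions — not that the
upstream imaging model is accurate.

## Numerical choices, problem sizes, limitations

Degenerate inputs never abort a cohort run: zero-variance samples raise
classed degenerate-input errors at the operation level, constant-sample
entropy returns 0 bits with a warning, predictors with a single level
are skipped from the association table with a warning, and affected
cases are marked in `report.json`. All validation errors carry
`icpdx_*` condition classes.

Simulation-based checks in the test suite use 10–50 seeds with
cohort sizes of 1–4 cases, classification samples of $n = 5000$, and
oracle samples of $n = 10^4$; these sizes were chosen to keep the full
suite around a minute while leaving Monte-Carlo margins well inside the
asserted tolerances. Fixture-based checks (the published aggregates,
correlations and F statistics) are exact recomputations on the packaged
18-row table and run in milliseconds.

Known limitations: per-case density-derived values (mode,
$\mathrm{DI_{ICP}}$, KS, ADS, entropy) are only approximately
reproducible even in principle, because the kernel, bandwidth rule,
integration scheme and entropy discretization behind the published
per-case table are unstated; the packaged fixture carries the published
per-case values verbatim for cohort-level work. The published arterial
data-point total (7,617) disagrees with the per-case column sum (8,623);
the fixture carries the per-case values and the discrepancy is noted in
the reader documentation. The published text and table disagree on the
venous amplitude median/IQR; the fixture follows the table.
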