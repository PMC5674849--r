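---
title: "Growth-rate inhibition metrics: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-rate inhibition metrics: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grscreen)
```

# The model

Endpoint viability screens measure a luminescence surrogate for viable
cell number once, at the end of a fixed treatment window, plus a
time-zero measurement on untreated plates at the moment of drug
addition. Under the assumption that untreated and treated populations
each grow exponentially at constant rates $k(0)$ and $k(c)$, the three
background-corrected counts per condition — the treated endpoint $x(c)$,
the same-plate vehicle control $x_{ctrl}$ and the time-zero count
$x_0$ — determine the rate ratio, and the growth-rate inhibition value

$$\mathrm{GR}(c) \;=\; 2^{\,\log_2(x(c)/x_0)\,/\,\log_2(x_{ctrl}/x_0)} - 1
\;=\; 2^{\,k(c)/k(0)} - 1$$

scores the drug effect *per division*: 1 means no effect, 0 complete
cytostasis (the treated population neither grew nor shrank), negative
values net cell killing, with $-1$ the floor (everything dead). Because
the readout units cancel in the two log-ratios, GR is invariant to the
luminescence gain; because the drug effect is expressed relative to
$k(0)$, it is invariant to the division rate of the line — the property
that makes GR metrics comparable across cell lines where IC50 and Emax
are not.

Per cell line and drug, GR values across the dose series are fitted to

$$\mathrm{GR}(c) = \mathrm{GR}_{inf} +
  \frac{1 - \mathrm{GR}_{inf}}{1 + (c/\mathrm{GEC}_{50})^{h_{GR}}}$$

which is anchored at $\mathrm{GR}(0) = 1$ and decreases toward
$\mathrm{GR}_{inf}$, with half-maximal effect at $\mathrm{GEC}_{50}$.

## Assumptions worth stating

* **Exponential, uniform growth.** Both rates are assumed constant over
  the window. Confluent wells, cell-cycle synchronization, or adaptive
  (drug-tolerant) dynamics violate this; none are modelled.
* **Readout proportional to cell number.** Background-corrected
  luminescence is treated as a linear surrogate for viable cells. The
  additive background is why near-background values are unreliable, and
  why corrected values are clipped at 1.
* **Time-zero transferability.** $x_0$ is measured on separate untreated
  plates; seeding consistency across those plates and the endpoint
  plates is assumed.

# Pipeline stages and their parameters

**Background correction** (`subtractBackground`). The background is the
median of blank (medium-only) wells, by default per plate; the median is
robust to a single aberrant blank, and per-plate estimation is the
conservative choice when plates may differ (a single scalar or named
per-plate vector can be supplied instead). Corrected values below 1 are
set to 1 and flagged; this floor both removes negative artifacts and
guarantees the log-ratios are defined.

**Robust averaging** (`robustMean`, `summarizeConditions`). Technical
replicates are summarized by the mean of the values whose distance in
log10 from the log10 of the plain mean is strictly below a threshold:
1.0 (a tenfold deviation) for treated triplicates, 1.5 for the more
numerous vehicle controls. The filter is a single pass against the
full-vector mean, not an iterative trim — that is the definition, and
iterating it would change the estimator. If the filter rejects every
value (possible when the mean falls log-far from all points), the plain
mean is returned with a warning rather than an undefined value. Vehicle
controls are always taken from the same plate as the treated wells;
time-zero wells are pooled per cell line and biological replicate and
summarized by their median.

**GR computation** (`computeGRTable`). Besides GR and the relative cell
count $x(c)/x_{ctrl}$, each record carries the control division count
$\log_2(x_{ctrl}/x_0)$ and the nominal division time (assay duration /
divisions, hours). Degenerate conditions are flagged, not dropped:
`undefined_growth` when $x_{ctrl} = x_0$ (the GR exponent divides by
zero) and `shrinking_control` when $x_{ctrl} < x_0$ (GR computable but
biologically meaningless). The QC layer, not the math layer, owns
exclusion, so that exclusions can be counted and reported.

**QC filters** (`filterLowGrowth`). Two rules, applied in order, both
strict inequalities: exclude conditions whose control underwent fewer
than 0.3 divisions (a 23% increase in cell number — barely growing
controls make the GR denominator tiny and the value wildly noisy), then
conditions with division time above 80 h (0.9 divisions over a 72 h
assay — empirically, replicate SEM of GR rises steeply below ~0.9
divisions). Exclusions are attributed to the first rule that fires, so
counts always partition the input. `semVsCutoffSweep` reproduces the
quality-vs-cutoff analysis on any table: SEM percentiles (50/75/90/95/99)
of GR across biological replicates as the division cutoff rises, plus
per-replicate fit $r^2$ and log10 GEC50/GR50 SEM percentiles on request.
GR50 SEMs are computed on log10 values across per-replicate fits with
infinite values excluded, since GR50 uncertainty is naturally an
order-of-magnitude quantity.

**Fitting** (`fitGRCurve`). Bounded least squares with box constraints
$\mathrm{GR}_{inf} \in [-1, 1]$ (GR values are bounded there for growing
controls), $h_{GR} \in [0.1, 5]$, and $\mathrm{GEC}_{50}$ within two
orders of magnitude of the tested concentration range, optimized in
log10 concentration since doses span ~5 decades. The optimizer is
multi-start L-BFGS-B on the residual sum of squares: deterministic
starts place GEC50 at the geometric mean of the range, at the dose where
GR crosses midway between 1 and its observed floor, and at the range
endpoints, with $h_{GR} = 2$ and $\mathrm{GR}_{inf}$ at the lowest
observed GR; four additional jittered starts use a fixed, configurable
seed. The finite-difference step is shrunk to $10^{-7}$ because the SSE
surface is nearly flat in log10(GEC50) when the curve midpoint sits at
the edge of the tested range, and the default step stalls short of the
minimum. On noiseless nine-dose data the generating parameters are
recovered to better than $10^{-7}$ relative error across a
$3\times3\times3$ grid spanning the box.

**Flat-fit fallback.** The sigmoid (3 parameters) is compared with the
constant model at the mean GR (1 parameter) by an F-test; below
significance $\alpha = 0.05$ the sigmoid is reported, otherwise the fit
is classed flat with $\mathrm{GR}_{inf}$ at the mean GR and GEC50/hGR
undefined. Whether the original analyses used this gate unconditionally
is not documented for every dataset, so the test can be disabled
(`flatTest = FALSE`), in which case the sigmoid is always reported.
Zero-variance input short-circuits to a flat fit (there is nothing to
test). Residuals are unweighted: technical-replicate variances are not
propagated into the fit.

**Metrics** (`extractGRMetrics`). GR50 comes from the closed-form
inversion $\mathrm{GEC}_{50}\,(0.5/(0.5 - \mathrm{GR}_{inf}))^{1/h_{GR}}$
with two censoring rules: $+\infty$ when $\mathrm{GR}_{inf} > 0.5$ (the
curve never reaches 0.5) and $+\infty$ when the solved value exceeds
$10^{0.5} \approx 3.16$-fold the top tested dose (extrapolation
artifact). Values between the top dose and 3.16-fold above it are kept:
only the half-decade buffer is censored. Flat fits below 0.5 report GR50
as $-\infty$ — a "below tested range" sentinel that sorts ahead of every
finite concentration and preserves potency ranking without fabricating a
number. GRmax is the measured (replicate-averaged) GR at the top dose,
clamped to $[-1, 1]$ with a flag, and is only comparable across records
sharing a top dose (flagged via `range_differs`). GRAOC is the
trapezoidal integral of $1 - \mathrm{GR}$ over log10 concentration,
normalized per log10 unit so that 0 means no effect and GR $\equiv 0$
gives exactly 1; the per-log-unit normalization is the convention that
realizes those anchors and makes the value dilution-spacing invariant.
GRAOC integrates the measured values rather than the fitted curve, so it
survives fit failures. The 100 μM display cap sometimes applied to GR50
in plots is a visualization convention and is never applied to stored
values.

**Aggregation** (`aggregateMetrics`). Median and quartiles per metric
per perturbagen or drug class, with type-7 (linear interpolation)
quantiles — the unstated convention is resolved to R's default and
documented here for reproducibility. GR50 and GEC50 are summarized in
log10 space and reported back in μM; infinite GR50 values ride along
under rank semantics ($+\infty$ sorts last), because dropping resistant
lines would bias group medians toward sensitivity. Response quadrants
(`classifyResponse`) split potency at GR50 ≤ 1 μM (the boundary counts
as potent) and efficacy at the sign of GRmax.

# The simulator

`simulatePlates` emulates the real assay layout: one endpoint plate and
one time-zero plate per cell line and biological replicate; nine-dose
1:5 dilution series (default top 100 μM, the middle of the realistic
33–167 μM screening range); 72 h treatment; technical triplicates;
biological duplicates; six vehicle-control and six time-zero wells and
four blanks per plate; additive background of 100 luminescence units
(realistic backgrounds run 35–250); seeding density 1000 cells/well and
unit gain (immaterial to GR, which is unit-invariant). Untreated cells
double every `doubling_time_h` hours; drug rescales the growth rate by
$\log_2(\mathrm{GR}_{true}(c) + 1)$, the exact inversion of the GR
definition, so with zero noise the pipeline recovers the true GR to
machine precision — a round-trip identity the tests rely on. Readout
noise is multiplicative log-normal (mean-preserving, default CV 5%, the
typical well-to-well reproducibility of luminescence endpoints) applied
to every well including blanks, on top of the fixed additive background;
this reproduces the empirical pattern that GR values from slow-growing
cultures are noisier, because fixed noise looms larger when the three
counts are close together. Seeding is deterministic: per-plate streams
are derived from the master seed.

What the simulator does **not** model: plate-geometry (edge) effects,
evaporation, pipetting error, cell-cycle synchronization, adaptive
resistance, non-linearity of the luminescence readout, or
between-replicate seeding drift. Passing tests therefore demonstrate
correctness of the computation and robustness to multiplicative readout
noise — not robustness to every failure mode of real plates, which is
precisely what the QC filters exist to catch empirically.

`traditionalMetrics` fits the same bounded sigmoid to relative cell
counts (asymptote constrained to $[0, 1]$, since relative counts are
non-negative and equal 1 at zero dose) and inverts for IC50. Simulating
one true GR curve at doubling times of 18/36/60 h shows GR50 agreeing to
numerical precision across lines while IC50 spreads by half a decade —
the confounding the framework removes, made testable.

# Numerical and edge-case decisions

* Strict thresholds everywhere the rules are phrased strictly ("fewer
  than 0.3", "greater than 80 h", robust-mean `<`): boundary records are
  retained. All thresholds are configurable.
* $x_{ctrl} = x_0$ is an error in the scalar `grValue` but a flagged
  record in the table path, so QC can count it.
* Empty retained sets propagate as empty tables with flags, not errors;
  the pipeline reports "nothing survived QC" and skips aggregation.
* SEM is the sample standard deviation over $\sqrt{n}$, undefined (and
  flagged) for $n = 1$, exactly 0 for identical replicates.
* Time-zero wells are pooled across a cell line / biological replicate's
  time-zero plates before taking the median; per-plate time-zero
  medians were the alternative, but time-zero plates are untreated and
  share seeding, so pooling uses more wells with no bias in exchange.
* Background can be estimated per plate (default) or supplied per batch
  as a scalar — both policies exist because either could have been used
  upstream; per-plate is the default as the more conservative choice.

# Problem sizes in the test suite

The suite exercises the pipeline at desk scale, chosen to keep the
Monte-Carlo components statistically meaningful while the whole suite
runs in well under a minute: 200-case property loops for the robust mean
and GR identities, a $3\times3\times3$ noiseless recovery grid, 1000
random fits for the GR50 closed-form/root-finding agreement, 100
simulated datasets for GEC50 recovery at 5% noise, and simulated screens
of two to three cell lines by one to two drugs for end-to-end checks.
The acceptance script re-runs the same computations from the installed
package and writes the resulting quantities as JSON.

# Known limitations

* Endpoint-plus-time-zero only: no multi-timepoint growth-rate
  estimation, and therefore no detection of within-window rate changes.
* No biphasic or two-site dose-response models; strongly non-sigmoid
  data will be classed flat or fit poorly (visible in $r^2$).
* No plate-effect or batch correction, and no imputation of excluded
  conditions.
* GRmax/GRAOC comparability across records requires matching dose
  ranges; the package flags but does not harmonize mismatched ranges.
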