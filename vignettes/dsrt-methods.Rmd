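---
title: "Methods: dual-readout drug sensitivity scoring and synergy analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-readout drug sensitivity scoring and synergy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsrt)
```

# The problem and the model

High-throughput drug sensitivity and resistance testing (DSRT) screens a
panel of cancer cell lines against hundreds of compounds, each at several
concentrations, on 384-well plates. Most such screens are read out with a
single cell-viability assay (metabolic activity or ATP content). That
readout confounds two very different biologies: a compound can *arrest*
growth and metabolism (cytostatic) or actually *kill* cells (cytotoxic).
This package analyzes screens that pair viability channels with a
cell-death (cytotoxicity) channel, so the two can be separated per cell
line and compound — in single-agent scores, in response classification, and
in combination-matrix synergy maps.

## Normalization and plate QC

Each plate carries negative controls (vehicle, 0.1% DMSO) and positive
controls (100 µM benzethonium chloride, fully lethal). Per plate and per
readout, raw signals are mapped to a percent scale anchored at the control
means: percent inhibition $= 100\,(\mu_{neg} - y)/(\mu_{neg} - \mu_{pos})$
for viability channels (signal falls as cells die) and percent toxicity
$= 100\,(y - \mu_{neg})/(\mu_{pos} - \mu_{neg})$ for the death channel
(signal rises as cells die). Both are affine in the raw signal, so any
per-plate gain or offset cancels. Values are deliberately *not* clipped at
this stage — clipping belongs to the fitting step, where it is a documented
numerical choice rather than silent data editing.

Plate quality is the Z'-factor,
$Z' = 1 - 3(\sigma_{pos} + \sigma_{neg})/|\mu_{pos} - \mu_{neg}|$, computed
from the raw control signals with sample standard deviations (which is why
the normalization anchors default to means; a median variant exists for
outlier-ridden plates but then the anchors and the QC statistic are no
longer the same summary). Flags follow the standard screening convention:
pass at $Z' \ge 0.5$, warn in $[0, 0.5)$, fail below 0. Plates missing a
control group are excluded and reported, never silently imputed.

## Dose–response model

Responses are fitted per cell line × compound × readout with a logistic
curve in log10 concentration,
$$y(x) = \frac{d}{1 + 10^{\,s(c - x)}},$$
with top asymptote $d \in [0, 100]$, log10 EC50 $c$ bounded one decade
beyond the tested range, and Hill slope $s \in [0.1, 10]$. The bottom is
fixed at 0 because the percent scale already anchors "no effect" at 0;
mildly negative or overshooting observations are measurement noise and are
clipped to $[-20, 120]$ before fitting. The slope is constrained positive:
inhibition and toxicity increase with dose, and biphasic curves are out of
scope. Fitting is bounded least squares with an analytic gradient,
multi-started from a fixed grid ($c$ at every tested dose, $s \in \{0.5, 1,
2\}$), with RSS ties broken by smallest slope then smallest $c$ — there is
no randomness in fitting, so identical data give bit-identical fits.

Degenerate inputs short-circuit deterministically: if no observation
exceeds the 10% activity threshold the compound is inactive and gets a flat
zero fit without optimization (this avoids manufacturing EC50s for
inactives, the dominant case in a 301-compound library); all-saturated
data get a flat-max fit; fewer than three distinct doses get a flagged flat
fit at the mean.

## DSS: area under the curve above threshold

The drug sensitivity score integrates the fitted curve above an activity
threshold $t$ (default 10%) over the tested log-concentration range
$[x_1, x_2]$ only — effects are never extrapolated beyond tested doses.
With $x_1' = \max\!\big(x_1,\; c - \tfrac{1}{s}\log_{10}(d/t - 1)\big)$ the
threshold crossing, the area has the closed form
$$I = \frac{d}{s \ln 10}\Big[\ln\big(1 + 10^{s(x - c)}\big)\Big]_{x_1'}^{x_2},
\qquad
\mathrm{DSS}_1 = 100\,\frac{I - t\,(x_2 - x_1')}{(100 - t)(x_2 - x_1)} .$$
`closed_form_vs_numeric()` recomputes $I$ by adaptive quadrature and is the
package's own oracle: the test suite certifies agreement to $10^{-6}$ over
1,000 random parameter draws. DSS is 0 exactly when $d \le t$, 100 for a
saturated curve with EC50 far below the range, increases in $d$ and
decreases in $c$. Only the DSS1 normalization is implemented; DSS2/DSS3
variant names are accepted by `dss_config()` but error on use, because
their exact normalization terms trace to a different publication chain and
silently guessing them would contaminate every downstream score.

Selective DSS is `sDSS = DSS − panel mean` for the same compound and
readout, with the panel mean taken over a reference cell-line collection
(`build_control_panel()`; the emulated design used 150 reference lines for
viability and 30 for toxicity readouts). Summed over the panel's own
members, sDSS is identically zero — a self-consistency check in the tests.

## Classification: cytostatic vs cytotoxic

Classification is joint over readouts, in DSS units: cytotoxic if the
toxicity-channel DSS is at least $T_{tox} = 5$; otherwise cytostatic if a
viability-channel DSS is at least $T_{viab} = 10$; otherwise inactive. The
source workflow states no numeric thresholds; these defaults make the
"strong viability response, low-to-no cytotoxicity" quadrant representable
and are validated against planted synthetic truth rather than against any
published table. $T_{viab}$ reuses the DSS activity threshold; $T_{tox}$ is
lower because the death channel saturates less and genuine kill signals are
rarer. Both are arguments, not constants.

## Combination matrices: Bliss and ZIP

An 8×8 matrix combines 7 nonzero doses of each drug plus a zero dose, so
the first row/column are monotherapies. Per readout, the Bliss score of an
inner cell is $100\,(f_{AB} - (f_A + f_B - f_A f_B))$ with observed effect
fractions clipped to $[0,1]$ first; the summary is the unweighted mean over
the 7×7 inner cells (no "most synergistic window" sub-score — the workflow
this emulates reports whole-matrix maps). The ZIP delta replaces raw wells
with curve-smoothed values: monotherapy curves are fitted, then each row
(and column) is refitted with the bottom pinned at the other drug's fitted
monotherapy effect at that dose, the two directional fits are averaged, and
the same Bliss-style excess is taken on the fitted values. A conditional
fit that fails falls back to observed values for that slice and is flagged.
Scoring each readout independently is the analytical point: the same drug
pair can be additive in viability yet strongly antagonistic in
cytotoxicity, and only per-readout scores expose that.

Sign convention, both models: positive = synergy, negative = antagonism,
in percentage points.

## Clustering and biomarker association

Response-profile matrices (default: sDSS) are clustered with complete
linkage: compounds with Spearman distance $1 - \rho$ (average-rank ties;
invariant to monotone transforms of a profile; zero-variance profiles get
the maximal distance 2 with a warning rather than NaN), cell lines with
Euclidean distance — the Cluster 3.0 / Java TreeView pairing, and the
package writes and re-reads TreeView's CDT/GTR/ATR files losslessly (the
tree files store similarity $1 - h$ at full precision).

Responder groups are defined per cell line by the mean toxicity DSS over a
drug class, thresholded (the threshold is a parameter; no published value
exists). Protein markers are compared between groups with a two-sample
t-test — Welch by default, because equal variances across responder groups
is an assumption nothing here licenses; the pooled test is a flag away.
Significance is reported at raw $p \le 0.05$ to match the emulated
workflow's reporting, with Benjamini–Hochberg adjustment available but off
by default (a deliberate mirror of that workflow, not a statistical
recommendation).

# The synthetic world

The generator is first-class, tested code: it is how every end-to-end claim
in this package is validated, so its defaults are a *stated world*, chosen
once from the emulated design and not tuned to test outcomes.

* **Design**: ~16 cell lines × ~301 compounds, 5 concentrations in 10-fold
  dilutions (a 10,000-fold range), 384-well plates with 16 negative and 8
  positive control wells (the counts are this package's choice of common
  384-well practice), three readout channels. Single wells per
  concentration — the usual DSRT economy — with replicates representable by
  concatenating simulations.
* **Raw scale**: negative-control mean 10,000 units, positive-control mean
  200 for viability channels, reversed for the toxicity channel. Arbitrary
  but fixed, so fixtures are stable.
* **Responses**: per cell line × compound, one viability and one toxicity
  logistic truth. Archetypes encode the central phenomenon: *cytostatic*
  (viability top 65–100%, toxicity top ≤ 8%, i.e. below the activity
  threshold), *cytotoxic* (toxicity top 60–100%, viability at least as
  strong — dead cells do not metabolize), *inactive* (both ≤ 8%). Active
  log-EC50s are drawn from a truncated normal (sd 0.5) centered in the
  tested range, emulating dose ranges "centered on the relevant activity
  concentration". PI3K/mTOR-, HSP90-, NAMPT- and antimetabolite-class
  compounds are cytostatic everywhere; CDK, anti-mitotic, proteasome,
  topoisomerase and HDAC classes are cytotoxic only in a sensitive subset
  of lines (default a third of the panel); other kinase inhibitors respond
  sporadically (20% cytostatic / 10% cytotoxic per line).
* **Noise**: multiplicative log-normal with mean 1 and CV `cv_mult`
  (default 5%), optional additive background, optional linear row/column
  gradient (off by default). With zero noise the pipeline recovers planted
  effects to numerical precision — the round-trip invariant.
* **Combinations**: inner cells are the Bliss expectation of the planted
  monotherapies plus a planted `interaction_delta`, clipped to [0, 100].
  Exact mean recovery of a planted delta therefore holds only where
  clipping never engages; planted *negative* deltas are partially absorbed
  at low-dose corners where the expectation is already near 0, so
  antagonism recovery is asserted on sign, not magnitude.
* **Anchored screens**: anchor antagonism is planted at the parameter
  level — targeted chemo-class compounds get a strong toxicity truth (top
  75–100%, central EC50, slope 1–2.5) and the anchor scales the top by 0.4
  and shifts log-EC50 by +0.3. Parameter-level planting keeps with-anchor
  responses exactly logistic, so at zero noise the fitted ΔDSS is the true
  ΔDSS and the planted band guarantees every targeted compound exceeds the
  |ΔDSS| > 10 flagging rule with margin. (A naive pointwise "−20 points"
  plant fails both properties: the shifted curve leaves the logistic family
  and weak compounds cannot lose 10 DSS units they do not have.)
* **Markers**: 70 standard-normal markers across the panel; informative
  markers get a mean shift of `effect_size` (default 3 SD) in the sensitive
  group — the planted effect the t-test power criterion is measured
  against.

What a green test does *not* establish: the generator draws independent
Gaussian/log-normal noise per well; real screens have spatially correlated
artifacts, batch effects between plates and runs, compound degradation, and
heteroscedasticity beyond the multiplicative model. The archetype taxonomy
is a three-class idealization of a continuum. Recovery rates measured here
are upper bounds on real-data performance, not estimates of it.

# Numerical choices and edge cases

* Percent responses clipped to $[-20, 120]$ pre-fit; fit bounds $d \in
  [0, 100]$, $s \in [0.1, 10]$, $c \in [x_{min}-1, x_{max}+1]$.
* Replicates at identical doses are averaged before fitting (equivalent to
  an equally-weighted fit under homoscedastic noise; tested).
* ZIP conditional fits reuse the bounded fitter with the bottom pinned and
  a reduced start grid (quartile $c$ starts × $s \in \{0.5,1,2\}$) because
  they run 14 times per matrix; the monotherapy fits keep the full grid.
* Combination fractions are clipped to $[0,1]$ *before* any Bliss
  expectation; deltas are reported ×100 in percentage points.
* Zero-variance profiles in Spearman clustering: distance fixed at 2.0
  (the anti-correlation maximum) with a warning, not NA.
* Degenerate controls (equal means) raise errors in normalization and
  return $-\infty$ from `z_prime()` — a plate that broken should fail
  loudly.
* t-tests with zero variance in both groups return $t=0, p=1$ when means
  agree (stats::t.test errors instead; identical marker rows are legal in
  simulated null tables).

# Known limitations

* DSS2/DSS3 normalizations are not implemented (see above).
* Loewe additivity and HSA synergy models, three-drug combinations, and
  order-of-addition effects are out of scope.
* The CLI reads JSON configuration, not YAML (no YAML parser among the
  package's dependencies).
* Growth-kinetics experiments (washout reversibility, live-cell imaging)
  and external mutation-database association are not modeled.
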