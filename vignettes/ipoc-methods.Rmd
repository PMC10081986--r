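---
title: "Methods: tracing sea-ice carbon with HBI biomarkers"
author: "ipoctrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracing sea-ice carbon with HBI biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipoctrace)
```

## The measurement model

Three C25 highly branched isoprenoid (HBI) lipids are quantified per
individual as response-normalized GC-MS selected-ion-monitoring peak
areas: IP25 (m/z 350.3) and HBI II (m/z 348.3), made by sea-ice diatoms,
and HBI III (m/z 346.3), made by pelagic phytoplankton. Because only the
ratio of the three carries source information, the units cancel in the
H-Print index,

$$\mathrm{H\text{-}Print}\,(\%) = 100 \cdot
  \frac{\mathrm{HBI\,III}}{\mathrm{IP_{25}} + \mathrm{HBI\,II} + \mathrm{HBI\,III}},$$

and `compute_hprint()` is invariant under any positive rescaling of all
three intensities. When the denominator is zero the index is undefined:
such a sample has no measurable HBIs and carries no source information,
so it is excluded (with its id logged), never imputed.

A linear calibration from a controlled feeding experiment converts
H-Print to the estimated sea-ice fraction of marine-origin carbon
(iPOC, %):

$$\mathrm{iPOC} = 101.08 - 1.02 \cdot \mathrm{H\text{-}Print},
  \qquad R^2 = 0.97,\; df = 23.$$

The calibration object is data, not a constant: alternative intercepts
and slopes can be injected anywhere a calibration is accepted.

**Clamping.** The line predicts 101.08 % at H-Print 0 and −0.92 % at
H-Print 100, so reported iPOC is clamped to [0, 100]; the raw prediction
is retained in a separate column, and `clamp = FALSE` recovers the bare
line. Whether out-of-range calibrated values should be truncated is a
genuinely open convention; clamping matches how iPOC is interpreted (a
carbon percentage on a 0–100 axis) while keeping the unclamped value
auditable.

**Classification.** Source classes are decided from the intensity
pattern, not from an iPOC threshold: all three intensities zero means
`excluded_no_hbis`; both sea-ice HBIs zero with HBI III present means
`pelagic_only`; any sea-ice HBI present means `both_sources`. The three
classes are exhaustive and mutually exclusive over all zero/nonzero
patterns (the tests brute-force all eight). No detection-limit threshold
beyond exact zero is applied in the pipeline; instrument-level dropouts
are the synthetic generator's job and upstream QC's.

## Input validation

Source datasets are heterogeneous legacy tables, so the reader maps
file headers to canonical fields through a YAML config and validates
every row against controlled vocabularies (four habitats, six taxon
groups, four benthic feeding strategies). Validation is total: each row
becomes either a sample or an error record, never a silent drop. A
missing month is an explicit `NA` — a representable "unknown", distinct
from any calendar month — because month-less samples must survive to the
monthly-summary stage, which excludes and counts them. Latitude
[55, 82] and year [1982, 2019] are the survey's observed ranges, not
format rules, so breaches warn rather than reject.

## Ecological summaries

Species- and month-binned summaries use type-7 (linear-interpolation)
quartiles. The box-plot whisker convention is configurable because the
two common conventions disagree: the default is Tukey (whiskers to the
most extreme values within 1.5 IQR of the quartiles, points beyond are
outliers), with `whiskers = "minmax"` as an override (whiskers at the
extremes, no outliers). The 50 % iPOC exceedance — a stronger sea-ice
than phytoplankton signature — is strict (`>`), so a sample exactly at
the threshold does not count.

## Regression, AIC, and encodings

`fit_ols()` is written from first principles: QR decomposition of the
design matrix, standard errors from the unscaled covariance via the R
factor, two-sided t tests on the residual degrees of freedom, and the
full Gaussian log-likelihood (constants included) so that
AIC = 2k − 2·logLik, with k counting the error variance, is directly
comparable to standard statistical software. The test suite checks it
against a naive normal-equations oracle and against `lm()`/`AIC()`.
Rank deficiency is an error that names the collinear columns rather
than a silent coefficient drop.

Two encoding choices deserve explanation:

* **Month** enters as a numeric 1–12 covariate by default. A single
  reported t-value for "month" (and for "month × habitat") implies a
  one-column coding; a sine/cosine circular coding is available as an
  option but is not the default.
* **Habitat** has four levels yet is conventionally reported with a
  single t-value, which again implies a one-column coding. The default
  is an ordered score (pelagic = 1, sympagic = 2, mixed = 3,
  benthic = 4), reflecting increasing access to sea-ice carbon through
  benthic storage of ice-algal falls. This is an interpretive choice:
  treatment contrasts (`habitat_coding = "contrast"`) are available and
  then per-level coefficients are reported. Results that depend on the
  habitat coding should be read with that ambiguity in mind.

Model comparison requires all candidates to be fitted on the identical
response vector (month-less samples are removed once, before any model
is fit) and ranks by AIC, breaking exact ties by parsimony and then
formula label.

## Sensitivity to omitted confounders

For a treatment column with t-statistic $t$ and residual degrees of
freedom $df$, the partial R² with the outcome is $t^2/(t^2+df)$. With
the partial Cohen's f, $f = |t|/\sqrt{df}$ and $f_q = q\,f$, the
robustness value — the minimal partial R², shared with both treatment
and outcome, that an unobserved confounder needs to reduce the estimate
by the proportion $q$ — has the closed form

$$RV_q = \tfrac{1}{2}\left(\sqrt{f_q^4 + 4 f_q^2} - f_q^2\right).$$

For a significance target, the adjusted statistic must only fall to the
α-critical t on $df-1$ degrees of freedom:
$f_{q,\alpha} = f_q - |t^*_{\alpha,df-1}|/\sqrt{df-1}$, floored at zero,
with the same closed form applied to $f_{q,\alpha}$, and an extreme-case
correction $RV = (f_q^2 - f^{*2})/(1+f_q^2)$ when
$f_{q,\alpha} > 1/f^*$. The correction matters: in that regime the
worst-case confounder is *not* equally associated with treatment and
outcome — for fixed association with the treatment, the
outcome-association that minimizes the adjusted t has a closed-form
interior optimum, and the tests verify both branches against a numeric
oracle that performs that minimization explicitly.

The three-month-shift check refits a month-bearing model after moving
every observation three months earlier with modular wraparound
(January − 3 = October) and reports both fits and both sensitivity
analyses side by side. Under month-balanced sampling with pulse-like
seasonality the habitat conclusion (sign and significance) survives the
shift. Note that under a *linear* month × habitat generating structure
the wraparound provably redistributes the habitat main effect (the
sawtooth remapping of month interacts with the linear term), so shift
stability is a statement about seasonal-pulse structure, not an
identity.

## Sediment inventory

Per layer, the sediment H-Print (from intensities, or measured
directly) converts through the same calibration to an ice fraction
(clamped to [0, 1]), and multiplies total organic carbon to give
**theoretical-maximum** iPOC per gram of dry sediment. "Theoretical
maximum" is implemented literally — no degradation, mixing, or
burial-efficiency discount — because that is what the quantity means;
real shelves have rapid bioturbation that buries part of this pool.
The age model is linear, `age(d) = sampling_year − d / rate`, with no
compaction correction; the default rate of 1 mm/yr is typical of the
Amundsen Gulf shelf. The accessible inventory reports the min/max
per-layer concentration over layers intersecting the bioturbation
horizon (default 70 mm); a partially overlapping layer counts whole,
which is conservative for a maximum, and the reported range is the
per-layer min/max, not an uncertainty envelope. Per-area inventories
would need dry bulk density and are out of scope.

## The synthetic generator

`generate_samples()` emulates the statistical structure the analysis
assumes, not the ocean: habitat-stratified mean iPOC (benthic 70,
mixed 55, sympagic 65, pelagic 40 % at the reference latitude 68.5° N),
a latitude gradient of 0.5 % per degree over 55–82° N, seasonal dips in
May/September/December scaled per habitat (pelagic 1.0, mixed 0.5,
sympagic 0.25, benthic 0 — benthic consumers feed on stored ice-algal
carbon year-round, pelagic consumers track the most recent bloom
because HBIs turn over in days to weeks), logit-scale individual noise
(SD 0.5), lognormal total HBI intensity, a gamma-distributed IP25:HBI II
split, and two detection corruptions: complete dropout (default 3 %,
producing excluded samples) and loss of the sea-ice HBIs only (default
4 %, producing `pelagic_only` samples). The habitat mix
(benthic 40 / mixed 15 / pelagic 30 / sympagic 15 %) reflects a
benthos-dominated survey. Under these defaults roughly 96 % of included
samples show both carbon sources and roughly two-thirds exceed 50 %
iPOC — survey-shaped headline statistics — but every test asserts
against the generator's own configured truth, never against field
numbers.

Three numerical choices:

* **Mean-matched logit noise.** Noise on the logit of iPOC/100 keeps
  values inside (0, 100) without truncation, but a logit-normal's mean
  is not its median, so the location parameter is adjusted (bisection
  against quantile-quadrature of the logit-normal mean, interpolated on
  a fine grid) so the configured values are the *means* of the simulated
  distribution. Without this, group means and regression coefficients
  would be biased by the curvature of the inverse logit.
* **Calibration inversion.** True iPOC inverts the *unclamped*
  calibration line restricted to H-Print ∈ [0, 100]; any iPOC in
  (0, 100) maps to an interior H-Print, so the inversion is exact and a
  noise-free, corruption-free run round-trips truth through the full
  pipeline to machine precision.
* **Linear seasonal mode.** Parameter-recovery studies need a
  generating mean structure that is linear in the fitted covariates —
  otherwise "recovering the generating coefficients" is undefined — so
  a second seasonal mode draws the mean from explicit
  month/habitat-score/latitude/month × habitat coefficients. Its default
  effect sizes (habitat 6, latitude 0.5, month 0.3,
  month × habitat −1.2) were fixed by a design power analysis: each
  asserted coefficient sits at ≥ 15 standard errors at n = 2000, so a
  20-seed median estimate isolates estimator accuracy from sampling
  noise.

What the generator does **not** emulate: trophic transfer and
between-species correlation structure, regional/spatial autocorrelation,
inter-annual trends, realistic species richness (a dozen archetypes
stand in for a 150+-species survey), or instrument response factors.
Passing tests therefore demonstrate that the pipeline's arithmetic,
exclusion logic, model selection and sensitivity statistics behave as
specified — not that the field conclusions would replicate on new data.

## Problem sizes and determinism

The test suite and the acceptance script run synthetic surveys of
200–3000 samples (2334 for the headline run, matching the scale of a
large multi-decade survey) and a 20-seed × n = 2000 recovery study;
these sizes give stable statistics while keeping a full run in tens of
seconds. All stochastic stages are seeded; identical config plus seed
reproduces every output file bitwise, and the run manifest hashes the
analytic configuration (excluding the output path) to make reruns
verifiable.

## Known limitations

* The ordered habitat score is an interpretive coding; contrast coding
  changes the meaning (and number) of habitat coefficients.
* The calibration is taken as given; its experimental uncertainty is
  not propagated into iPOC estimates.
* The sediment estimate is a per-gram theoretical maximum; converting
  to areal inventories or correcting for degradation requires data the
  module does not assume.
* OLS assumes independent Gaussian errors; survey data with repeated
  species or stations would call for mixed models, which are out of
  scope here.
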