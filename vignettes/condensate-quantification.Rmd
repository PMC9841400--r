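---
title: "Quantifying biomolecular condensates: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying biomolecular condensates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CondensateKit)
```

# The measurement problem

Transcription factors such as the androgen receptor (AR) can demix into
micron-scale, membraneless nuclear foci with the hallmarks of
liquid-liquid phase separation (LLPS): rapid internal exchange probed
by fluorescence recovery after photobleaching (FRAP), dissolution by
1,6-hexanediol, formation above a saturation concentration, and droplet
formation by the purified protein in vitro. Establishing these
properties quantitatively requires four measurement layers — per-cell
focus counting from confocal z-stacks, FRAP recovery fitting, droplet
and colocalization quantification, and concentration estimation by
densitometry — plus a common statistical reporting layer. CondensateKit
implements all of them, together with a synthetic-data generator that
produces every input with known ground truth, so the whole pipeline can
be validated end to end without microscope access.

# Foci detection and per-cell classification

## Model

Analysis is two-dimensional, on the maximum-intensity z-projection of
the focus (green) channel, mirroring the common practice of projecting
a z-stack before segmentation. Foci are segmented with an adaptive
local-contrast threshold: a pixel is foreground when

$$I(y,x) > \mu_w(y,x) + k\,\sigma_w(y,x),$$

where $\mu_w$ and $\sigma_w$ are the mean and standard deviation over a
$w \times w$ window (reflective padding at the borders). Commercial
"adaptive threshold" tools are proprietary; the local mean-plus-$k$-SD
rule is the standard open formulation, and both parameters are exposed
in `analysisConfig()`.

Foreground pixels are grouped into 8-connected components, each
reported with a 0-based centroid, an area of
$n_{px} \cdot \text{pixelSize}^2$ µm², and a mean intensity. The
minimum-area filter defaults to **0 px** — every detected object is
kept, including single-pixel foci. Nuclei are segmented on the
nuclear-channel projection with a global threshold (a manual scalar or
Otsu's method), 4-connected labelling (which avoids chaining adjacent
nuclei through diagonal pixel bridges), hole filling, and removal of
border-touching nuclei, whose counts would be biased low by clipping. A
focus belongs to the nucleus whose mask contains its rounded centroid;
foci outside every nucleus stay unassigned and are excluded from
nuclear counts, so assigned plus unassigned always equals detected.

A nucleus is **foci-positive** when it contains at least 20 foci; the
cutoff is inclusive (a count of exactly 20 is positive) and
configurable. Field summaries report
$100 \cdot n_{positive}/n_{nuclei}$ and the mean count per nucleus.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `adaptiveWindow` | 15 | px | ≈ 1 µm at 0.067 µm/px, spanning a diffraction-limited punctum |
| `adaptiveOffsetK` | 3 | local SDs | conventional 3-sigma contrast |
| `minFocusAreaPx` | 0 | px | keep all objects |
| `positivityCutoff` | 20 | foci | inclusive per-nucleus cutoff |
| `nucleusThreshold` | `"otsu"` | AU | automatic stand-in for a manual threshold |

Absolute focus counts depend on the window and $k$; the pipeline is
therefore validated by ground-truth recovery, not by matching any
particular published count.

## Numerical choices

Local statistics come from summed-area tables computed on mean-centred
data, and the threshold comparison carries a relative tolerance of
$10^{-6}$ of the image's dynamic range. Both guards exist because
integral images accumulate floating-point rounding: without them,
numerically flat regions (constant background, smooth Gaussian tails)
can be flagged as foreground purely by cancellation error. Component
ids are assigned in raster order of each component's first pixel, so
labelling is deterministic.

# FRAP kinetics

## Normalization and model

Each trace carries a bleached-region and a simultaneously acquired
reference-region intensity series. Double normalization

$$F(t) = \frac{B(t)/R(t)}{\overline{B_{pre}}/\overline{R_{pre}}}$$

cancels acquisition photobleaching exactly (it multiplies both
channels) and fixes the pre-bleach level at 1. Recovery is fitted as a
single exponential from the first post-bleach frame ($t' = 0$):

$$F(t') = F_\infty - (F_\infty - F_0)\,e^{-k t'},$$

with $F_0$ fixed to the observed first post-bleach value rather than
fitted — on a 30 s window this markedly reduces the correlation between
$F_\infty$ and $k$. The half-time is $t_{1/2} = \ln 2 / k$ and the
mobile fraction, in percent of the reference signal, is
$100\,(F_\infty - F_0)/(1 - F_0)$; its complement is the immobile
fraction. The mobile fraction is deliberately not clamped: values
outside [0, 100] are returned with a quality flag so that population
averages stay unbiased. Population summaries use a Student-t interval
with $n-1$ degrees of freedom across foci, matching
"mean (95% CI), n foci" reporting; per-fit covariance is not used.

## Identifiability at the immobile limit

For a non-recovering trace the model is degenerate: as $k \to 0$ the
fitted plateau can extrapolate arbitrarily far beyond the window while
changing the in-window curve only marginally, which inflates the mobile
fraction (a +9 percentage-point bias at 2% noise in simulation). The
rate is therefore bounded below so the fitted half-time never exceeds
**twice the post-bleach window** — slower exchange cannot be
distinguished from an immobile fraction on the data — and fits at the
bound are flagged `slow_recovery_unresolved`. With the bound, simulated
immobile populations fit to a mean mobile fraction within a fraction of
a percentage point of zero. The nonlinear fit is initialized from a
log-linear estimate of $k$, with the start amplitude floored at 5% of
the bleach depth (a zero-amplitude start makes the gradient in $k$
singular) and up to 5 jittered restarts under a fixed restart seed.

Soumpasis-style diffusion models and bleach-spot geometry corrections
are out of scope: the single-exponential (half-time, mobile fraction)
pair is the parameterization that population FRAP reports use.

# Droplets, colocalization, dose response and turbidity

Droplet images are thresholded with fixed inclusive ranges on a 16-bit
intensity scale — 550–60000 (green), 300–60000 (red), 100–60000 (gray)
— the upper bound excluding saturated pixels; no rescaling is applied
to inputs. Objects are 8-connected components with areas in µm².
Colocalization uses intensity-weighted Manders split coefficients
restricted to threshold-passing pixels,

$$M_1 = \frac{\sum_{G \cap R} G_i}{\sum_G G_i},$$

and symmetrically $M_2$; a pixel-count overlap area is reported
alongside, since a purely area-based coefficient is the other plausible
reading of "colocalization coefficient". When no pixel passes a
channel's threshold the coefficient is defined as 0 with a warning
flag.

The saturation concentration is estimated *operationally*: the lowest
concentration whose droplet statistic is significantly above the blank
(two-tailed Student's t, p < 0.05) with a mean exceeding the blank
mean. This is an estimator choice — phase-separation assays report the
phenomenon, not an estimator — and it is deliberately conservative at
desk scale. Turbidity series (OD at 340 nm) are summarized per
condition with pairwise tests against a control; on numeric condition
grids a breakpoint is estimated as the condition at the lower end of
the largest consecutive increase in means, which under a
flat-then-rising response locates where the rise begins.

# Densitometry

Band intensity is modelled as linear in concentration; the standard
curve is an ordinary least-squares fit and concentration estimates are
inverse predictions $\hat c = (I - b)/m$ with first-order calibration
uncertainty

$$\mathrm{sd}(\hat c) = \frac{s}{|m|}\sqrt{1 + \frac1n +
  \frac{(\hat c - \bar c)^2}{S_{cc}}}.$$

A 95% interval is $\hat c \pm t_{n-2,0.975}\,\mathrm{sd}(\hat c)$.
Estimates below zero carry a `below_range` flag and values outside the
standards' span an `extrapolated` flag; log-log calibration was
considered and rejected because band intensity on modern fluorescent
scanners is linear over the relevant range.

# Statistics

The reporting layer wraps the classical procedures: one-way ANOVA
(between/within mean squares, $(k-1, N-k)$ df), the pooled-variance
Student's t-test (Welch available behind a flag; the pooled form is
what "Student's t-test" names), and star annotation with half-open
bins — ns for $p \ge 0.05$, `*` for $[0.01, 0.05)$, `**` for
$[0.001, 0.01)$, `***` for $[0.0001, 0.001)$, `****` below $10^{-4}$.
The endpoint convention follows "ns ≥ 0.05"; the interval wording of
published star legends is ambiguous at interior endpoints, and
half-open bins make the label a monotone step function of $p$. No
multiple-testing correction is applied by default (a Bonferroni option
exists), matching common single-comparison reporting in imaging papers.

# The synthetic-data generator

## What it emulates

- **Foci fields**: two channels (nuclear stain, green) at the counting
  geometry (0.067 µm/px, 0.21 µm z-step by default). Nuclei are
  non-overlapping discs placed by rejection sampling (bounded at 1000
  retries, then an explanatory error); foci are 3D Gaussian puncta
  ($\sigma_z = 2\sigma_{xy}$, the axial elongation of a confocal PSF)
  on a diffuse nucleoplasmic level. Spots render over the full frame
  and the nuclear rim is blurred ($\sigma$ = 2 px): hard truncation
  boxes and step edges are artefacts real optics never produce, and a
  local-contrast threshold duly detects them. Focus centroids keep a
  minimum pairwise separation of $5\sigma_{xy}$ so the ground-truth
  count refers to resolvable puncta. Poisson shot noise and additive
  Gaussian read noise are applied last; intensities are clipped at
  zero (documented, and relevant only at near-zero backgrounds).
- **FRAP traces**: exact single-exponential recovery after an
  instantaneous bleach (a ~16 ms bleach pulse is instantaneous relative
  to 0.5 s sampling), mono-exponential acquisition photobleaching on
  both channels, multiplicative Gaussian noise. Defaults follow a 30 s
  window at 0.5 s sampling with 5 pre-bleach frames.
- **Droplet fields**: 256 × 256 two-channel frames of uniform-intensity
  discs with a controllable colocalized fraction (green discs centred
  on red discs), intensities above the default threshold ranges.
- **Turbidity**: flat baseline below the saturation concentration,
  exponential approach to a plateau above it.
- **Standard curves**: linear intensity–concentration points with
  relative noise and a held-out query band.

Every generator is bit-reproducible under a fixed seed and never
perturbs the session RNG.

## What it does not emulate

No optical physics beyond the Gaussian-PSF stand-in: no Airy rings, no
depth-dependent aberration, no chromatic offset, no cell-to-cell
heterogeneity in nucleoplasmic background, no irregular nuclear shapes,
no focus size/intensity distributions, and no biological variability in
FRAP kinetics (every trace in a simulated population shares one true
parameter pair, so population CIs reflect fitting noise only, whereas a
real "n = 21 foci" interval also carries focus-to-focus variability).
Passing the recovery tests therefore demonstrates that the estimators
are correct and nearly unbiased under the stated noise models — not
that any particular biological image will be segmented perfectly.
Exact-count recovery is asserted in the noise-free limit; with shot
noise and a zero area filter, speckle produces spurious single-pixel
objects at any sensitivity, which is exactly why absolute counts are
treated as parameter-dependent.

# Problem sizes and runtime

The test suite validates counting on 200–360 px fields with 2–3 nuclei
over 20 seeds, FRAP recovery on 100-trace simulations at 1–3% noise,
colocalization on 50 seeded 256 × 256 fields, ANOVA type-I error on
1000 null draws, and densitometry interval coverage on 500 curves —
sizes chosen so the full suite runs in well under a minute on one core
while keeping Monte-Carlo standard errors small. The acceptance script
refits 55 simulated traces and finishes in seconds.

# Known limitations

- The adaptive threshold's absolute output depends on window and $k$;
  cross-study comparisons should fix both.
- Centroid-containment assignment can misattribute a focus lying on a
  nucleus boundary; with well-separated nuclei this is rare.
- The operational saturation-concentration estimator inherits the
  concentration grid's resolution and the replicate count's power.
- Inverse-prediction intervals assume homoscedastic standard-curve
  noise; strongly relative noise over a wide range mildly inflates
  coverage at the extremes.
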