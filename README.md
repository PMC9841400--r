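# CondensateKit

Quantification of liquid-like biomolecular condensates from fluorescence
microscopy and companion biochemical assays, built for studies of
transcription-factor condensation (e.g. androgen receptor foci in
prostate cancer cells). The package covers the four measurement layers
such studies rely on, each testable end to end against a synthetic-data
generator with known ground truth:

- **Nuclear foci quantification** — maximum-intensity z-projection,
  adaptive local thresholding (foreground where
  `I > mean_w + k * sd_w` over a *w*-pixel window), 8-connected focus
  labelling with areas in µm², nucleus segmentation, centroid-based
  focus-to-nucleus assignment, and foci-positive classification
  (a nucleus with ≥ 20 foci is positive, inclusive).
- **FRAP kinetics** — double normalization
  `F(t) = (B(t)/R(t)) / (B̄_pre/R̄_pre)` against an unbleached reference
  region, then a single-exponential recovery fit
  `F(t′) = F∞ − (F∞ − F₀)·exp(−k t′)` with the first post-bleach value
  fixed as F₀, reporting the half-time `t½ = ln2/k`, the mobile fraction
  `100·(F∞ − F₀)/(1 − F₀)`, and Student-t population confidence
  intervals across foci.
- **In vitro droplet quantification** — fixed-range thresholds
  (550–60000 green, 300–60000 red, 100–60000 gray, both bounds
  inclusive), object counts and total area, intensity-weighted Manders
  split coefficients M1/M2 on threshold-passing pixels, dose-response
  tables with an operational saturation-concentration estimate, and
  turbidity (OD340) summaries with a breakpoint estimate.
- **Densitometry and statistics** — linear standard-curve fitting with
  inverse prediction and propagated uncertainty; one-way ANOVA,
  two-tailed unpaired Student's t-tests, and significance stars
  (ns ≥ 0.05, `*` 0.01–0.05, `**` 0.001–0.01, `***` 0.0001–0.001,
  `****` < 0.0001).

## Worked example

Simulate a field of nuclei with known focus counts, quantify it, and
fit a FRAP population:

```r
library(CondensateKit)

f <- makeFociField(fociFieldSpec(
    fieldShape = c(360, 360), nNuclei = 3, nucleusRadius = 3.8,
    fociPerNucleus = c(19, 20, 25), readNoiseSd = 0, shotNoise = FALSE,
    seed = 77))
res <- quantifyFoci(f$stack, analysisConfig())
res$nuclei
#>   nucleus_id area_um2 foci_count foci_positive
#> 1          1 45.39726         19         FALSE
#> 2          2 45.37032         25          TRUE
#> 3          3 45.35237         20          TRUE
res$summary
#>   n_nuclei n_positive percent_positive mean_foci_per_nucleus
#> 1        3          2         66.66667              21.33333
```

All three ground-truth counts are recovered exactly; the nucleus with
19 foci falls below the 20-focus cutoff, so 2 of 3 nuclei (66.7%) are
foci-positive.

```r
pop <- simulateFrapPopulation(21, tHalfTrue = 3.80, mobileTrue = 51.01,
                              noiseSd = 0.03, seed = 4001)
pop$tHalf
#>    n     mean    ci_lo    ci_hi
#> 1 21 3.811183 3.719512 3.902853
pop$mobileFraction
#>    n     mean    ci_lo    ci_hi
#> 1 21 51.26209 50.67643 51.84776
```

Twenty-one noisy recovery traces generated at a 3.80 s half-time and a
51.01% mobile fraction are fitted back to a population mean of ~3.80 s
and ~51%, with 95% confidence intervals.

See the methods vignette (`vignettes/condensate-quantification.Rmd`)
for the models, parameter choices and known limitations.

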