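---
title: "Methods: image-based hemagglutination endpoint calling and lectin quantitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based hemagglutination endpoint calling and lectin quantitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemaggr)
```

## The assay and its measurement model

Active phytohemagglutinin (PHA) cross-links red blood cells. In a
round-bottom well this produces a diffuse mat covering most of the well
bottom; without active lectin the cells sediment into a compact central
dot. Photographed over a lightbox, both phenotypes are darker than the
white background, and the *thresholded area* of dark material inside a
well separates them cleanly: mats cover several-fold more area than
pellets. `hemaggr` turns that contrast into an objective endpoint call for
a two-fold serial dilution series.

The measurement chain is deliberately simple and fully deterministic:

1. *Scale*: `calibrate_scale()` divides the plate manufacturer's
   well-bottom diameter (mm) by the same well's edge-to-edge pixel extent.
   One isotropic scale is assumed; the physical setup (camera centered,
   level, ~75 cm above the plate) keeps perspective distortion below the
   per-well measurement noise, and no perspective correction is attempted.
2. *ROI grid*: `build_roi_grid()` places one circular ROI per well,
   row-major from the center of well A1, spaced by the well pitch
   converted to pixels. The ROI radius is `roi_fraction` (default 0.95) of
   the well-bottom radius so the well wall never enters the measurement.
   Computing the grid from one anchor, rather than dragging a combined ROI
   between rows by hand, makes runs reproducible and headless.
3. *Threshold and measure*: after conversion to 8-bit grayscale
   (ITU-R BT.601 luminance weights 0.299/0.587/0.114),
   `extract_and_threshold()` keeps pixels with gray value in `[0, 235]`
   inside each ROI — the inclusive upper bound is part of the protocol and
   is configurable — and `measure_wells()` reports per-well area
   (`pixel count × mm_per_px²`), centroid, and the number of 8-connected
   components. Multiple components in one well are summed into a single
   area: a fragmented edge-effect mat must be comparable to a contiguous
   one. The component count is kept as a diagnostic. No size or
   circularity filters are applied.

## Endpoint calling

`negative_stats()` summarizes the PBS + red-cell control wells of the same
run: mean area, sample standard deviation (n−1 denominator; the estimator
is a package choice, as protocols rarely specify it), and the positivity
threshold `mean + 3·SD`. A well is positive when its area **strictly
exceeds** the threshold; a tie (possible only when the SD is zero) calls
negative, the conservative direction for a safety assay. Controls are
required per run and the API provides no way to reuse a stored threshold,
because pellet areas drift as red blood cells age.

`call_endpoint()` then applies two rules:

* the **endpoint** is the rightmost supra-threshold well
  (`last_positive`); `first_negative = last_positive + 1` when it exists
  inside the series;
* any sub-threshold well strictly left of the endpoint is flagged as the
  **edge-effect artifact** — at high lectin concentration the mat rolls
  into small polygons whose thresholded area drops below the negative
  band — and can never itself become the endpoint.

The second rule formalizes what a trained reader does by eye ("ignore the
early dip"). It is intentionally algorithmic: the artifact is identified
*relative to the endpoint*, not by its morphology, so a genuinely negative
well in the middle of a series (possible in noisy data) is also flagged
rather than silently truncating the titer. Series spanning two plates are
concatenated by well index before calling; the caller never sees plate
boundaries.

An all-negative series reports a censored titer (below one HAU), never a
fabricated zero. A fully positive series reports `last_positive = n` with
no first negative — the signal to extend the dilution onto a second plate.

`qc_positive_control()` compares the positive-control endpoint with its
expected well (default tolerance 0 wells); the `analyze` command exits
with status 2 when it fails, the basis for repeating a run.

## Dilution bookkeeping and concentration

With the first well undiluted, `retained_volume_ul` per well (default
100 µL) and per-step factor `f` (default 2), well *n* holds
`start_conc × volume / f^(n−1)` ng, and the titer at an endpoint in well
*n* is `f^(n−1)` HAU. For a weight-per-volume powder extract the same
arithmetic tracks powder mass: 10% w/v is 100,000 ng powder per µL.

The hemagglutination concentration estimate divides the minimum detectable
analyte amount θ (default 200 ng, an assay property supplied as
configuration) by the powder mass in the first negative well. Computation
is at full precision: for the 10% w/v example with the endpoint between
wells 14 and 15, well 15 holds 610.35 ng and the estimate is
327.68 mg/g. Reports that round the powder mass to 610 ng print 327.87,
truncated to 327 at display precision; the package computes exactly and
rounds only at the reporting layer. The assay's intrinsic accuracy is ±1
dilution step, so no tighter uncertainty is attached.

## ELISA standard curve

The ELISA model is a straight line `A = α + β·ng` fit by ordinary least
squares, with a t-based 95% CI on β. A four-parameter logistic is out of
scope: within the calibrated range (up to the 300 ng top standard) the
response is treated as linear, and readings above the top standard are
flagged rather than extrapolated. The intercept is estimated, not forced
through zero, because a 0-ng standard carries a measurable blank.
Replicates enter the fit individually so the CI reflects the true residual
degrees of freedom. Readings inverting below the lower limit of
quantification (default 15 ng) are censored — reported as below the
LLOQ-equivalent concentration, never as a number.

Back-calculation to mg active lectin per g dry powder divides the
nanograms in the well by the well volume (default 100 µL), multiplies by
the dilution applied to the extract, and divides by the powder mass
concentration of the undiluted extract (default 0.1 mg/µL, i.e. 10% w/v).
These constants are configuration, not constants of nature; defaults
follow the standard plate protocol. `exposure_dose()` and
`reduction_ratio()` are exact arithmetic on the results.

## The synthetic plate renderer

No public corpus of annotated hemagglutination photographs exists, so the
package ships a generator that renders plates with known ground truth.
What it emulates:

* white lightbox background (gray 255) with a mild left-to-right
  illumination gradient (default 3% relative) and Gaussian sensor noise
  (default SD 2 gray levels);
* phenotype morphology by analyte amount: full mats (~80% of the ROI,
  gray 175), fuzzy oblong mats and donut mats near the detection
  threshold (~40–50%), edge-effect polygon clusters at very high amounts
  (~3% — *below* the pellet band, reproducing the deceptive artifact),
  and dark compact pellets for negatives (~5.5% of the ROI, gray 90);
* a stochastic positivity transition: a well is positive with probability
  `plogis(log2(amount/θ) / w)`. The default width `w = 0.05` log2 units
  confines ambiguity to roughly a quarter dilution step around θ; a well
  half a step from threshold essentially never flips, which matches how
  sharply the assay turns over between adjacent wells, while wells landing
  very close to θ remain genuinely ambiguous. Doubling a series' starting
  concentration therefore shifts its endpoint by exactly one well in
  ≥ 95% of seeded replicates — the calibration requirement for the
  default.

Two distributional choices matter for endpoint statistics. Pellet areas
jitter **uniformly within ±20%** of their mean rather than with Gaussian
tails: sedimented dots are stereotyped in size, and bounded support keeps
the largest possible pellet inside the mean + 3 SD band, so the renderer
does not produce spurious isolated "positives" deep in the negative run —
something real plates do not show. All other phenotype size draws are
normal clamped at 2 SD for the same reason. Seeded renders are
bit-reproducible, and every render carries a per-well truth table (amount,
state, positivity) plus a provenance YAML.

What it does **not** emulate: meniscus optics, specular highlights, color
information (the pipeline is grayscale by design), plate misalignment or
rotation (pre-processing options exist but synthetic plates are rendered
aligned), and red-cell aging beyond a scalar pellet-area drift parameter.
Passing the round-trip suite therefore demonstrates the pipeline's
correctness on well-formed photographs, not robustness to gross capture
errors.

## Validation problem sizes

The test suite validates the pipeline at sizes chosen to exercise every
code path while staying quick on one CPU: oracle-equivalence checks on 60
rendered wells at zero noise (pixel counts must equal a brute-force count
exactly, areas within 2% of the analytic shape area); an end-to-end
recovery study of 100 seeded plates spanning HAU 1–8192 with edge-effect
injection on high-titer rows (≥ 95% exact endpoint recovery, never off by
more than one well, artifacts flagged but never endpoint-shifting); 100
seeded ELISA replicates at noise SD 0.01 AU for CI coverage and 1000 for
slope bias. Renders use 0.1 mm/px (a 6.4 mm well bottom spans 64 px),
which keeps mats and pellets comfortably above rasterization error;
the pellet-area consistency check uses 0.05 mm/px because a ~7 px pellet
radius would otherwise be dominated by pixelation.

## Known limitations

* Plate localization is not automatic: the ROI anchor, rotation and crop
  are explicit configuration. This is intentional — the anchor is
  measured once per imaging setup — but means the tool does not handle
  arbitrary hand-held photographs.
* The endpoint rule trusts the rightmost supra-threshold well. Extremely
  contaminated wells beyond the true endpoint would extend the titer; the
  per-run positive control and the artifact flags are the guards.
* The donut morphology is captured only through its reduced area, not as
  a separate state in analysis.
* ELISA linearity is assumed within the standard range; saturating
  absorbances must be diluted into range, as flagged by `above_range`.
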