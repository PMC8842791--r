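---
title: "Measuring relative telomere length from two-channel qFISH images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring relative telomere length from two-channel qFISH images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telofish)
```

## The measurement model

Telomere-specific FISH probes hybridize in proportion to telomere repeat
length, so under constant exposure the integrated Cy3 signal of a telomeric
spot is a linear proxy for the telomere length it reports. `telofish`
operationalizes this as a per-cell statistic: every detected spot is scored
by its mean intensity on the *unenhanced* Cy3 image times its area (its
integrated intensity), a cell's spots are summed, and the sum is divided by
the cell's integrated DAPI signal:

$$\mathrm{TFI}_c \;=\; \frac{\sum_{s \in c} I_s A_s}{D_c}.$$

The DAPI denominator normalizes for nuclear DNA content and section
thickness: a nucleus cut thinly contributes proportionally less of both
telomeric and total DNA signal. The interpretation of TFI as *relative*
telomere length rests on three assumptions: linearity of probe signal,
constant exposure within a cohort, and telomeric signal residing inside the
nuclear ROI.

Two cells in the same image can be compared directly; two specimens cannot,
because staining efficiency and section quality vary. The package therefore
computes the per-cell **epithelial/stromal ratio**: each epithelial cell's
TFI divided by the mean TFI of all stromal cells *of the same image*.
Stromal telomere length is treated as a stable internal reference. The
ratio is deliberately computed per image, never against pooled stroma from
other images, and an image without stromal cells is an error rather than a
silent fallback — a wrong denominator would bias every epithelial cell in
the image. **TLV**, the cell-to-cell telomere length variation, is the
sample standard deviation (n − 1) of the per-cell value within one
biological specimen.

### Which value TLV is computed on

Published TLV magnitudes (tens of intensity units) are consistent with the
TFI scale rather than with the epithelial/stromal ratio scale (below one),
while the surrounding text calls both simply "telomere length". The package
defaults to TLV on raw per-cell TFI of epithelial cells and exposes
`metrics$tlv_value = "ratio"` as a configuration switch; the choice is
recorded in the output configuration rather than silently resolved.

## The spot-detection chain

The chain follows the classic telomere-quantification recipe: background
subtraction, a sharpening filter, rolling-ball enhancement, binarization,
and measurement of the binary mask against the unenhanced image. The
enhanced image is used *only* to decide which pixels belong to spots; all
intensities are measured on the background-subtracted but otherwise
unfiltered Cy3 image. We read "unfiltered" as *un-enhanced*: background
normalization precedes everything else, and integrating raw-offset pixels
would let the camera baseline (order 100 AU/px over tens of pixels)
dominate the 10^3–10^4 AU·px spot values.

Step by step, with defaults and the reasoning behind them:

* **Background subtraction** (`background.method = "percentile"`,
  `background.value = 50`): subtracts a scalar background estimate and
  clamps at zero. The median is used because with Poisson + read noise a
  low percentile (e.g. the 5th) underestimates the background *level* by
  about 1.6 noise SDs, which inflates integrated DAPI totals by several
  percent; the median estimates the level itself and is robust as long as
  foreground occupies well under half the frame (nuclei cover ~20 % in
  typical fields).
* **Sharpening** (`sharpen.amount = 1`): 3×3 unsharp mask
  `img − amount · Laplacian`, clamped at zero. Flat fields are unchanged;
  `amount = 0` is the identity.
* **Rolling-ball enhancement** (`rollingball.radius = 8` px): subtracts
  the grayscale opening with a flat disc of radius 8 — the flat form of
  the rolling-ball background filter. Features narrower than the disc
  survive; broad background is removed. The flat element keeps the whole
  chain homogeneous of degree one in intensity, so scaling the Cy3 channel
  by c scales every TFI by exactly c (a non-flat ball of fixed height
  would break this). The radius must exceed the largest genuine spot
  radius (a few px after PSF blur) by a comfortable factor.
* **Thresholding** (`segment.threshold = "noise"`): foreground is the set
  of enhanced pixels above 4 × the median of the *positive* enhanced
  pixels. After opening, background pixels are mostly zero, and the
  positive remainder is dominated by the noise floor; its median is
  insensitive to how bright or dim the spot population is, which matters
  when cohorts differ in telomere length — a threshold derived from the
  spot population itself (Otsu on the heavy-tailed enhanced histogram
  locks onto the brightest class) under-detects dim spots and biases
  cohort comparisons. Otsu (`"otsu"`) and fixed numeric thresholds remain
  available.
* **Size filtering** (`segment.min_area = 2`, `segment.max_area = 1000`
  px): removes single-pixel noise and implausibly large components.
  The upper bound is generous because several PSF-scale spots inside one
  nucleus legitimately merge into components of a few hundred pixels.
* **Mask growth** (`segment.grow = 2.5` px): the surviving components are
  grown outward so the measurement mask recovers the PSF-spread tail of
  each spot, which a hard threshold clips (the loss is largest for dim
  spots and would otherwise bias exactly the comparisons of interest).
  Growth is *label-preserving*: each grown pixel is claimed by its nearest
  component and components never merge, so neighbouring cells' spot
  clusters keep separate centroids and separate records.
* **Spot-to-cell assignment**: by the ROI label under the spot centroid.
  "Contained within the inscribed area" is ambiguous for spots straddling
  two ROIs; the centroid rule is deterministic, and a centroid on
  background yields `cell_label 0`, excluded from per-cell totals.
* **"Intensity × area"**: interpreted as mean spot intensity × area,
  i.e. the spot's integrated intensity, so that a cell's value equals the
  total telomeric signal inside its masked spots.
* **TFI display scale** (`tfi.scale = 1`): TFI is reported as the raw
  ratio by default. Published murine TFI values in the tens imply an
  unstated display multiplier; when one is used here it is recorded in the
  output metadata rather than baked into the numbers.

## The synthetic specimen generator

The generator exists so that the full chain — rendering through group
statistics — can be validated against known truth. It emulates: elliptical
nuclei placed without overlap, either on crypt rings of ~10 tangentially
aligned cells (epithelium) or scattered uniformly (stroma); per-cell
Poisson spot counts with lognormal integrated spot intensities; lognormal
total DAPI signal, rendered uniformly over the nucleus with circular
vacuole holes (DAPI only, the ROI keeps the full nucleus) for mucus/goblet
cells; a linear background offset plus x-gradient; Gaussian PSF blur;
Poisson shot noise and Gaussian read noise; 16-bit quantization and
clipping. Each ROI label extends 2 px (`roi_margin`) beyond the rendered
nucleus, emulating the generous manual freeform circumscription of a
blurred DAPI blob — with a tight mask the PSF moves ~15 % of nuclear
signal outside the ROI and no measurement-side choice can recover it.

Spots are Gaussian blobs (sigma 1.5 px, support truncated at 2.5 sigma)
whose weights are normalized *over the cell's mask pixels*, so before blur
and noise the Cy3 integral over a cell equals its true total signal times
the channel gain exactly; with `psf_sigma = 0` and noise off the chain is
exact to floating point, which the tests assert. Rendered values are
quantized to integers only when noise is on, so the noiseless contract
survives in-memory analysis; TIFFs are always integer.

Default conditions (chosen once as a realistic operating point, reasoned
from signal-to-noise before any recovery test was run): 256×256 frames,
PSF sigma 1 px, background 100 AU + 0.05 AU/px gradient, shot noise on,
read noise 5 AU, 6 spots/cell with mean integrated spot signal 5000 AU·px
(lognormal, sdlog 0.35), nuclear DAPI total 5 × 10⁴ AU (sdlog 0.2),
65 epithelial + 35 stromal cells per frame. This puts dim-cohort spot
peaks ~10 noise SDs above background — detectable but not trivial.

What the generator does **not** emulate: 3-D sectioning (no partial
nuclei), chromatic shift between channels, tissue folds and
autofluorescent debris, spatially varying staining efficiency within one
image, and spot clustering beyond uniform placement within the nucleus.
Passing recovery tests therefore demonstrates the correctness and internal
calibration of the measurement chain under idealized spot and noise
statistics, not robustness to every histological artifact; on real
sections the manual ROI and the per-image stromal reference absorb part of
that extra variation.

## Numerical and design choices

* Placement uses rejection sampling with 200 attempts per cell (or per
  crypt), then errors naming the compartment — deterministic and simple.
* Coordinates are pixel-centered, origin top-left, x rightward, y downward;
  masks are dense integer matrices with 0 = background.
* One integer master seed per cohort; specimen sub-seeds are derived by a
  fixed affine rule modulo 2³¹ − 1 and recorded in the manifest, so any
  specimen can be regenerated alone.
* Connected components use 8-connectivity by default (4 available).
* The studentized range tail for Tukey HSD is evaluated by direct numerical
  integration of its defining double integral to well below 10⁻⁶ absolute
  error; `stats::ptukey` is accurate only to ~10⁻⁴, which visibly breaks
  the exact k = 2 reduction to the pooled t-test. The Tukey–Kramer standard
  error handles unbalanced groups.
* The default unpaired test is the pooled Student t (two-sided); Welch is
  available. Published comparisons in this field were run in era-typical
  software whose default was the pooled test, and the package's
  summary-statistic reproductions are consistent with that: the TLV
  comparison falls inside its printed significance bound under the pooled
  test but not under Welch. Which variant the original software used is
  not stated anywhere; the default is a package decision, not a claim of
  fact.
* Degenerate statistics follow stated conventions rather than erroring
  mid-pipeline: both-SD-zero summary tests give p = 1 (equal means) or
  p = 0 (unequal), identical paired differences give p = 0 unless all
  zero, and each such event is logged.
* Zero-DAPI cells are excluded with a logged warning; spotless cells are
  retained with TFI 0 (they are evidence of short telomeres, not missing
  data).

## Problem sizes in the test suite

The acceptance-style checks simulate 2 cohorts × 5 specimens × 100 cells
at the default 256×256 frame size (≈ 10 s total) with true
epithelial/stromal ratios 0.9 and 0.45, and assert cohort-mean recovery
within 10 % and pooled-t separation at α = 0.01. Unit and property tests
use 128×128 specimens with 10 + 10 cells, 16×16 brute-force morphology
oracles over 100 random images, and 1000-replicate null simulations for
the type-I error of the t-test and one-way ANOVA. These sizes were chosen
so the full suite exercises every stage in well under a minute of
simulation time per test file.

## Known limitations

* Cohort-mean ratio estimates carry generator sampling variance as well as
  measurement error; with 5 specimens the between-specimen SE of the
  realized truth ratio is a few percent, so single-cohort point estimates
  a seed apart can differ noticeably even with an unbiased chain.
* Very crowded nuclei can merge at the *threshold* level (before growth);
  the centroid rule then assigns the merged cluster to one cell. Compartment
  means are nearly unaffected, but per-cell spot counts in dense crypts are
  not reliable.
* The ROI masks are inputs (as in manual workflows); no automatic nuclear
  segmentation from DAPI is attempted.
* No deconvolution, no telomere-fusion or anaphase-bridge detection, no
  survival or regression modelling.
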