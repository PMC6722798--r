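---
title: "Quantitative ER immunohistochemistry scoring: model and design"
author: "erquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative ER immunohistochemistry scoring: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erquant)
```

## The measurement model

A brightfield photomicrograph of an ER-immunostained,
hematoxylin-counterstained section is a transmitted-light image: at every
pixel, each RGB channel records an intensity $I_c$ relative to the
unstained white reference $I_0$. Under the Beer–Lambert law the optical
density

$$\mathrm{OD}_c = -\log_{10}\!\left(\frac{I_c}{I_{0,c}}\right)$$

is proportional to the amount of absorbing dye in the light path and is
*additive* across dyes. On this base-10 scale OD 1.0 corresponds to 90 %
of photons absorbed and OD 2.0 to 99 %, which is what anchors the
calibration: the scale is fixed by physics, not by the camera.

Two dyes are present: DAB (brown; deposited where the ER antibody bound,
the quantitative signal) and hematoxylin (blue; a non-specific nuclear
counterstain affecting all tissue). Each dye has a characteristic unit OD
vector across the RGB channels, so the per-pixel OD vector is a
non-negative combination

$$\mathbf{od} = c_H \mathbf{v}_H + c_D \mathbf{v}_D + c_R \mathbf{v}_R,$$

and color deconvolution is the linear solve for $(c_H, c_D, c_R)$. The
third (residual) vector is the normalized cross product of the first two;
it completes the basis and absorbs unmixing noise. Simple background
subtraction cannot separate a dark blue nucleus from a light brown one;
unmixing in OD space can, which is the entire point of the pipeline: DAB
that is visually drowned by hematoxylin is still linearly recoverable.

### Assumptions

* Fixed acquisition: constant illumination, no automatic gain or white
  balance, so one $I_0$ (default 255 per channel) serves all images. An
  optional per-image estimate (99th-percentile intensity) is deliberately
  **not** the default; normalizing per image would silently absorb real
  staining differences between slides.
* The two stain vectors are known. The shipped preset is the standard
  published H-DAB pair (hematoxylin $(0.650, 0.704, 0.286)$, DAB
  $(0.269, 0.568, 0.778)$, each normalized), the defaults of the widely
  used ImageJ deconvolution plugin; both are overridable in
  `stainMatrix()` / `runConfig()`. Automatic vector estimation
  (Macenko-style SVD) is out of scope.
* 8-bit RGB input. The quantization floor, not the optics, limits
  accuracy (see *Numerical choices*).

## Sampling and measurement

Nuclei are selected stereologically: a regular grid of $n_x \times n_y$
crosses (default 24 × 18) is overlaid on the field and exactly the nuclei
whose traced outline contains at least one cross are measured. This makes
nucleus selection unbiased by staining: the decision to measure a nucleus
depends only on where it sits, never on how brown it looks. A nucleus hit
by several crosses counts once — the grid samples *nuclei*, not hits
(point-counting convention).

Two placement conventions were plausible for the crosses (cell centers of
a uniform partition vs. lattice intersections); the published grid figure
does not distinguish them. We place crosses at cell centers,
$x_i = (i + 0.5)\,W/n_x$, because it keeps every cross strictly inside
the image and off the border. Both the grid size and (via `makeGrid()`
arguments) the placement density are configurable.

Inside each outline the DAB map is averaged over pixels whose *centers*
fall inside the polygon, even-odd rule — the raster behavior of common
ROI managers. Coordinates are 0-based, origin top-left, x rightward, y
downward; the pixel $(i_x, i_y)$ has center $(i_x + 0.5,\ i_y + 0.5)$.
These conventions are part of the file-format contract of `readROIs()`
(GeoJSON or per-vertex CSV) to avoid half-pixel dialect drift between
tools.

Fields are pooled per case by concatenation: every measured nucleus
counts equally regardless of its field. The reference protocol analyzes
at least 10 fields per case at 400×; fewer fields triggers a warning,
never an error, because the statistic is still well defined.

## Scoring

A nucleus is **positive** when its mean DAB OD strictly exceeds the
threshold (default 0.1 OD). The boundary is assigned to the negative
class because, empirically, ODs of 0.1 and below occur in cases read as
negative by eye; 0.1 is the lowest 10 % of the attainable range given
that mean nuclear OD does not exceed 1 in practice.

Per case, with $p$ = percent positive and $\bar{d}$ = mean DAB OD over
**all** measured nuclei:

$$\text{quantitative ER score} = \frac{p + 100\,\bar{d}}{20} \in [0, 10].$$

Averaging over all nuclei (not only positives) is the reading consistent
with the published discordant-case table — cases with 98 % positive
nuclei and mean OD of 0.0055 only make sense if negatives are in the
denominator — and it makes the two addends commensurate (both live on a
0–100 scale).

The same two summaries feed the Allred-compatible triple:

* **Proportion score** 0–5. The published bins (−, <1, 1–10, 11–33,
  34–66, >67) leave integer gaps at 10–11, 33–34 and 66–67 %; we close
  them by extending each bin down to the previous printed bound
  (half-open intervals: $(10, 33] \to 3$, etc.). Every printed example
  keeps its score and the map becomes total and monotone.
* **Intensity score** 0–3. Only the 0/1 boundary (0.1 OD) is anchored by
  the data; the 1/2 and 2/3 edges are not published anywhere we can
  recover. The defaults 0.4 and 0.7 partition the remaining attainable
  range evenly and are exposed as `intensityBins` everywhere they enter.
* **Discordance.** Proportion score ≥ 3 with intensity score 0 — the
  3+0, 4+0, 5+0 totals that a semi-quantitative reading cannot produce in
  practice, flagged per case.

`PositivityRule` carries a second, lower cutoff, `detectionFloor`
(default 0). The published per-case table lists percent-positive values
that are arithmetically incompatible with a 0.1-OD positivity cutoff
(e.g. 98 % positive with mean OD 0.0055); those percentages can only have
been counted under an "any detectable DAB" criterion. Rather than guess
silently, the package exposes both cutoffs: set
`positivityRule(threshold = 0, detectionFloor = 0)` to reproduce
detection-floor counting, and leave the default 0.1 for the standard
reading. The quantitative score itself is reported verbatim from the
formula in either case, including its ceiling of 10 (vs. Allred's 8);
no renormalization is applied.

## Cohort statistics

`compareScores()` computes Pearson $r$ with the two-sided $t$-test
($n-2$ df) and Cohen's $d$ with the pooled sample SD between the
semi-quantitative total and the quantitative score, plus $r$ between
percent-positive and mean intensity, histogram counts of both score
distributions, and the discordant-case list. Design notes:

* The sample ($n-1$) SD is used throughout; it is the convention that
  reproduces the reference table's printed summary SD (0.00334; the $n$
  denominator would give 0.00319).
* The grouping behind the reference study's published effect size
  ($d = 3.8215$) is not stated there; the package computes $d$ between
  the paired score columns and makes no attempt to reproduce that value.
* p-values are rendered to 3 significant figures with a "< 0.001" floor,
  matching reporting style; internally a 1e-15 floor avoids claiming
  zero.

## The synthetic generator

`renderField()` draws non-overlapping elliptical nuclei (axes uniform in
8–20 px, jittered orientation — the simplest shape that exercises polygon
rasterization honestly at 400×-like scale) on a 360 × 270 px field,
assigns each nucleus hematoxylin OD 0.3 plus a DAB OD drawn from its
class distribution (positives $\mathcal{N}(0.5, 0.1)$ kept above the
threshold, negatives 0 by default, clamped to the sub-threshold range),
paints the background with pale hematoxylin (OD 0.05), and renders
through the forward Beer–Lambert model with optional Gaussian intensity
noise before 8-bit quantization. Exactly
$\mathrm{round}(f \cdot n)$ nuclei per field are positive, so the
ground-truth fraction is controlled, not merely expected.

All randomness flows from one master seed through named substreams
(placement, stain levels, acquisition noise, observer), so stages vary
independently and every artifact — images, ground truth, cohort CSV — is
byte-reproducible from the seed.

`generateCohort()` additionally draws per-case parameters (positive
fraction uniform on $[0,1]$; positive-nucleus DAB OD increasing with the
fraction plus jitter, emulating the empirical coupling between abundance
and staining strength) and a synthetic "pathologist": the Allred bins
applied to ground truth, with the intensity score perturbed by ±1 with
configurable probability. That observer model is what lets tests
reproduce score-overestimation outliers without real observers.

What the generator does **not** emulate: tissue texture, chromatin
substructure, nucleus overlap and clumping, out-of-focus blur,
vignetting, stain-vector drift between slides, and non-tumor tissue
(normal/dysplastic/in-situ fields are excluded upstream by the user in
the real protocol). Passing tests therefore demonstrate that the
*computational* pipeline is correct and self-consistent under the stated
imaging model — not that the pipeline is robust to the full variability
of real slides.

## Numerical choices

* **Base-10 OD** everywhere, so the 90 %/99 % absorption anchors hold
  exactly. The legacy 0–255 "OD calibration" convention of some imaging
  software is interpreted as the *intensity* scale on which the log
  transform acts, which is the only reading consistent with both quoted
  absorption percentages and the 0–2 OD working range.
* **Zero-intensity floor:** intensity 0 is treated as 1/255 of $I_0$,
  capping OD near 2.4 and keeping the transform finite without
  distorting the stated OD ≤ 2 working range. Intensities above $I_0$
  (glare) read as OD 0.
* **Negative concentrations** after unmixing are clamped to 0 —
  concentrations are physical amounts; the residual channel keeps the
  noise.
* **8-bit round-trip tolerance.** Rendering known concentration maps
  through the forward model and unmixing them back recovers
  concentrations in $[0, 2]$ with a *mean* relative error of ~1.3 %
  (H-DAB matrix condition number ≈ 3). Individual pixels deep in the
  dark range (transmitted intensity of a few counts) can exceed 2 %
  because half a count of rounding there is worth several percent of OD;
  the round-trip guarantee is therefore stated and tested as a mean over
  pixels with concentration ≥ 0.05. Mean OD over a realistic nucleus
  (~150 px) recovers within 0.5 %.
* **Boundary rules**, stated once and tested: positivity is strict
  (`> threshold`); grid crosses on a polygon boundary count as hits;
  pixel membership is center-in-polygon, even-odd; percent-positive is
  kept as an exact rational and only rendered to 4 decimals in CSV
  output, with the Allred mapping applied to the unrounded value.
* **Determinism:** CSVs are written with '.' decimals, LF newlines,
  UTF-8, no quoting, so a rerun from the same configuration and seed is
  byte-identical; the YAML `RunConfig` is serialized next to every
  output.

## Problem sizes

The test suite and the acceptance script run at deliberately modest
scale: round-trip checks on 60 × 60 rasters, oracle comparisons on
100–200 random discs against the 24 × 18 grid, parameter recovery on one
500-nucleus case (50 nuclei × 10 fields, of which the grid typically
samples ~300), Monte-Carlo statistics at $n = 10^4$, and synthetic
cohorts of 12–30 cases. These sizes put every estimate well inside its
stated tolerance (binomial sampling bound at the sampled $n$; ±0.05 for
the Monte-Carlo statistics) while keeping a full run around a minute.

## Known limitations

* The stain vectors are assumed, not estimated; a slide stained far from
  the H-DAB preset will unmix poorly and the package will not warn.
* Nucleus outlines are consumed, not produced — there is no segmentation
  or tracing GUI, and ImageJ's binary `.roi` format is not parsed
  (GeoJSON/CSV only).
* The Allred intensity bins above 0.1 OD are a design default, not a
  community standard; cross-study comparability of the 1–3 intensity
  scores depends on agreeing on those edges.
* Whole-slide pyramidal formats, µm calibration and stain normalization
  between slides are out of scope.
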