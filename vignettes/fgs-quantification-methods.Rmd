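---
title: "Quantifying tumor-to-normal fluorescence contrast: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor-to-normal fluorescence contrast: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgsquant)
```

## The measurement problem

In fluorescence-guided surgery (FGS) a contrast agent is judged by how well
it separates tumor from surrounding normal tissue. The standard scalar
summary is the tumor-to-normal ratio (TNR),

$$\mathrm{TNR} = \frac{\overline{I}_{\mathrm{tumor}}}{\overline{I}_{\mathrm{normal}}},$$

the ratio of mean fluorescence intensity over a tumor region of interest to
that over a normal-tissue reference region. For orthotopic brain-tumor
models the natural reference is the contralateral hemisphere: the tumor is
implanted on one side, so the mirror-image region on the other side is
anatomically matched, tumor-free tissue.

`fgsquant` implements this measurement chain for two kinds of agents:

* **Near-infrared (NIR) activatable probes**, imaged as a single intensity
  channel. The tumor ROI is segmented from a co-registered nuclear-dye
  channel (tumor tissue is far more cell-dense than brain parenchyma), then
  transferred onto the NIR channel.
* **5-ALA / protoporphyrin IX (PPIX)**, imaged as an RGB photograph under
  blue light. PPIX fluoresces red-pink over a blue tissue background, so
  tumor and background differ chiefly in *hue*. A fixed luminance
  conversion would discard that contrast; instead a discriminative
  projection vector is fitted and the scalar product with the pixel colors
  produces the grayscale image on which the TNR is computed.

Because real section images of this kind are not publicly deposited, the
package ships a phantom generator that reproduces the *geometry* of the
measurement with known ground truth, making every stage verifiable by
parameter recovery.

## The phantom generator

`phantom_spec()` describes a two-hemisphere coronal section with an
elliptical tumor on one side. From one specification,
`generate_section()` renders three co-registered channels:

* **nuclear**: `nuclear_tumor_level` (default 1.0 AU) inside the ellipse
  over `nuclear_background_level` (0.1 AU) outside — a 10:1 cellularity
  contrast that drives segmentation;
* **NIR**: `nir_contrast` $\times$ `nir_normal_level` inside over
  `nir_normal_level` (1.0 AU) outside. `nir_contrast` (default 30, the
  order of magnitude reported for cathepsin-activated NIR probes in brain
  sections) is the ground truth the pipeline must recover;
* **RGB**: a red-pink tumor color (default (0.80, 0.20, 0.24)) over a blue
  background (0.16, 0.16, 0.47), mimicking PPIX under blue light.

Noise is additive zero-mean Gaussian, clipped at zero, with one standard
deviation parameter (default 0.05 AU, i.e. 5% of the nuclear tumor level)
applied to the nuclear and NIR channels; the RGB channel receives
per-channel Gaussian jitter (sd 0.02) clipped to $[0,1]$. An optional
infiltration band widens the tumor edge with a linear intensity ramp,
standing in for infiltrating cells at the margin; the band width is
measured in pixels via the geometric-mean semi-axis of the ellipse. No
attempt is made to model optical physics (scattering, depth attenuation,
spectral response) or histological texture — the phantoms are geometric
test objects, not simulated micrographs, and passing recovery tests on
them demonstrates correctness of the measurement chain, not performance on
real tissue.

Cohorts add between-animal biological variability: each animal draws its
own true contrast from a lognormal distribution with median `nir_contrast`
and a chosen coefficient of variation (CV). Lognormal is the natural
choice for a strictly positive ratio whose observed standard deviations
are large relative to the mean; the default cohort CV of 0.55 matches that
regime. Paired homogenate tables and ex-vivo fragment time courses follow
the same pattern — multiplicative lognormal noise with mean exactly one,
so noiseless generation reproduces the specified ratios exactly and noisy
generation is unbiased. Ex-vivo activation follows a saturating
$t/(t+t_{1/2})$ time course ($t_{1/2}$ = 10 min) sampled at 2, 5, 10 and
120 minutes, with one noise draw per fragment so every fragment's time
course is strictly increasing. Every generator is a pure function of its
parameters and an explicit seed; no global RNG state is consumed.

## Segmentation and the normal ROI

`segment_tumor()` thresholds the nuclear channel with a two-class
between-class-variance criterion (256-bin histogram spanning the observed
range, ties broken toward the lowest candidate, so the result is
deterministic and invariant to positive gain). Cleanup uses *opening by
reconstruction*: the binary image is eroded with a disc of radius
`smoothing_radius` (default 1 px) and only connected components that
survive erosion are kept — at their full, un-eroded extent. Plain opening
would shave single-pixel extremities off a perfectly recovered ellipse;
reconstruction removes sub-radius speckle while keeping noiseless recovery
pixel-exact, which is the property the test suite pins. Components smaller
than `min_area` (default 25 px) are discarded and the largest remaining
component is the tumor mask.

The normal ROI is by default `mirror_roi()`: the tumor mask reflected
across the hemispheric midline, giving a same-size, location-matched
reference. Reflection requires the tumor to lie strictly on one side of
the midline, and refuses masks whose reflection would lose 1% or more of
its pixels off the image edge. Whether a "contralateral hemisphere"
reference means a mirrored ROI or the whole hemisphere is a genuine design
choice; both are provided (`normal_roi = "hemisphere"` takes every tissue
pixel — nuclear intensity above a low quantile, default the 5th percentile
— on the opposite side), and the mirrored ROI is the default because it
matches size and anatomy simultaneously. `transfer_mask()` moves masks
between co-registered channels; it demands identical shapes, tolerates an
integer offset, and refuses transfers losing more than 10% of the mask.

## TNR and related summaries

All region means are arithmetic over mask pixels, with no background
subtraction (a tissue mask may be supplied to restrict the normal ROI).
When an animal contributes several sections, the per-animal TNR is the
mean of per-section TNRs — each section is one observation — rather than
a pixel-pooled ratio; pooling is available via
`aggregate_tnr(method = "pooled")`. Between-section consistency is
summarized by `section_cv()`, the sample (n−1) standard deviation over the
mean. Homogenate TNR normalizes fluorescence to sample weight by default;
any other denominator column (e.g. total protein) can be named. Ex-vivo
readings are normalized per experiment and timepoint to the mean of the
reference tissue processed alongside, which removes instrument and batch
scale; fold differences are ratios of group means.

## The color projection

Given the channel-wise median tumor color $m_T$ and normal color $m_N$,
the projection vector solves

$$\max_{\lVert v\rVert = 1}\; \lvert v\cdot m_T - v\cdot m_N\rvert ,$$

whose closed-form solution is the normalized median difference
$v = (m_T - m_N)/\lVert m_T - m_N\rVert$, signed so the tumor projects
higher. The unit-norm constraint is what makes the problem well-posed —
without it the objective is unbounded — and the test suite verifies the
closed form against a dense brute-force search over more than $10^6$
unit directions. Per-sample vectors are averaged (and renormalized) into a
single cohort vector used to convert every RGB image, so all samples share
one conversion. Medians are marginal per-channel medians with the midpoint
rule for even counts; the geometric median was rejected as needlessly
iterative for a 3-vector summary whose role is robustness, not geometry.

Projected values can be negative. The default clamps them at zero —
PPIX-specific signal cannot meaningfully be negative and the TNR needs a
positive denominator — with the caveat that when the normal region
projects near zero the clamped TNR becomes large and unstable; an
`offset` mode (shift by the global minimum) is provided for that regime,
and a non-negativity constraint on the vector components is available.
These are flagged in the output metadata rather than silently chosen.

## Statistics

Group and agent comparisons use the Mann-Whitney U test (unpaired), the
Wilcoxon signed-rank test (paired), and the paired t test, all two-sided.
The wrappers fix the exact-versus-approximate switch explicitly — exact
enumeration-based p-values when $n+m \le 12$ with no ties (Mann-Whitney)
or at most 20 non-zero, tie-free differences (signed-rank), a normal
approximation with tie and continuity correction otherwise — and record
the mode in the result, so small-sample p-values are reproducible and
verifiable by enumeration (the suite checks every arrangement up to total
sample size 8 against independent enumeration oracles). Zero differences
are discarded before ranking, the classic convention. No multiplicity
correction is applied; $\alpha = 0.05$ is used only for flagging.

## Numerical and storage choices

* Reflection and ellipse rasterization test pixel centers; masks are
  boolean matrices in R's native 1-based row/column indexing.
* The midline may be half-integral, which places it *between* two columns
  and makes the two hemispheres exact mirror images (the phantom default).
* Ratio invariance under a common positive gain is exact in IEEE
  arithmetic for power-of-two gains and holds to rounding (≤ 1e-12
  relative) otherwise.
* Intensity channels are stored as two-page 16-bit TIFFs scaled into
  $[0,1]$ by a power-of-two factor recorded in a YAML sidecar; values are
  snapped to the 16-bit grid before writing, so a write–load cycle
  returns exactly the stored values and re-writing is bit-stable. The
  quantization step is about 0.05% of the normal-tissue level — far below
  the phantom noise floor. (The installed TIFF writer offers no
  float sample format; 16-bit-plus-scale was chosen over its 32-bit
  integer path, whose float intermediates are not idempotent.) RGB images
  are 8-bit PNGs, loaded as $[0,1]$; masks are 8-bit 0/255 TIFFs.
* Pipeline outputs are schema-stable CSVs plus YAML for vectors and the
  resolved configuration; existing files are never overwritten without
  `force`.

## What the simulations cover

The test suite and the acceptance script (`scripts/acceptance.R`) rerun
the full chain on phantoms at the reference conditions: contrast recovery
for true ratios 5–30 under noise (10 sections per condition, mean
recovered TNR within 10%, noiseless recovery exact); segmentation
intersection-over-union ≥ 0.9 over 50 noisy phantoms; per-animal
between-section CV below 0.15 in ≥ 90% of animals under default noise;
size and direction of the paired Wilcoxon over thousands of simulated
null and shifted cohorts (10 animals each, between-animal CVs 0.55 and
0.70, the spread regime reported for such cohorts); and the projection
closed form against the sphere-search oracle. Problem sizes (192 × 256 px
reference sections, 96 × 128 px cohort replicates, 5,000 null replicates)
were chosen so the whole suite runs comfortably on a laptop while keeping
Monte-Carlo error well inside the asserted bounds.

Known limitations: phantoms are single-ellipse, 2-D, texture-free;
segmentation assumes one dominant bright component; the mirrored ROI
assumes approximate left-right symmetry and breaks for midline-crossing
tumors (rejected explicitly rather than mis-measured); the clamped
projection TNR is unstable when normal tissue projects near zero; and no
registration between sections is attempted — channels are assumed
co-registered, as they are for same-section imaging.
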