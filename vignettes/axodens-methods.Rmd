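---
title: "Quantifying labeled axons, boutons and somata: models and methods"
author: "axodens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying labeled axons, boutons and somata: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axodens)
```

## The problem

Viral co-injection of a red cytosolic reporter (tdTomato) and a green
synaptophysin-fused reporter (SypGFP) into the ventral tegmental area (VTA)
of a TH-Cre mouse labels dopaminergic neurons: the red channel fills axons
projecting to forebrain targets, and the green reporter concentrates in
synaptic boutons, the ~1 µm varicosities where dopamine is released.
Quantifying such material across serial sections of the basolateral
amygdala (BLA) raises three detection problems — curvilinear axons, point-like
boutons, and round labeled somata at the injection site — plus a normalization
problem: labeling efficiency varies between injections, so raw structure
counts are not comparable across animals.

`axodens` implements the full chain: a synthetic two-channel confocal
simulator with exact ground truth, the three detectors, cell-count-normalized
densities over matched sections, inter-region log2 intensity ratios, and the
statistical comparison layer. Because no raw images accompany the study this
models, every stage is validated against the simulator's exact truth.

## The simulator

A section is a pair of 3-D stacks (default 10 planes at 1 µm spacing,
matching confocal acquisition of 100 µm sections) with lateral calibration
0.62 µm/px ("10x" mode) or 0.25 µm/px ("25x" mode). Image formation is:
rasterize the scene, convolve each plane with a Gaussian PSF, add background,
then apply noise.

* **Axons** are persistent random walks: fixed 2 µm steps whose heading
  increments are von Mises with concentration `axon_kappa` (default 20,
  mildly tortuous; `Inf` gives straight lines). Paths are clipped exactly to
  the field, and the clipped arc length is the ground-truth length. Axons are
  rasterized as tubes of width `axon_width_um` (default 0.75 µm) at
  `axon_intensity`; each axon occupies one z plane.
* **Boutons** are a homogeneous Poisson process along the summed arc length
  with a sex- or group-specific linear density; they render as Gaussian spots
  of 1 µm FWHM in green, and at 30% of the axon intensity in red — the
  cytosolic fill makes boutons faintly visible in the axon channel, which is
  exactly why a separate synaptic reporter is needed for thresholding.
* **Somata** are non-overlapping discs with areas uniform on 49–200 µm²,
  rendered into both channels at the injection site.
* **Noise** defaults to `poisson_gaussian`: Poisson shot noise on
  (signal + background, default 20 counts) plus Gaussian read noise
  (default SD 2). With the default bouton amplitude the peak-over-background
  SNR of a rendered bouton is ≈ 6 at 10x.

A cohort draws one lognormal labeling-efficiency multiplier per mouse
(`mouse_effect_cv`, default 0.2) and applies it to *both* channels — to the
expected number of labeled axons per section and to the number of labeled
somata at the injection site — because efficiency is a property of the
injection, not of a reporter. This is precisely the variation that
normalizing densities by the injection-site cell count is meant to remove.

The default BLA axon areal density is 0.0005 axons/µm² (~12 axons in a
256² px 10x field, mean spacing above 10 µm). This matches the regime the
method requires: the BLA is quantifiable exactly because labeling there is
sparse enough to segment single axons, while denser regions (NAC) are not.
Region densities for NAC/BLA/PFC default to 0.004/0.0005/0.000125, keeping
the qualitative ordering NAC > BLA > PFC.

Every generator is a pure function of its configuration and seed: identical
inputs reproduce bit-identical images.

## The detectors

All three detectors share one thresholding rule: a band-pass response is
computed, its background mean and SD are estimated *inside the ROI* by
iterated 3σ clipping (robust to roughly 20% bright-pixel contamination), and
the response is binarized at `mean + threshold_sd × SD`. The presets follow
the two acquisition modes: 5 SD at 10x, 7 SD at 25x, and 3 SD for somata.
Because the background estimate absorbs any global offset, detections are
invariant to constant intensity shifts. Two practical details matter:

* An ROI is applied by zeroing pixels outside the hand-drawn contour. That
  step edge excites any band-pass filter, so the detectors internally refill
  the outside with the in-ROI background mean before filtering (detections
  are still restricted to the ROI). Without this, the contour itself
  contributes a constant false-positive load per section, which biases group
  ratios whenever true counts differ between groups.
* On an exactly noise-free image the response SD is numerically zero and
  `k × SD` thresholding is meaningless; the threshold then falls back to 20%
  of the peak response above background. Only noiseless inputs are affected.

**Axons.** The response is the magnitude of the most negative eigenvalue of
the scale-normalized Hessian at `ridge_scale_um` (default 0.75 µm), clipped
at zero — bright ridges on a dark background. After thresholding, components
below `min_object_px` (default 4) are removed and the mask is thinned to
unit width (Zhang–Suen, with a cleanup pass that removes residual 2×2 blocks
by deleting only topology-preserving pixels). The skeleton pixel count is
the axon-length proxy: one pixel ≈ one pixel-width of axon. Two properties
of this contract are worth stating. Diagonal skeleton steps cover √2 pixel
widths, so the pixel count underestimates true length by up to ~10% for
isotropic orientations; on simulated sections the calibrated error stays
within 15%. And while the binary mask is strictly nested as the threshold
rises, the *thinned* skeleton is not exactly monotone — a shrinking mask can
reroute the medial line through slightly longer diagonal staircases — so
skeleton counts are monotone only to within ~2%.

**Boutons.** The response is the negated Laplacian of Gaussian at
σ = diameter/(2√2) ≈ 0.354 µm. Within each suprathreshold component, boutons
are regional maxima (Euclidean-disc neighborhoods) separated by at least one
bouton diameter, greedily enforced in decreasing response order. Boutons
closer than roughly the PSF-broadened resolution limit (~1.5 µm here) merge
into single detections. This is a physical limit, not an implementation
artifact; at the default male linear density (0.16/µm) it removes ~14% of
boutons, at half that density ~3%, which is why a designed 2× density ratio
is recovered as ≈ 55% rather than exactly 50%.

**Somata.** LoG at the soma scale (σ matched to the equivalent-disc radius
of the mid-gate area, ≈ 4.5 µm), 3 SD threshold, then the 49–200 µm² gate.
The LoG support of any compact object at this scale is ≥ ~120 µm², so the
gate is applied to areas measured on a *half-max refinement*: within each
response component, pixels above background + ½(peak − background) of the
raw image. The half-maximum contour of a blurred disc sits at the true disc
edge, so gated areas are physical. Components above 200 µm² are split by a
distance-transform watershed and the pieces re-gated — discarding merged
pairs instead would systematically undercount at high labeling density.

## Quantification

Stacks are max-projected; ROI polygons (0-based pixel coordinates, even-odd
rule on pixel centers, so areas are bit-reproducible) zero the outside.
Serial sections are matched by ordinal position and any position missing for
one mouse is dropped for all. Per mouse: axon density = total skeleton
pixels / tdTomato-labeled cell count at the injection site; bouton density =
total bouton count / SypGFP-labeled cell count; region size = summed ROI
areas. Densities are expressed as percentages of the male-group mean, which
by construction averages exactly 100 in males. For inter-region intensity
comparisons, each region's mean raw ROI intensity (no background
subtraction; a toggle-free deliberate choice matching "average fluorescence
per pixel") is divided by that brain's injection-site mean intensity and
then by the cohort NAC average, expressed in log2. The NAC average is the
*geometric* mean: it is the natural average on a log scale and it is the
only convention under which the NAC log2 values average exactly zero.

## Statistics

`rm_anova()` is the hand-written within-subject decomposition
(F on (k−1, (k−1)(n−1)) degrees of freedom, no sphericity correction by
default, Greenhouse–Geisser available), cross-checked in the tests against
`aov(y ~ condition + Error(subject))`. Its effect size is
η² = F·df1/(F·df1 + df2); this partial form reproduces the published value
0.8693 from F(2,6) = 19.96, so it is the convention actually used with that
label. Follow-ups are pairwise paired t tests with FDR control at q = 0.05:
the two-stage step-up procedure by default (matching the follow-up default
of the graphing software named in the reporting style), plain
Benjamini–Hochberg as an option; both are verified against exhaustive
threshold enumeration. `two_sample_t()` in auto mode runs an F test of
variance equality at α = 0.05 and switches to Welch (Satterthwaite degrees
of freedom) when variances differ, recording Shapiro–Wilk and F-test
p-values in the decision trail. Cohen's d uses the pooled SD (an
average-variance variant is available);
`cohens_d_from_t(t, n1, n2) = t√(1/n1 + 1/n2)` recovers d from published
statistics. `power_check()` simulates lognormal per-mouse densities and
reports the rejection rate of the auto t test — ≈ 0.05 under the null
(calibration is asserted at 2000 simulations), → 1 for a 2× effect at low
noise.

## Problem sizes and runtime choices

The test suite validates detectors on 96²–512² fields with 2–3 z planes and
small cohorts; the sex-ratio recovery check runs the full pipeline at the
study design (5 mice per sex, 20 matched sections, 256² px 10x fields,
10-plane stacks) for two seeds, and the acceptance script averages ten
seeds. Injection-site fields default to 1024² px (635 µm at 10x): with ~150
somata the soma-scale LoG support must stay well under the background
estimator's contamination tolerance, and a VTA-sized field achieves that.
Rendering and filtering hot paths (separable convolution, shot/read noise)
are compiled; a full 10-seed recovery run takes on the order of ten minutes
on one CPU.

## What the simulator does and does not show

Passing tests demonstrate that the detectors recover known geometry, that
densities are invariant to labeling efficiency, and that the designed sex
difference survives the full pipeline. The simulator does not model
autofluorescence, vascular artifacts, immunostaining variability, axial
blur anisotropy, tissue deformation, or atlas registration error, and axons
occupy single z planes rather than sloping through the stack. Real-data
performance therefore depends on conditions the synthetic benchmark cannot
certify; the thresholds and scales are exposed in `detection_params()` for
recalibration against real material.

## Known limitations

* Skeleton pixel count is a biased length estimator for diagonal runs
  (up to ~10% under isotropy); comparisons between groups imaged and
  processed identically are unaffected.
* Bouton counts saturate with density through the ~1.5 µm merging limit;
  group ratios are mildly compressed toward 100% (measured: a designed 50%
  recovers as ~55%).
* Soma detection undercounts slightly (~4% at default SNR) near the 49 µm²
  gate edge; the bias is shared across animals and cancels in normalized
  densities.
* The two cell-count channels are detected independently per channel; joint
  red/green detection is not implemented.
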