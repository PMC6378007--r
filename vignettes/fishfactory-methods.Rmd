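---
title: "Methods: simulating and measuring 3D-FISH proximity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring 3D-FISH proximity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishfactory)
```

This vignette is the package's account of its science: the models it
implements, the parameters that matter, the numerical choices made where
the design was genuinely open, and what the synthetic data can and cannot
tell you about real microscopy.

## The measurement problem

3D-FISH labels the chromosomal positions of chosen genes and images them
through a confocal z-stack (here the reference acquisition geometry is
1024 × 1024 pixels per slice and 60 slices at a 0.2 µm step, which covers a
whole nucleus axially). Each probe produces, in a diploid interphase
nucleus, up to two diffraction-limited spots per channel. The quantity of
interest is spatial proximity: a pair of signals separated by **2 µm or
less** (the boundary is inclusive) in three dimensions is called a
*long-range interaction*, the imaging proxy for two loci sharing a
transcription factory. Per condition, the headline statistic is the
percentage of nuclei whose closest green–red pair satisfies the criterion,
with SEM error bars across replicates and Student's t-tests between
conditions.

Because raw microscopy data for the motivating experiments are not publicly
deposited, this package pairs the measurement pipeline with a simulator
whose ground truth is known exactly. That serves two purposes: end-to-end
validation (inject a known colocalization rate, recover it through
rendering, segmentation and detection) and the random-placement null model
(what proximity would look like if loci were positioned uniformly at
random).

## The nucleus generator

A simulated nucleus is a *moderately deformed ellipsoid*:

* **Semi-axes** default to (5.0, 4.2, 3.5) µm. No reference nucleus size is
  printed for the motivating experiments, so this default was chosen once:
  its volume (≈308 µm³, equivalent-sphere radius ≈4.2 µm) is typical of
  cultured human interphase nuclei and consistent with the null-model
  calibration below. Per-nucleus multiplicative size jitter (default ±5%)
  and a uniform random orientation make the ensemble heterogeneous.
* **Deformation.** The only description available is qualitative
  ("moderately deformed"), so the surface is perturbed radially by a fixed
  low-order harmonic field: the ellipsoidal radius is multiplied by
  `1 + A·g(u)/max|g|`, where `g` is a sum of six random low-frequency
  cosines of the surface direction and `A ≤ 0.3` (default 0.1). This keeps
  the shape smooth and star-convex, so the inside test stays exact and
  cheap; the original simulator reportedly drew shapes from real segmented
  nuclei, a library we do not have, and the parametric family substitutes
  for it.
* **Nucleoli** (default 2, radius 0.6–1.0 µm — counts and sizes are not
  stated anywhere, so these are exposed configuration with sensible
  defaults) are spheres placed uniformly inside the ellipsoid shrunk by the
  nucleolus radius, which guarantees each sphere lies entirely inside the
  undeformed ellipsoid. They appear as gaps in the chromatin texture.
* **Chromatin texture**: band-limited Gaussian noise (standard-normal
  values on a grid with 0.8 µm spacing, trilinearly interpolated)
  modulates the DAPI intensity multiplicatively with contrast 0.4.

Signals are placed **uniformly over the whole nucleus mask** by default —
nucleoli are *not* excluded, following the literal description of random
gene placement; exclusion is an option. For recovery experiments the
placement spec can inject a per-gene-pair colocalization probability *p*:
with probability *p*, one allele of the second gene is re-placed uniformly
within the colocalization radius (default 2 µm) of a random allele of the
first, still inside the mask. This correlated placement is an extension for
parameter-recovery testing, not a biophysical model, and is flagged as such
in the configuration.

## Rendering

The renderer produces calibrated multi-channel stacks. The DAPI channel is
the texture-filled mask blurred by the PSF; probe channels render each spot
as a separable anisotropic Gaussian (defaults σ_lateral = 0.2 µm,
σ_axial = 0.5 µm — a desk-scale surrogate for a confocal PSF, not a vendor
optical model) whose voxel sum equals the spot brightness (default 1200
photons, 15% log-normal spread). A uniform background (2 photons) and
Poisson noise complete the image; `"poisson+gaussian"` adds read noise.
The default lateral sampling is 0.25 µm/px (the reference acquisition
prints no pixel size; with a 40× objective and a 1024-pixel field this is
a plausible value, and it is configurable).

Everything is deterministic given seeds, and every generated nucleus
carries its ground truth (mask parameters, nucleolus geometry, true spot
positions), so pipeline error can be measured exactly.

Nuclei are rendered into per-nucleus crops (the test suite uses
64 × 64 × 64 voxels = 16 × 16 × 12.8 µm), which fully contain one default
nucleus in any orientation; a slide-scale field is represented by the
manifest of crop origins from `populate_slide()`, which rejects overlapping
bounding spheres so nuclear masks never intersect. This keeps memory flat
regardless of sample size: 500-nucleus conditions run in a stream,
discarding each stack after measurement.

## Measurement

* **Segmentation**: the DAPI channel is smoothed (Gaussian, 0.4 µm),
  thresholded globally by Otsu's method, holes are filled (nucleoli are
  dark but belong to nuclear volume), and 6-connected components are
  labelled. Volume is voxel count × voxel volume. Components touching the
  stack border are flagged and excluded from volume statistics, since their
  volume is truncated. On noiseless spheres this recovers volume to within
  ~2% (the residual is Otsu's placement of the threshold along the blurred
  edge); accuracy degrades mildly when foreground occupies a very small
  fraction of the field.
* **Spot detection**: anisotropic Laplacian-of-Gaussian filtering matched
  to the expected spot size, 26-neighbourhood local maxima above a robust
  threshold, and per-axis quadratic sub-voxel refinement of the response
  peak. The threshold is `7 × MAD` of the response inside the (dilated)
  nuclear mask. Seven, not the textbook five: a nuclear mask spans tens of
  thousands of voxels and the Poisson-noise response is right-skewed, so a
  5σ cut produces spurious maxima in roughly a quarter of spot-free nuclei,
  while a true spot at SNR 5 still scores ~8–13 because the matched filter
  pools photons over the whole blob. With the default optics the detector
  localizes isolated spots with ≈0.05 µm RMSE; two spots closer than about
  0.6 µm laterally fuse into one detection — a resolution limit, not an
  error, and QC-flagged downstream.
* **Allele selection**: the two highest-quality detections per channel are
  kept. Nuclei with fewer or more raw detections than expected are
  QC-flagged; nuclei lacking a full complement are excluded from interaction
  denominators (how the motivating experiments handled such nuclei is not
  stated; flag-and-report is this package's policy).

## Interaction statistics

Distances are plain 3-D Euclidean distances in physical units (voxel
centres at `(index − 0.5) × spacing`). Two percentage definitions are
implemented because published percentages rarely say which they use:
`per_nucleus_min` (a nucleus interacts if its closest cross pair is within
the threshold — the default, since published headline percentages are too
large to be per-pair rates) and `all_pairs` (each of the 2 × 2 = 4 cross
pairs counted separately). For allele pairing (A:A) there is a single
inter-allele distance per nucleus.

Distance distributions use **14 intervals**; the interval edges are not
printed anywhere, so the default is 1 µm bins over [0, 13) with an open
final bin `[13, ∞)` — wide enough to keep the documented far tail beyond
10 µm, and configurable. Intervals are left-closed, right-open; counts
always sum to the number of input distances.

Error bars are the SEM across replicates when a replicate structure exists
(the reference experiments used n = 2 replicates of ≥500 nuclei), else the
binomial standard error `100·√(p(1−p)/n)`. Between-condition tests are
Welch's t-test on per-nucleus indicators by default, with the pooled
("classic Student") variant available; no multiple-testing correction is
applied, matching the raw-star convention of the source figures — a choice
noted rather than silently "fixed".

## The random-placement null

For a sphere the distance law of two independent uniform points is closed
form, `F(s) = (s/R)³ − (9/16)(s/R)⁴ + (1/32)(s/R)⁶`; `F(R, R) = 15/32`
exactly, which anchors the Monte-Carlo tests. For ellipsoids and voxel
masks the null is sampled by rejection (exact for arbitrary star-convex
masks). The reported benchmark — **7.79% of random pairs within 2 µm** —
pins down the calibration: the geometry of the original simulated nuclei
was never printed, so this package solves `F(2, R) = 0.0779` for the
equivalent-sphere radius, giving **R = 4.23 µm**. That radius is a
calibration constant, not a measured nuclear radius, and it is consistent
with the default generator ellipsoid (equivalent-sphere radius 4.19 µm).

`compare_to_null()` tests an observed 14-interval histogram against the
null by chi-squared goodness of fit (pooling sparse high-distance cells to
a minimum expected count of 5) and reports the observed-minus-expected
mass beyond 10 µm, the far-tail signature of random placement. The null
histogram must come from a much larger Monte-Carlo sample than the observed
data, otherwise the reference's own sampling error inflates the statistic.

`background_interaction_rate()` computes the diploid background — the
probability that the closest of the 2 × 2 cross pairs falls within 2 µm
under purely random placement, averaged over the generator's shape
ensemble (~28% for the default geometry). The expected per-nucleus
interaction percentage for an injected probability *p* is
`100·(p + (1 − p)·background)`; end-to-end recovery tests check the
measured percentage against this prediction within Monte-Carlo error.

## Problem sizes and numerical choices

The validation suite uses the per-condition scale of the reference
experiments (500 nuclei per injected probability, run through the full
render → segment → detect → call chain) on 64³-voxel crops; full-frame
1024 × 1024 × 60 stacks carry identical per-nucleus content and are
exercised through geometry and configuration checks rather than full
renders. Volume-recovery experiments fix the semi-axes (no size jitter) so
the 20% reduction (per-axis scale 0.928, 0.928³ ≈ 0.799) is the only
volume difference between conditions. Ties in local maxima are broken by
voxel order; sub-voxel offsets are clamped to ±0.5 voxel; degenerate
t-tests (zero variance in both groups) return the limiting statistic
rather than an error.

## What passing tests do and do not show

The simulator reproduces the *geometric and photometric* structure of
3D-FISH stacks: nuclear shape variability, dark nucleoli, chromatin-like
intensity texture, diffraction-blurred point signals, photon noise,
anisotropic sampling. It deliberately omits: chromosome territories (so
same-chromosome proximity bias, as for gene pairs on one chromosome,
cannot and should not be generated — uniform placement is the null, not a
model of such pairs), replication doublets (>2 spots per gene), spectral
bleed-through, chromatic shift, and depth-dependent aberrations. Recovery
of injected probabilities therefore validates the pipeline's measurement
chain, not any biological claim; published wet-lab percentages appear in
this package only as emulation presets (`emulation_presets()`), never as
values the simulator is expected to reproduce.
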