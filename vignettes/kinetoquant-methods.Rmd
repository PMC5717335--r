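---
title: "kinetoquant: measurement model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kinetoquant: measurement model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinetoquant)
```

This vignette documents the science inside the package: the measurement
model, its assumptions, the tunable parameters, and the choices made where
the underlying published procedure leaves room for interpretation. It
states no empirical result that the test suite does not itself compute.

## The measurement problem

Kinetochores are diffraction-limited spots: 50–100 per mitotic cell,
sitting on a structured background (cytoplasmic antibody haze, neighbouring
chromatin). The quantity of interest is the integrated fluorescence of one
protein at one kinetochore, with the local background removed, measured
volumetrically rather than on a maximum-intensity projection (projections
mix in out-of-focus background and clip axially extended objects).

The chain is:

1. **ROI.** Otsu-threshold the DAPI channel; the analysis universe is the
   padded bounding cuboid of the nuclear foreground. This discards most of
   the field, stabilizes the ACA histogram that the next Otsu sees, and is
   cheap insurance against bright junk outside the cell.
2. **Segmentation.** Otsu-threshold the ACA (centromere) channel inside the
   ROI, label 3D connected components, and discard objects below
   `min_object_voxels` (default 70) as noise.
3. **Mask expansion.** Outer-kinetochore proteins (Ndc80, Knl1 and their
   phospho-epitopes) sit 50–100 nm outside the inner-centromere ACA signal,
   so the ACA mask is dilated by `expand_radius_px` (default 4 px =
   0.32 µm at 0.08 µm pitch) before measuring.
4. **Local background.** A ring (`annulus_width_px` = 2) separated from the
   measured mask by a gap (`annulus_gap_px` = 1) estimates the local
   background level; voxels belonging to *any* region's measured mask are
   excluded from every annulus, so close sister kinetochores never
   contaminate each other's background estimate.
5. **Corrected sum.** For mask $M$ and annulus $A$ in channel $c$:
   $$S_c = \sum_{v \in M} I_c(v) \;-\; \overline{I_c(A)}\,|M|.$$
   This is exact bookkeeping, not a fit; the test suite checks the identity
   to round-off, and its two corollaries — invariance under adding any
   constant to the image and exact zero on uniform images.
6. **Per-cell summary and statistics.** The mean corrected sum over a
   cell's kinetochores is the per-cell value; cells, not kinetochores, are
   the sampling unit (typically 10 per condition). Two-group comparisons
   are Shapiro–Wilk-gated (α = 0.05 per group) between a pooled-variance
   Student's t-test and a two-sided Mann–Whitney test; three or more groups
   use Kruskal–Wallis on ranks with Dunn's pairwise z-tests.

## Numerical choices

* **Otsu.** 256-bin histogram over the sample range; the threshold
  maximizes between-class variance; ties break toward the lowest
  qualifying threshold. The returned value is the largest sample value in
  the background class, so "foreground = strictly greater" is exact even
  for discrete data. The implementation is checked against an exhaustive
  search over all bin splits.
* **Connectivity.** Default 26 (full 3D neighbourhood); 6 and 18 are
  available, and the labeler is verified voxel-identically against an
  independent flood fill at 6 and 26.
* **In-plane dilation.** Expansion and annulus dilation act per z-slice.
  The published radii are quoted in xy pixels, while the z-step (0.2 µm)
  is 2.5 × the pixel pitch — a "4-pixel ball" in voxel units would be
  0.32 µm laterally but 0.8 µm axially, absorbing neighbouring objects.
  A `dilate_3d` flag provides the voxel-isotropic ball for users who want
  it.
* **"70 pixels" means 70 voxels of the 3D component.** The segmentation is
  explicitly volumetric, so the size filter applies to the 3D object, not
  to any single slice.
* **Measurement mask and annulus base.** The published wording ("the
  fluorescence signal within this mask", after describing the expansion;
  "a 2-pixel annulus ... to the perimeter of each segmented mask") is
  ambiguous about whether measurement and annulus refer to the core ACA
  mask or the expanded mask. Since the expanded mask is the measurement
  region and the gap exists to separate background from measured signal,
  both default to the *expanded* mask; `measure_mask = "core"` and
  `annulus_around = "core"` select the other reading.
* **Negative corrected sums are kept.** Clamping at zero would bias
  depleted/dim conditions upward; the unbiasedness test (mean of noisy
  replicates within 2 SE of the noiseless value) depends on this.
* **Line profiles** use trilinear interpolation at 0.5-pixel default
  spacing, with distances reported in µm; an optional min–max
  normalization puts channels on a common [0, 1] axis for co-plotting.
* **Empty annuli** (possible for objects filling the ROI) flag the region;
  flagged regions are excluded from per-cell summaries and counted in the
  run log, rather than silently contributing a fake background.

## Statistics

* The normality gate runs Shapiro–Wilk per group at α = 0.05; any group
  that is constant (Shapiro undefined) routes to the rank test. The branch
  taken is recorded in the result.
* "Student's t-test" is the classic pooled-variance test (Welch available
  by flag), two-tailed.
* Mann–Whitney uses the exact null when both n ≤ 8 without ties, and the
  tie-corrected normal approximation with continuity correction otherwise.
* Kruskal–Wallis H carries the standard tie correction. Dunn's pairwise
  z statistics compare mean ranks with variance $N(N+1)/12$ minus the tie
  term; decisions are reported at the 0.05/0.01/0.001 tiers *unadjusted*
  by default — matching the fixed-α "Dunn's Method" decisions of classic
  desktop statistics packages — with Bonferroni adjustment by flag. The
  choice is recorded in the output.
* Stars: \*\*\* p < 0.001, \*\* p < 0.01, \* p < 0.05, strict
  inequalities; p = 0.05 exactly is "ns".
* Identical degenerate groups return p = 1 with a warning rather than an
  error, so a batch run over many channels does not die on a pathological
  one.

## Interactome analysis

LFQ intensities are log2-transformed (standard practice for
variance-stabilizing label-free data); the per-protein fold change is the
difference of group means of log2 intensities, the p-value an unpaired
pooled-variance t-test on the same values. Missing values are explicit
(`NA`, never 0) and the only handling is the valid-value filter (≥ 2
present per group by default) — no imputation. Classification follows the
per-protein p < 0.05 rule with positive fold change; no multiple-testing
correction drives the flag (a Benjamini–Hochberg FDR column is emitted for
reference only). Zero-variance rows get p = 1 and a flag. Annotation is a
static set-membership join against user-supplied protein lists — not live
GO enrichment.

## The synthetic generator: what it emulates, what it does not

The generator exists so that every stage is testable against known truth
with no external data. It emulates:

* the acquisition geometry — 0.2 µm z-steps, 0.08 µm square pixels (so
  4 px = 0.32 µm);
* sister-kinetochore pairs at fixed 1.0 µm separation, random orientation,
  uniformly placed in a nuclear ellipsoid, with ≥ 1.5 µm between distinct
  pairs so the ground-truth object count is unambiguous (sisters of one
  pair may still merge — that happens in real images too);
* spots as separable anisotropic Gaussians whose per-voxel values are the
  Gaussian mass integrated over the voxel, so a spot's infinite-domain sum
  equals its amplitude exactly (checked against Gauss–Legendre quadrature);
* widefield noise: Poisson on background + signal, then additive Gaussian
  read noise, then clamping at zero;
* LFQ tables as log-normal baselines with planted log2 enrichment,
  replicate noise, and missing-completely-at-random dropouts.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| voxel size | (0.2, 0.08, 0.08) µm | the targeted acquisitions |
| σ_xy, σ_z | 0.15, 0.35 µm | a ~0.10 µm point-spread width convolved with the ~0.25 µm ACA domain; with the published 70-voxel size filter, a narrower spot (σ_xy = 0.10 µm) would have an Otsu-contour footprint of only ~50 voxels and be filtered out entirely — the filter and the spot model must be consistent |
| spot amplitude | 30 000 counts | bright enough that Otsu separates foreground from a 50-count background; at 10 000 counts foreground/background bimodality collapses |
| amplitude CV | 0.2 lognormal | typical kinetochore-to-kinetochore biological spread |
| background | 50 counts/voxel | mid-range 12-bit camera offset + haze |
| read noise | 3 counts RMS | typical interline CCD |
| pair separation | 1.0 µm | metaphase sister-kinetochore distance |
| cells per group | 10 | the published design |
| LFQ replicates | 4 per group | the published design |
| LFQ table size | 3512 proteins, 42 enriched | the published experiment's scale |
| LFQ noise | 0.3 log2 units | typical replicate CV for label-free data |

It does **not** emulate: a measured PSF or deconvolution artefacts,
chromatic shift, camera gain/EM registers, illumination flatness,
photobleaching, chromatin-shaped DAPI texture (the DAPI channel is a
smoothed ellipsoid indicator, only good enough to exercise ROI cropping),
structured proteomics missingness (dropout is independent of intensity),
or contaminant/reverse protein-group rows. A green synthetic test
establishes that the *pipeline arithmetic and inference* behave as
specified under a known world — not that any particular biological result
is correct, and published protein counts (3512 quantified / 42 enriched)
are scales adopted for realism, not reproduction targets.

## Known limitations

* Touching sister kinetochores are not split (no watershed); they are
  measured as one object, matching the published volumetric procedure.
* Phase labels are user-supplied metadata; no cell-cycle classification
  from images.
* The reference-normalization (`normalize_to_reference`) that maps the
  control-group mean to 1.0 is this package's presentation convention for
  "arbitrary units relative to control" figures; the underlying corrected
  sums are always available.
* The TIFF codec is deliberately minimal: baseline, uncompressed,
  grayscale multi-page (uint16 for integer data, float64 otherwise), with
  stack metadata in an ImageDescription JSON tag. Proprietary formats
  (e.g. DeltaVision `.dv`) must be converted to TIFF first.
* Per-seed end-to-end recovery of a depletion fraction with 10 cells per
  group carries visible sampling noise (the 200-seed acceptance criterion
  constrains the mean recovered ratio to 0.35 ± 0.035); single experiments
  should not be over-interpreted at the second decimal.
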