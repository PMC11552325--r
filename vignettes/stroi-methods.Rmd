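---
title: "Methods: image-guided ROI analysis for spatial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-guided ROI analysis for spatial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stroi)
```

## Overview

`stroi` turns tissue-image segmentation masks into spot-level contrasts.
The workflow is a fixed chain — preprocess, segment, build ROIs,
analyze — in which every stage is an exported function with an explicit
contract, and the segmenter itself is a pluggable backend. This
vignette records the model assumptions, the parameters that matter, the
numerical conventions, and the design decisions that were genuinely
open, so that results can be interpreted (and disputed) precisely.

## Coordinate model

All pixel coordinates are 0-based with `(x, y) = (column, row)`. Spot
positions are stored at full image resolution and mapped to the working
image by multiplying with the hires scale factor; the working spot
diameter is scaled the same way. When a spot must be rasterized to a
single pixel (mask membership, click resolution) the convention is
round-half-up (`floor(x + 0.5)`), chosen over R's round-half-to-even
because it is the convention image libraries use and it makes boundary
behaviour testable with exact fixtures.

The image is cropped to the bounding box of in-tissue spot coordinates
expanded by one working spot diameter (configurable). This removes the
fiducial frame geometrically — by where the tissue spots are — rather
than by detecting fiducials in the image. Degenerate crop windows are
expanded to at least 2×2 pixels because downstream rasters need area.
The crop offset is recorded in the run manifest, and out-of-bounds
spots are flagged and labeled `OTHER` downstream rather than dropped.

## Preprocessing

Spots outside the tissue and spots with fewer than 200 transcripts
(strict inequality: a 200-transcript spot stays) are removed; the
threshold counts *transcripts* (the row sum of raw counts), not
detected genes. Genes detected in fewer than 3 spots are then dropped;
this gene filter has no published rule attached to it, so the default
is the minimal standard choice and it is recorded in the manifest.
Normalization is the conventional library-size log transform
`ln(1 + c * T / total)` with `T = 1e4`; both `T` and the spot filter
are configurable. Raw counts are kept alongside the normalized matrix,
so normalization is repeatable and the DEG fold change can be computed
on the de-logged scale.

## Segmentation backend contract

A backend declares `everything` and/or `boxes` capabilities.
Everything-mode returns scored mask proposals; the pipeline keeps those
with score at least the confidence threshold (for SAM-style models the
score is the predicted IoU, so the threshold has the same stringency
semantics). Box mode must return exactly one mask per box, in box
order. Everything-mode masks may overlap — de-overlapping is
deliberately *not* done at segmentation time; conflicts are resolved at
ROI construction (below).

The built-in reference backend clusters RGB pixels with seeded k-means
(iteration cap 25, at most `k_colors` clusters, capped at the number of
distinct colours), takes the majority colour class along the image
border as background, and emits each 8-connected component of the
remaining classes with at least `min_area_px` pixels as a mask with
score 1. Connectivity is 8 because diagonal adjacency is standard for
blob extraction; the labelling is minimum-label propagation to a fixed
point, which is exact (property-tested against a BFS oracle). In box
mode the largest non-background component inside the box is returned;
a box containing only background returns the box region itself, so a
box prompt always yields a usable mask. The backend is a pure function
of (image, parameters, seed); on well-separated colours the result is
seed-independent as well.

This backend is a real segmenter for high-contrast, solid-colour
imagery (and is what makes the test suite self-contained); it is *not*
a substitute for a learned model on H&E texture. On real stained tissue
a wrapped foundation-model backend should be used; every downstream
stage is agnostic to the choice.

## Mask filtering and ROI construction

Everything-mode masks that do not co-locate with spots (fiducial
remnants, empty glass) are removed using the co-location proportion:
the fraction of a mask's pixels covered by the union of spot disks of
one working spot diameter. Masks below 0.01 are dropped; survivors are
re-ranked by area, largest first. Two genuine ambiguities were decided
here:

- **Denominator.** "Overlap of mask pixels with spot coordinates" can
  be read as mask-pixel coverage or as the fraction of spots falling in
  the mask. The primary definition is mask-pixel coverage, because it
  makes the 0.01 cutoff scale-free with respect to mask size; the
  alternative (`proportion_def = "spots-in-mask"`) is available.
- **Points vs disks.** Spots are treated as disks of the platform spot
  diameter, not points, since pixel overlap implies area. The
  proportion is computed on the exact rasterized disk union and is
  property-tested to equal an exhaustive per-pixel oracle.

A spot belongs to every mask whose raster contains its rasterized
centre. ROI labels are then pure set algebra: `ROI1` if the spot lies
in any ROI-1 mask, `ROI2` if in any ROI-2 mask, `EXCLUDED` if in masks
of both (overlapping proposals are routine; exclusion keeps the
contrast clean and is warned about), `OTHER` otherwise. An empty ROI 2
means one-versus-others: all remaining in-tissue spots become `ROI2`.
Click selection (for an interactive layer) toggles the *smallest*
containing mask, so nested fine structures remain selectable; adding a
mask to one ROI removes it from the other.

## Differential expression

Per gene, a two-sided Wilcoxon rank-sum test compares normalized
expression between ROI spot groups, using the normal approximation
with tied-rank variance deflation and **no continuity correction** —
the convention of the standard single-cell gene-ranking
implementations, kept so results are comparable with published panels.
Two numerical consequences are worth stating plainly:

- Against inclusive exact permutation enumeration the approximation is
  accurate in the significance tail (within 0.02 absolute for exact
  p < 0.2 at group sizes of 10) but deviates by up to ~0.03–0.07 at
  mid-range p for groups of 10 or fewer, where the discrete rank-sum
  distribution is coarse. Gene *ranking* is unaffected (the mapping
  from the rank-sum deviation to p is monotone), which is what the
  top-k display consumes. The suite asserts exactly these bounds.
- A gene with identical values in both groups (including all-zero
  genes) has zero rank variance and is assigned p = 1 and logFC = 0.

The fold change is `log2(mean(expm1(x)) + eps)` difference between the
groups with pseudocount `eps = 1e-9`, computed as a difference of logs
so that swapping ROI 1 and ROI 2 negates it bit-exactly. Adjustment is
Benjamini–Hochberg over all tested genes. Classification uses strict
inequalities (`logFC > cutoff`, `p_adj < cutoff`; defaults 1 and 0.05),
so a gene exactly at a cutoff is `ns`; the top-10 list is ordered by
fold change with ties broken by smaller adjusted p, then gene id.

## Over-representation analysis

The query is the up-regulated gene set of one ROI (ROI 1's panel uses
`up_roi1`, ROI 2's uses `up_roi2` — per-ROI panels mirror how enriched
terms are usually displayed side by side). The universe defaults to all
genes surviving preprocessing, i.e. what could have been detected;
`--universe library` style alternatives can be had by passing the
library union instead. Matching is case-insensitive by uppercasing,
applied to ORA matching only (DEG tables keep the data's original
case, which matters for mouse symbols). The test is the one-sided
hypergeometric upper tail `P(X >= k)` — over-representation only —
with terms of zero universe overlap skipped, BH over the tested terms,
and a `reported` flag at adjusted p < 0.05; all tested rows are
retained, so the cutoff is a display rule, not a data filter.

## The synthetic fixture

`make_fixture()` generates the conditions every stage is tested under:
a white working image with non-overlapping solid-colour regions (two
rectangles by default, 200×200 px), spots on a square lattice (pitch 8
px, in-tissue within one pitch of a region, ~440 in-tissue spots of 625),
negative-binomial counts (baseline mean 0.5 per gene over 2000 genes
≈ 1000 transcripts per spot; dispersion 0.5, i.e. variance
`mu + 0.5 mu²`) with 10 marker genes per region up-shifted by log2 fold
change 2 inside their region, a planted gene-set library (one term per
region's markers plus 20 decoy terms of random non-marker genes), and
per-spot cell-type fractions drawn from per-region Dirichlet profiles.
Negative binomial rather than Poisson because spatial counts are
overdispersed and the rank test should be exercised under realistic
noise. The lattice is square rather than hexagonal: every geometric
contract here is lattice-agnostic, and a square grid is trivially
oracle-checkable; hex placement would only matter for density, not
correctness. Full-resolution coordinates are stored at twice the
working scale (`hires_scalef = 0.5`) so the alignment step is
exercised non-trivially.

What passing on this fixture shows: the geometry, filtering, contrast
construction and statistics are correct, and planted signal of
realistic magnitude is recovered end to end (all ten planted markers
top the DEG list; the planted term is the only reported gene set).
What it does not show: performance on real H&E texture (no stain
variation, no background gradients), hexagonal-lattice spot spacing,
segmentation quality of learned backends, or the behaviour of the
deconvolution method that produces real fraction inputs.

## Problem sizes and runtime choices

The test suite runs the end-to-end fixture at its default size (2000
genes, ~440 spots), exact permutation oracles at group sizes up to
10 + 10 over 200 genes, the null calibration at 500 genes × 100 spots,
the pixel-union oracle on fifty ≤128×128 rasters, and hypergeometric
enumeration for every universe size up to 12. These sizes were chosen
so each oracle is exhaustive (or has negligible Monte-Carlo error)
while the whole suite completes in about a minute.

## Known limitations

- Single-sample: one image, one spot table per run; no batch container.
- Mask storage is dense boolean rasters — fine at Visium working-image
  scales, wasteful for very large whole-slide rasters.
- The reference backend assumes colour-separable regions; it makes no
  attempt at texture or stain-intensity modelling.
- The Wilcoxon normal approximation's mid-range p inaccuracy at very
  small ROIs (under ~10 spots per group) is documented above; with
  such small groups any spot-level test is underpowered regardless.
- Deconvolution fractions are consumed, never estimated.
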