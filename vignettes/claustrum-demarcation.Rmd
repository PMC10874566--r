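---
title: "Demarcating the claustrum from marker colocalization: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demarcating the claustrum from marker colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(clamap)
```

## The problem and the approach

No anatomical border separates the mouse claustrum from the insula, so its
demarcation rests on contrast between markers: claustrum-enriched genes
(Nurr1/Nr4a2, Nr2f2) label a dense patch of cells that coincides with
retrogradely traced claustrocortical projection neurons, while the cortical
marker Tle4 labels the structures surrounding that patch on all sides and is
nearly absent from it. `clamap` turns that qualitative picture into a
pipeline of measurable quantities: cell-level colocalization fractions,
enriched/devoid zone polygons registered across animals, dual-axis intensity
profiles, and the group statistics that compare them.

Because no reference imaging dataset accompanies this implementation, every stage is
exercised on synthetic slices whose ground truth is known exactly. The
simulator is first-class, tested code: what the tests demonstrate is that
each analysis stage recovers the truth it was given, under a noise and
geometry model chosen to resemble the real acquisition.

## The synthetic slice model

A slice is a square frame (default 1024 px at 1 µm/px) imaged as an 11-plane
z-stack (2 µm steps spanning 20 µm, inclusive endpoints). The spatial layout
(`claustrum_geometry()`) has three zones:

* **enriched** — an ellipse (default semi-axes 250 × 80 µm, rotated 30° as a
  stand-in for the external-capsule direction) holding the claustrum-like
  cell population;
* **ring** — an elliptical band (width 150 µm, separated from the ellipse by
  a 20 µm devoid margin) holding the surrounding Tle4-rich cortex;
* **background** — everything else, including the margin gap, with sparse
  expression of all markers.

Cell counts per zone and channel are Poisson at configured densities
(cells/mm²); positions are uniform within the zone; depths uniform over the
imaged volume. Each cell has a *primary* channel plus secondary memberships
drawn independently per configured ordered pair: membership of B given
primary A is Bernoulli with probability f(A:B). Defaults follow the reported
adult claustrum fractions — retro:Nurr1 0.87, retro:Nr2f2 0.81, retro:Tle4
0.01, Nurr1:Tle4 0.015, Nr2f2:Tle4 0.004 — and densities are calibrated so a
default frame carries ≈ 63 retrograde cells, ≈ 210 Nurr1⁺ and ≈ 185 Tle4⁺
cells per slice, the counts typical of adult tissue at this field size.
Only pairwise fractions are modelled (no three-way constraints), because the
quantification is pairwise Venn counts.

Rendering places an isotropic Gaussian spot per member cell: lateral sigma
combines half the soma radius (4 µm default) with the PSF sigma (1.5 µm); the
axial footprint is a Gaussian over the z-planes, renormalized so every cell
deposits the same integrated intensity regardless of depth (this keeps
max-projection detectability uniform and makes the equal-mass oracle test
exact). Noise is Poisson on the signal followed by additive Gaussian read
noise (SD 2), both low by default so ground-truth tests stay tight. Rendered
intensities are continuous in memory; `write_stack()` quantizes to 16-bit
counts, so the TIFF round trip is lossless for integer data.

For the c-Fos novelty experiment, `condition_presets()` sets
f(Nurr1:cFos) = 0.100 in naive controls and 0.256 after open-field exposure,
and f(Tle4:cFos) = 0.030 / 0.057 — i.e. +15.6 and +2.7 percentage-point
activation differences. The observable the contrast is designed around is the *difference*; the 10 %
naive baseline is this package's declared convention, chosen as a typical
baseline immediate-early-gene fraction.

**What the simulator does not emulate:** soma morphology (cells are Gaussian
blobs), intensity variation between cells, uneven illumination and
vignetting, z-dependent attenuation, autofluorescence, irregular (non-
elliptical) claustrum boundaries, and anisotropic cell densities inside a
zone. Passing tests therefore certify the pipeline's correctness on
centroid-level structure and its robustness to shot/read noise — not
performance on real histology, where detection thresholds and the KDE
bandwidth would need tuning.

## Coordinate and acquisition conventions

Pixel indices are 0-based in documentation; physical coordinates are µm with
the origin at the top-left pixel center, x rightward (columns), y downward
(rows). All polygon and profile outputs are physical µm. The pixel size is
not part of the emulated acquisition record, so 1 µm/px is a declared
default, kept explicit in every API. Stacks are written as multi-page
grayscale TIFF in channel-major page order with a JSON sidecar for channel
names, calibration and slice metadata (the TIFF writer available here has no
description field; a sidecar keeps the image file standard).

Anteroposterior subdivisions follow the bregma ranges anterior
(+1.80 to +0.70), middle (+0.70 to −0.20), posterior (−0.20 to −1.00), with
each interval closed on its anterior edge (a boundary coordinate belongs to
the more posterior-starting interval: +0.70 is middle). The source ranges
share endpoints without saying which side owns them; this is the package's
tie-break.

## Detection

The counting operator is deliberately the simplest fully specified
automation: Gaussian smooth (sigma 2 µm) → threshold → connected components
→ split touching components by local maxima with non-maximum suppression at
`min_separation_um` (6 µm) → area filter (8–500 µm²) → intensity-weighted
centroids. Otsu on the max-normalized smoothed image is the default
threshold, which makes the count invariant under uniform intensity
rescaling. Intensity weighting gives sub-pixel centroids, which the zone and
profile stages rely on. Degenerate inputs are defined, not errors: a blank
image returns an empty set; a contrast-free image warns and returns empty.

On zero-noise, non-overlapping synthetic slices the detector attains
recall = precision = 1 with centroid error below 1 px; at default noise and
density, merged close pairs (two somata nearer than the suppression
distance) cost a few percent recall, which is the suppression rule working
as specified rather than a failure mode.

## Colocalization

Two detections in different channels are "the same cell" when their
centroids lie within `match_radius_um` = 5 µm (about one soma radius); the
visual judgment the convention replaces carries no metric criterion, so
the radius is a package convention. Matching is greedy globally-nearest:
repeatedly accept the closest remaining cross-channel pair within the
radius, ties broken by id order. At biological densities (inter-soma spacing
well above the radius) this equals the exhaustive optimal assignment, which
the tests verify on small instances; in adversarially dense instances greedy
can pair fewer cells than the optimum, a regime the data never enters.

One consequence of any distance criterion: measured fractions sit slightly
above the configured membership probabilities (e.g. 0.89 observed vs 0.87
configured at default densities) because chance-adjacent cells within 5 µm
also match. The recovery tests that compare against binomial sampling error
therefore use membership-only cohorts (no independent partner-channel
population), isolating the configured fraction; the workflow tables on full
cohorts report the spatially measured quantity, as any real experiment
would.

Aggregation order is fixed: per-mouse means over that mouse's slices first
(fractions also count-pooled per mouse), cohort mean ± SD over mice second —
the mouse is the statistical unit throughout.

## Zone delineation

The enriched zone automates "outline the region holding > 90 % of the
labelled cells": a Gaussian KDE of the centroids (sigma 25 µm, evaluated on
an 8 µm grid padded by 4 sigma), then the highest density level whose
largest connected superlevel region still contains at least the target
fraction (0.90) of the cells, found by 40 bisection steps; the polygon is
the outer contour of that region's mask, simplified by Ramer–Douglas–Peucker
at tolerance grid/2 and capped at 200 vertices (tolerance doubles until the
cap holds). Containment is always re-verified on the final simplified
polygon, and the level is walked down if simplification dropped it below
target — so the ≥ 0.90 property holds by construction on every successful
output. Fewer than 10 cells is an error (the zone is undefined, not empty).
The largest-region tie-break encodes the expectation that the claustrum
zone is one blob; the bandwidth controls only boundary smoothness, since the
containment rule pins the level.

The devoid zone inverts the logic: KDE of the devoid-marker (Tle4) cells;
threshold = 0.25 × the median density *at the marker cells* (a robust
"typical labelled density"); the devoid region is the connected sublevel
component containing the anchor — in the pipeline, the retro zone's
centroid. Its KDE starts wider (1.4 × the enriched bandwidth) and widens
adaptively (× 1.5, up to 3 retries) when the sublevel set leaks through a
chance gap in the surrounding band, detected as the "devoid" polygon
swallowing the marker cells (> 20 % containment). With the default band
density the devoid polygon covers 60–85 % of the true interior — eroded near
the band by kernel bleed-in, which is the expected bias of a density
criterion and irrelevant to its role as an anchor-containing interior
estimate.

Registration uses the **vertex mean** of the polygon, not the area centroid,
a deliberate registration convention; the difference is observable (subdividing
one edge into collinear vertices pulls the vertex mean toward it) and
pinned by a test. Overlays translate each mouse's polygon pair by minus the
reference vertex centroid and count per-grid-point occupancy; only
translation is used — no rotation or scaling.

## Intensity profiles

An axis is anchored at the retro enriched-zone centroid: axis 1 along the
configured zone orientation (the external-capsule proxy), axis 2
perpendicular. A profile bin's value is the mean of all pixels whose
projection onto the axis falls in that bin (20 µm default) and whose
perpendicular offset is within half the strip width (100 µm = the 0.1 mm
convention). This pixel-binning definition is what the brute-force per-pixel
oracle computes, and the vectorized implementation matches it to 1e-6.
The 0.1 mm figure is read as the strip width, with the bin length left
configurable — a "0.1 mm section" admits either reading.

Z-scoring uses the population SD over present bins (bit-reproducible;
immaterial at these bin counts); a constant profile becomes all zeros with a
degeneracy flag rather than NaNs. No smoothing precedes peak detection — the
strip average already regularizes — and peak ties break toward the bin
nearest the axis origin. Realignment shifts all channels of a slice by the
retro peak position, so the reference peak sits at 0 mm in every slice by
construction; cross-slice envelopes average bins covered by at least half
the slices, avoiding edge artifacts from unequal shifts. On default cohorts
the retro and Nurr1 envelope peaks coincide within one bin and the Tle4
envelope shows a trough at the peak — the anti-correlated spatial pattern
the demarcation approach exploits.

## Statistics

Two-group comparisons are Student's pooled-variance unpaired t-tests
(df = n1 + n2 − 2): the pooled form is pinned by the t(13) convention for
groups of 5 and 10 mice. Zero pooled variance with equal means returns
t = 0, p = 1; with unequal means it errors. Multi-group comparisons are
one-way ANOVA with protected Bonferroni post hoc tests: pairwise t
statistics use the pooled within-group mean square and the within df, and
p-values are scaled by the number of comparisons m = k(k−1)/2 and capped at
1. k = 2 is allowed and reproduces t² exactly. Significance stars use the
strict thresholds *p < 0.05, **p < 0.01, ***p < 0.001, ****p < 0.0001.
Calibration is tested: over 10 000 null replicates the t-test rejects at
5 % ± 0.6 %.

## Problem sizes

The test suite and the workflow scripts choose sizes that keep every run in
minutes on one core while leaving the acquisition-level defaults untouched:
module tests use 256 µm frames with densities scaled up to preserve per-zone
cell counts; the enrichment and detection-fidelity checks run 20 and 1
full-size (1024 µm) slices; fraction-recovery cohorts pool ≥ 2000 retro
cells; profile envelopes average one mouse's six full-size slices; the
c-Fos contrast uses the full 5 + 10 mouse design (ground-truth centroids,
since rendering adds nothing to a counting contrast). Each script states its
own cohort size.

## Known limitations

* Zone delineation assumes a single connected enriched region; genuinely
  fragmented labelling would be outlined as its largest fragment.
* The devoid region is biased inward by kernel bleed from the surrounding
  band; its boundary is a density construct, not a tissue border.
* Measured colocalization fractions include a density-dependent
  chance-coincidence component inherent to distance-based matching.
* Greedy matching is only guaranteed optimal when somata are sparse relative
  to the match radius.
* Straight profile axes: no curved, structure-following profiles.
* The simulator's realism gaps listed above mean parameter defaults should
  be re-tuned before use on real histology.
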