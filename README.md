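# clamap — claustrum demarcation from marker labelling and retrograde tracing

The mouse claustrum is a thin sheet of neurons wedged between the striatum
and the insula, with no anatomical border separating it from the overlying
cortex. A practical way to demarcate it is combinatorial labelling: genes
like *Nurr1* (*Nr4a2*) and *Nr2f2* are densely expressed **inside** the
claustrum, while *Tle4* labels the surrounding deep cortical layers and is
conspicuously **absent** from claustrum projection neurons, which can
themselves be tagged by retrograde tracing from cortical targets. `clamap`
implements the quantitative image-analysis pipeline behind this approach as
reusable, tested R code, exercised end to end on synthetic multi-channel
confocal slices with known ground truth:

- **synthetic slice simulator** — an elliptical claustrum-like zone of
  marker-positive cells inside a surrounding Tle4 band, rendered into
  1024×1024, 11-plane z-stacks (2 µm steps over 20 µm) with configurable
  per-pair colocalization fractions, Poisson + Gaussian noise, and full
  ground truth;
- **stack I/O and maximum-intensity projection** (multi-page TIFF + JSON
  sidecar);
- **cell detection** — Gaussian smooth → Otsu threshold → connected
  components → peak splitting → intensity-weighted centroids (µm);
- **colocalization** — greedy nearest-centroid matching within 5 µm,
  Venn-style counts n(A), n(B), n(A∩B) and fractions per slice, mouse and
  cohort, with anterior/middle/posterior subdivisions assigned from bregma
  coordinates;
- **zone delineation** — the enriched zone as the outer contour of the
  KDE superlevel set containing ≥ 90 % of a channel's cells; the Tle4-devoid
  zone as the anchor-containing sublevel region; vertex-mean centroids and
  centroid-aligned cross-animal overlays with occupancy maps;
- **intensity profiles** — 0.1 mm strip means along the external-capsule
  axis and its perpendicular, z-scored, realigned to the retrograde peak and
  averaged into mean ± SD envelopes;
- **group statistics** — pooled-variance unpaired t-tests (df = n1+n2−2)
  and one-way ANOVA with Bonferroni-corrected protected post hoc
  comparisons, with the mouse as the statistical unit.

## Worked example

Simulate one default slice, detect the retrogradely labelled cells on its
maximum-intensity projection, and outline the enriched zone:

```r
library(clamap)

cfg <- generator_config(seed = 7)        # 1024 um frame, 11 z-planes
truth <- sample_cells(cfg)
sum(truth$cells$retro)
#> [1] 80

vol <- render_slice(truth, cfg, channels = "retro")
cells <- detect_cells(max_project(vol, "retro"), detection_config())
poly <- delineate_enriched_zone(cells, zone_config())
poly
#> <clamap_zone_polygon> enriched/retro: 33 vertices, centroid (497.0, 505.6) um, contains 91.3%
```

`contains 91.3%` is the fraction of detected retro cells inside the returned
polygon — the ≥ 90 % enrichment rule the delineation enforces by
construction. The devoid zone is anchored at that polygon's vertex centroid:

```r
tle4 <- cellset_from_truth(truth, "Tle4", config = cfg)
delineate_devoid_zone(tle4, vertex_centroid(poly), frame_um = c(1024, 1024))
#> <clamap_zone_polygon> devoid/Tle4: 40 vertices, centroid (439.6, 471.0) um, contains 0.0%
```

(near-zero containment here means the Tle4-devoid polygon excludes
essentially all Tle4 cells, as it should).

The `analysis/` directory holds the numbered workflow scripts
(`01_simulate.R` … `06_stats.R`) that run the full pipeline on synthetic
cohorts and write their tables under `results/`. Representative output:

```
$ Rscript analysis/03_colocalization.R
cohort colocalization fractions (mean over 6 mice, pooled subdivisions):
  Nurr1:Tle4   0.025 +/- 0.007
  retro:Nr2f2  0.837 +/- 0.028
  retro:Nurr1  0.892 +/- 0.011
  retro:Tle4   0.018 +/- 0.011

$ Rscript analysis/06_stats.R
Nurr1: naive 10.4% -> OF 25.7% (+15.3 points), t(13) = 22.53, p = 8.4e-12 ****
Tle4:  naive  3.9% -> OF  6.4% (+2.5 points),  t(13) = 6.11,  p = 3.7e-05 ****
Nurr1 colocalization across modules: F(3, 15) = 80.6, p = 1.8e-09 (****)
```

The measured cross-channel fractions sit slightly above the configured
generator values (e.g. 0.892 vs 0.87) because a 5 µm spatial criterion also
captures occasional chance-adjacent cells — see the methods vignette for why
this is expected of any distance-based colocalization measure.

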