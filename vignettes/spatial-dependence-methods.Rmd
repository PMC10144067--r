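---
title: "Assessing spatial dependence in breeding fields: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing spatial dependence in breeding fields: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldlisa)
```

## The problem

A breeding trial sows many germplasms in replicated plots and compares
their phenotypes. The comparison is only fair if the field treats every
plot alike. Terrain is a common reason it does not: on a sloping,
poorly drained field, water accumulates downslope, and a moisture-
sensitive crop such as kenaf grows visibly worse there. The question
`fieldlisa` answers is *whether* such spatially structured growing
conditions exist, *where* they are, and *how* to block the field so
that future randomizations compare entries within — not across —
environmentally similar zones.

The input is deliberately minimal: two co-registered single-band
elevation rasters in a planar metric CRS (a bare-ground DTM and a crop-
surface DSM, e.g. from a UAV photogrammetry product) and a table of
plant positions with plot and germplasm labels. Everything downstream
is computed by the package.

## From rasters to per-plant heights

The canopy height model is the per-cell difference `DSM − DTM`. Each
plant's height estimate is the **maximum** height-map value over cells
whose centers fall within a circle of 40 cm diameter around the sowing
point. The maximum (rather than the mean) is robust to the small
georeferencing offsets between map and plant coordinates and to the
fact that most buffer cells cover soil or leaves below the apex; the
cell-center-in-circle rule avoids partial-cell ambiguity. Enlarging the
buffer can only increase the estimate (a tested invariant), so the
diameter should stay below the plant spacing to avoid capturing a
neighbor's apex; at the default 25 cm spacing the 40 cm buffer slightly
overlaps neighboring plants of the same ridge, which is acceptable
because within-plot neighbors share a germplasm.

Heights are then standardized over all plants of the acquisition date
jointly, using the population (divide-by-N) standard deviation. This
convention makes the second moment `m = Σ z² / N` equal to 1, which
simplifies the local Moran statistic below; it also means z-scores are
comparable across the whole field, not within germplasms — intentional,
since the spatial analysis asks about field position, not genotype.

Plants with `z < −1.646` (the lower ≈5% of the standard-normal
cumulative probability) are flagged as outliers — mostly failed or
heavily damaged individuals — and excluded from the spatial analysis.
The z-scores are *not* re-standardized after removal: the cutoff is a
screening rule, not a model assumption, and re-normalizing would shift
every remaining score for reasons unconnected to the field. (The
conventional 5% normal quantile is −1.645; the package default keeps
the slightly more conservative −1.646 used in the field protocol it
follows, a difference that moves the removed fraction by well under
0.01 percentage points.)

## Local Moran's I and its inference

For plant *i* with standardized value `z_i`,

```
I_i = (z_i / m) * sum_j W_ij z_j,     m = sum_i z_i^2 / N
```

`W` is a binary distance-band weight matrix: `W_ij = 1` when plants *i*
and *j* lie within the threshold distance, 0 otherwise, `W_ii = 0`. The
default threshold of 1.75 m is the largest distance between plants of
adjacent plots under the default layout, so every plant has at least
one neighbor from another plot — essential, because purely within-plot
neighborhoods would measure genotype similarity, not field structure.
An inverse-distance variant (`1/d_ij` within the band) is available;
binary is the default because the quadrant classification depends only
on the sign of the spatial lag, which any positive rescaling of a
weight row preserves (a tested invariant).

The sign pair (`z_i`, lag) places each plant in a Moran-scatterplot
quadrant: H-H, L-L, L-H, H-L, with zeros tie-broken to the "high" side.
Significance uses **conditional permutations**: holding `z_i` fixed,
the values of its `|N(i)|` neighbors are re-drawn without replacement
from the other N−1 observations; 999 redraws give a reference
distribution for `I_i`. With `R` the count of permuted statistics at
least as extreme as the observed one, on the observed side of the
permutation mean, the folded one-sided pseudo p-value is
`(R + 1) / (M + 1)`.

**Sidedness.** The folded rule picks the tail *after* seeing the
statistic. Because the observed statistic's rank among the M + 1
exchangeable values is uniform under spatial randomness, the folded
rule flags both tails and its realized size is about twice the nominal
level (≈2% of locations at α = 0.01). The package therefore defaults to
the **two-sided** pseudo p-value — the folded value doubled and capped
at 1 — whose size matches its nominal level exactly at the default
settings (with M = 999 and α = 0.01, `2·⌊0.01·1000/2⌋/1000 = 0.01`);
this calibration is verified by a Monte Carlo suite under complete
spatial randomness. The folded variant remains available
(`sided = "folded"`) for compatibility with common LISA software, where
its minimum attainable value is `1/(M+1)` = 0.001 at 999 permutations.

Points flagged at `pseudo_p ≤ alpha` (default 0.01) keep their quadrant
label; all others, and isolated points (no neighbor within the band,
reported with a warning, never silently dropped), are labeled NS.

The implementation is checked against independent oracles rather than a
reference library: the additivity identity `Σ_i I_i = S0 · I_global`
against a brute-force double-sum global Moran's I, a hand-derived
three-point chain, exhaustive enumeration of all conditional
arrangements at N = 6, and the row-standardized Moran-scatterplot slope
identity. The permutation kernel is a short C++ routine (partial
Fisher–Yates per draw) driven by R's RNG, so all results are
reproducible from integer seeds.

## Cluster regions, zones, and replicate tests

Per-plant classes are aggregated to plot resolution: a plot joins the
low-growth region when at least `min_fraction` (default 0.5) of its
non-outlier plants are significant L-L, and the high-growth region
analogously for H-H. The 0.5 default makes double membership impossible
except by exact tie (a raised error at permissive thresholds); it is
the package's own operationalization of "intensively clustered" —
field practice often draws these regions by hand, which is not
reproducible. Regions are unions of plot rectangles, not smoothed
polygons: plots are the unit of management, and plot-resolution regions
are directly testable. Zones A (low-growth region), B (high-growth) and
C (all other plots, including bare ones) always partition the field.

Replicate similarity is tested per germplasm with the Kruskal–Wallis
test (tie-corrected, chi-square approximation — adequate at ~15 plants
per plot; an exact test is not provided) across its replicate plots,
followed by Dunn's post hoc z on pooled tie-corrected ranks with
Benjamini–Hochberg step-up correction within each germplasm's
comparison family. Because replicate plots carry identical seed,
small p-values indicate positional (environmental) effects. The
Wilcoxon rank-sum helper (exact enumeration when the smaller sample has
≤ 8 values and no ties, normal approximation without continuity
correction otherwise, explicit `alternative`) supports two-group
comparisons such as soil-moisture contrasts between zones; the caller
chooses the direction. Kruskal–Wallis, Wilcoxon and the BH adjustment
delegate to R's `stats` functions; Dunn's z is implemented here.

## The synthetic field generator

The generator emulates the study system that motivated the package:

- **Layout** — 24 germplasms × 3 replicates = 72 plots on an 8-wide
  grid, 15 sowing points per plot in a single ridge row at 25 cm
  spacing, 50 cm between plots, germplasm-to-plot assignment a uniform
  random permutation under the seed. Plot rectangles add a 0.25 m
  margin around the sowing row (real plot dimensions are rarely
  reported; only spacings are).
- **Terrain** — a plane descending 2 m toward the northwest (azimuth
  315°) across the field plus smoothed Gaussian roughness (sd 0.05 m,
  2 m correlation length). With zero roughness the raster is an exact
  plane, which the recovery tests exploit.
- **Growth** — each germplasm gets a relative vigor drawn once per
  trial (sd 0.125 around 1) and scaled by a stage-typical height
  (1.2 m early season, 2.5 m late), so the genotype ranking is shared
  across acquisition dates and only phenology and noise differ — the
  basis of the cross-date persistence checks. One entry ("EF-2") fails
  to germinate, leaving three bare plots. The environmental effect is a
  logistic ramp of terrain elevation between the field's 10th and 40th
  elevation percentiles, falling to a 0.6 multiplier at the bottom —
  a smooth, monotone stand-in for moisture-driven suppression in the
  poorly drained low corner. Per-plant Gaussian noise (0.08 m early,
  0.15 m late) is truncated so heights stay non-negative.
- **Rendering** — the DSM equals the DTM plus a cosine-tapered crown
  (radius 0.12 m) per plant whose apex cell carries the exact true
  height, overlaps resolved by maximum, plus Gaussian render noise
  (0.02 m, clamped at DTM − 3 sd). The default raster resolution is
  5 cm/pixel; centimeter-scale products can be configured but are
  heavier than routine testing needs.

With all noise terms at zero the full pipeline returns every true
height exactly; with the environmental effect switched off and equal
vigor the heights are exchangeable across the field, providing the null
configuration under which the LISA flagging rate is checked against its
nominal level. What the generator does **not** emulate: photogrammetric
reconstruction artifacts (doming, blurred crowns, shadows),
georeferencing error between dates, ridge/furrow microtopography, and
within-plot competition. Passing the synthetic suites therefore
demonstrates the statistical machinery and its calibration, not the
photogrammetric robustness of the extraction step on real imagery —
on real data the plot-max height regression (R² ≈ 0.8 is typical for
UAV canopy height models of thin-stemmed crops) is the check to run,
via `validate_heights()`.

## Numerical choices and degenerate inputs

- Constant extracted heights raise a degenerate-variance error rather
  than returning NaN z-scores.
- A buffer smaller than one raster cell is rejected; a buffer
  containing only nodata cells drops the plant with a warning.
- Misaligned DSM/DTM pairs (shape, cell size or origin) raise an
  alignment error instead of recycling silently.
- Permutation tie handling: permuted statistics within `1e-12·(|I|+1)`
  of the observed value count as ties, absorbing float rounding from
  the different accumulation order of observed and permuted lags.
- All randomness flows through explicit integer seeds with
  save/restore of the global RNG state; identical configurations give
  byte-identical output files (md5-verified in the test suite).

## Problem sizes used by the test and acceptance suites

The suites run the default 72-plot field (≈1,080 plants, ≈60 neighbors
per plant at 1.75 m) with 999 permutations in a few seconds per stage;
null-calibration uses 50 replicates of 200 random points; the
Kruskal–Wallis type-I suite uses 2,000 simulations of 3 × 15 values.
These sizes give Monte Carlo standard errors comfortably below the
tolerances they are checked against while keeping a full run under a
minute on one CPU.
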