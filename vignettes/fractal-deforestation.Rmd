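---
title: "Methods: local connected fractal dimension and LCFD thresholding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: local connected fractal dimension and LCFD thresholding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fractalfrag)
```

## The problem

Deforestation in tropical frontier landscapes is not a single process. It
starts as perforation (scattered clearings inside intact forest) and
dissection (roads and linear infrastructure), passes through fragmentation
(the forest mosaic breaks apart), and ends in shrinkage and attrition of
the remaining forest patches. Patch-count metrics summarize a landscape in
one number per date; they say little about *where* forest loss is isolated
and simple versus connected and aggressively expanding. The local connected
fractal dimension (LCFD) answers that at pixel resolution.

## The LCFD model

Input is a binary landscape: a boolean lattice with `TRUE` for deforested
cells and a physical cell size (30 m by default, the resolution of
Landsat-derived land-cover products). At each deforested pixel:

1. **Locally connected set.** The 8-connected cluster containing the focal
   pixel is traced inside the window of the largest scanning box (31×31
   pixels by default), clipped at the image border. Pixels of other
   clusters inside the window are excluded. The set is traced once, at the
   largest scale, and reused for all smaller boxes.
2. **Box-counting masses.** For each scheduled box side
   `ε ∈ {3, 7, 11, 15, 19, 23, 27, 31}`, `M(ε)` is the number of
   connected-set pixels inside the ε-box centered on the focal pixel.
   Boxes are clipped at the border, and masses use the available cells.
3. **Dimension.** The LCFD is the unweighted ordinary-least-squares slope
   of `log M(ε)` against `log ε`. The log base cancels in the slope.

Three geometries anchor the scale: a fully foreground neighborhood has
`M(ε) = ε²`, hence LCFD exactly 2; a unit-width straight line has
`M(ε) = ε`, hence exactly 1; an isolated pixel has `M(ε) ≡ 1`, a constant
profile whose slope is 0. The useful interpretive range is
`1 < LCFD ≤ 2`: the farther above 1, the more the cleared neighborhood
fills the plane.

Assumptions worth stating: the dimension is *local* (nothing beyond the
31-pixel window matters), connectivity is 8-neighbor throughout, and the
regression uses all scheduled scales without goodness-of-fit filtering —
the per-pixel R² is retained as a diagnostic band instead. Values are not
clipped: ring-like geometries can exceed 2 and are reported as-is.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `scales` | 3, 7, …, 31 | pixels | box sides; odd, strictly increasing. At 30 m this spans 90–930 m, keeping the analysis local while leaving 8 points for the fit |
| `cell_size` | 30 | m | physical pixel side |
| `skip_margin` | `FALSE` | — | when `TRUE`, pixels closer than 15 px to a border are omitted instead of using clipped boxes |
| `connectivity` | 8 | — | patch and cluster adjacency rule |

**Border policy.** Clipping boxes at the border yields a full-coverage map
but depresses the dimension of margin pixels (a corner of a filled plane
sees only a quarter box). `skip_margin = TRUE` trades coverage for
exactness; the package's own anchor checks use it when every valued pixel
must equal the analytic value.

## Fragmentation metrics

The metric set is the standard patch-level family, computed on the same
8-connected patches as the LCFD: deforested area DA (ha), patch count NP,
patch density PD (patches per 100 ha), edge density ED (m of
foreground–background rook boundary per ha; image-border edges excluded by
default), mean Euclidean nearest-neighbor distance ENN_MN (m,
center-to-center between nearest cells of distinct patches; undefined when
NP < 2), and the clumpiness index. Clumpiness uses the adjacency form: with
`g_ii` the like rook adjacencies (ordered-pair double count), `Σg_ik` all
rook adjacencies involving foreground, `G = g_ii/Σg_ik` and `P` the
foreground proportion,

```
CLUMPY = (G − P) / P        if G < P and P < 0.5
         (G − P) / (1 − P)  otherwise
```

so a single-cell checkerboard (G = 0, P = 0.5) scores exactly −1, a
spatially random landscape scores near 0 and a consolidated block
approaches 1. The landscape-area denominator of PD and ED is an explicit
argument (defaulting to the raster extent) and is reported alongside the
metrics, because density columns are meaningless without it.

One caveat documented here because it is easy to assume otherwise: ED is
*not* monotone under adding foreground — filling a one-cell hole removes
four edge segments. Only DA is monotone under cumulative growth.

## LCFD thresholding

Segmentation thresholds are cut points on the LCFD distribution. Two
independent detectors are provided; their agreement is itself evidence that
a cut reflects real population structure.

### Concentration–area with wavelet maxima (CA-wavelet)

The exceedance area `A(ρ ≥ C)` of the LCFD list behaves as a power law
`C^(−β)` within one population; a change of exponent marks a population
boundary. The detector samples `log₁₀ A` on a uniform concentration grid
(256 levels by default; a flag switches to a log-spaced grid, on which a
pure power law is exactly linear), transforms it with Mexican hat wavelets
(two vanishing moments, so the transform is a multiscale second-derivative
operator) over 16 log-spaced scales from 2 to a quarter of the signal
length, and chains the per-scale local maxima of `|Wf(u, s)|` across
adjacent scales by nearest-position matching within `1 + s/2` samples.
Persistent maxima lines converge to the curvature anomalies — the
slope-change points.

Numerical choices, each of which mattered in development:

* **Reflective padding** suppresses boundary maxima; the discrete kernel is
  centered to exact zero mean, so adding a constant to the signal leaves
  the field unchanged (a property test on this invariant caught a
  reflection bug in an earlier revision).
* **Ranking**: persistence (scale span) first; ties break on the modulus at
  the line's *finest* scale. A genuine slope break retains fine-scale
  modulus, while the broad curvature of a smooth background decays rapidly
  toward fine scales — the standard modulus-scaling argument.
* **Edge exclusion**: lines ending within the finest kernel's support
  (5 × the smallest scale, in samples) of either end are discarded. Every
  bounded sample's exceedance curve plunges to `log A = 0` at its maximum;
  that end plunge is a curvature anomaly by construction and never a
  population boundary.
* **Tail support** (`min_tail_fraction = 0.01`): a cut must leave at least
  1% of the values on each side. A "threshold" separating 30 pixels from
  30,000 separates nothing.
* **Significance floor** (`min_modulus_frac = 0.01`): lines whose peak
  modulus is below 1% of the signal's total variation are binning noise.

The geometric cut at 1.0 — the dimension separating point-like from
line-like local sets — is always appended, whether or not a maxima line
sits near it.

### 1-D k-means with automatic k

The second detector clusters the LCFD value list (values only, no spatial
coordinates — the class value ranges are what define thresholds). Lloyd
iterations run from deterministic quantile seeding (centroids at the
`(i − 0.5)/k` quantiles), stop when the largest centroid displacement falls
below 0.001 or after 20 iterations, and reseed any emptied class at the
value farthest from its centroid. Deterministic seeding was chosen over
random restarts because seed-dependent thresholds are unacceptable in a
reporting pipeline; on 1-D data with separated populations the quantile
start is already close to the optimum, which the test suite verifies
against an exhaustive optimal-interval oracle at small n.

The number of clusters is picked by majority vote of four internal
validity indices computed on a seeded subsample (2000 values): mean
silhouette width, Calinski–Harabasz, Davies–Bouldin, and the
within-sum-of-squares elbow (largest second difference). Ties break toward
the smaller k. Thresholds are the midpoints between one class's maximum
and the next class's minimum; both raw bounds are retained in the output,
since reporting conventions differ on which of the three to quote.

### Classification

`classify_lcfd()` bins the map with half-open, lower-inclusive intervals:
class c covers `[cut_{c−1}, cut_c)`, and a value exactly at a cut belongs
to the class above. The convention is arbitrary but fixed, making class
counts reproducible; refining a threshold set never moves existing
boundaries. The per-class process annotation (below 1.0: perforation or
dissection candidates; 1.0 to the high cut: fragmentation; above:
shrinkage/attrition candidates) is an interpretive aid, not a detector —
spatial processes are defined by patch topology over time, which a single
map cannot establish.

## The synthetic generator

The generator exists so that every stage is testable against known
geometry, and its defaults are the package's reference conditions.

* The five processes are explicit morphological recipes: perforation
  stamps disjoint discs strictly inside forest (patch topology provably
  unchanged; deforested patch count rises by exactly the hole count);
  dissection carves a constant-width spanning strip (forest patch count
  1 → 2); fragmentation carves a strip grid ((n+1)² remnants); shrinkage
  dilates the deforested set with a disc; attrition deletes whole forest
  patches, smallest first, to a target area fraction. Hole sizes and strip
  widths have no quantitative source; the defaults (radius 2, width 2,
  two strips per orientation) were chosen once for visual similarity to
  the canonical process illustrations and are otherwise arbitrary.
* Cumulative growth is a seeded contact process: 25 nuclei on a 192×192
  lattice, per-step conversion probability 0.25 for forest cells touching
  deforestation (8-neighborhood), spontaneous clearing at 2×10⁻⁴ per cell
  per step, 7 steps — mirroring the seven cumulative periods of a
  multi-decade Landsat record at a size where the full pipeline runs in
  seconds. With conversion probability 1 and no spontaneous births the
  process is exactly the Chebyshev ball dilation, which the tests exploit.

What the generator reproduces is *qualitative*: monotone cumulative area,
rising clumpiness, contracting-then-stabilizing nearest-neighbor distance,
and a left-heavy LCFD distribution early in consolidation. What it does
not emulate: anisotropic road networks, topographic and land-tenure
constraints, multi-class land cover, spatially correlated conversion
pressure, or the absolute scale of a real study region (millions of
hectares). Passing tests therefore demonstrate correctness of the
machinery and the expected direction of every trend, not calibrated
realism.

Two planted-value generators support the detector tests:
`simulate_two_regime()` draws values by inverse-transform sampling of a
piecewise power-law survival function, so the regime-change position is
known exactly. Because the support is truncated, the upper regime is a
clean power law only while `S(C)` is large against the truncation mass —
the detector is robust to this, but global two-segment fits are not, which
is why the piecewise-linearity check in the tests widens the support. The
method-agreement fixture is a density *step*: a dense uniform body below
the break (65%) and a sparser uniform tail above it. A smooth bimodal
mixture was considered and rejected: the wavelet detector provably
converges to the curvature shoulders of a smooth trough, not its center,
so only a genuine slope discontinuity gives both detectors the same target.
On that fixture the k-means boundary is evaluated at k = 2, the number of
planted populations; the automatic k sometimes prefers 3, whose extra
boundary quantizes the uniform segments and is unrelated to the break.

## Verification design

The LCFD engine is verified bit-for-bit against an independent oracle that
re-derives every pixel from scratch — flood fill by repeated 8-neighbor
dilation, direct box counts, and an `lm()` fit — on seeded random masks
(40×40 in the acceptance suite, 20 masks). Patch labeling is checked
against iterative label propagation on every one of the 65,536 4×4 binary
grids. Threshold recovery is measured over 50 seeded two-regime syntheses
with breaks drawn in [1.2, 1.8] (median absolute error in concentration
grid steps), and k-selection over planted five-component Gaussian mixtures
with component means 0.1, 0.5, 1.0, 1.4, 1.8 and σ = 0.03. The pipeline
determinism check reruns the full synthetic pipeline at a fixed seed and
compares output files byte by byte. Problem sizes (192×192 growth
lattices, 20,000-value distributions, 256-level concentration grids) were
chosen so the whole suite exercises every stage in about a minute on one
core.

## Degenerate inputs and tie-breaks

* Constant LCFD lists: the CA curve is flagged degenerate and only the
  geometric threshold is returned, with a warning; `select_k()` rejects.
* Empty masks: `lcfd_map()` warns and returns an all-missing map.
* `k` larger than the number of distinct values is rejected.
* Equal-distance k-means assignments go to the lower-indexed centroid
  (`ties.method = "first"`), another determinism guarantee.
* `ENN_MN` is reported missing when fewer than two patches exist; `Ratio`
  is missing for the first period and whenever the previous area is zero.

## Known limitations

* The LCFD border policy under clipping depresses margin values; use
  `skip_margin` for strict comparisons at the cost of a 15-pixel frame.
* The CA-wavelet detector resolves breaks no finer than the concentration
  grid and cannot see cuts in the outermost 1% tails by design.
* The process annotation is heuristic; it deliberately does not claim to
  detect the five spatial processes from a single date.
* Raster I/O is plain-text ASCII grid only; georeferencing is limited to
  an affine lower-left corner + cell size, with no CRS transformation.
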