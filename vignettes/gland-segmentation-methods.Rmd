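---
title: "Methods: blind color decomposition and morphology-driven gland segmentation"
author: "glandseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blind color decomposition and morphology-driven gland segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glandseg)
```

This vignette documents the models, parameters, and numerical choices behind
`glandseg`, in the spirit of a methods section: what is computed, under which
assumptions, and where the genuinely open design decisions were made.

## The decomposition model

Brightfield absorption imaging follows the Beer–Lambert law: a pixel carrying
stain densities $d = (d_s, d_e)$ (stromal, epithelial) transmits

$$I_c = I_{0,c}\, e^{-(M d)_c}, \qquad c \in \{R, G, B\},$$

where the columns of $M$ are the unit-sum optical-density direction vectors
("reference chromaticities") of the two stains. Optical densities
$\mathrm{od}_c = \ln(I_{0,c} / I_c)$ are therefore *additive* in the stains,
and the normalized vector $\mathrm{od} / \sum_c \mathrm{od}_c$ — a barycentric
point in the chromaticity triangle — depends only on the *ratio* of stain
contributions, not on staining intensity. This is the key decoupling: tissue
thickness, stain concentration, and exposure scale the OD vector but leave the
chromaticity point fixed (an exact invariance, covered by a property test).

The model assumes (i) two absorbing stains, (ii) a locally constant
background intensity $I_0$, and (iii) negligible scattering. Assumption (ii)
is handled by estimating $I_0$ as the per-channel 99th-percentile intensity of
the tile (the unstained background estimate), overridable when a calibration
white is available. Zero intensities are clipped to one camera count before
the log, bounding the OD of opaque pixels; negative ODs (pixels brighter than
the estimate) are clipped to zero.

**Background exclusion.** Pixels with total OD below `minTotalOD = 0.10`
carry almost no color; their chromaticity is noise-dominated, and including
them would smear the stain clusters. They are excluded from the EM cloud (but
counted in the bookkeeping). This masking, together with ridge-regularized EM
covariances, stands in for an explicit sensor/biochemical noise model: what
matters downstream is robustness of the fitted references to background and
camera noise, which the tests exercise directly.

**EM fit.** Barycentric points are rank-2, so the mixture is fitted in an
orthonormal 2-D basis of the triangle plane (Euclidean distance there equals
the distance between barycentric vectors). Initialization is k-means++ under
the caller's seed followed by a k-means refinement; EM then runs full 2×2
covariances with a ridge of $10^{-6}$ on the diagonal, a log-likelihood
tolerance of $10^{-8}$, and a 500-iteration cap (exceeding it raises a
convergence error carrying the iteration count — heavily overlapped clouds
converge slowly, and callers fitting such clouds deliberately can raise the
cap). Clouds larger than 20,000 points are deterministically subsampled; the
fit is seed-deterministic and invariant to point order. Two component means
closer than `minSeparation = 0.02` in the plane are reported as a *degenerate
stain*: chromaticities that close cannot be distinguished as two stains, and
letting EM split a single noisy cluster would produce a nearly singular
mixing matrix and meaningless density maps. A single-stain fallback
(`fallbackSingleStain`) is available for tiles genuinely carrying one stain.

**Stain assignment.** Picrosirius red stains the stroma red, so of the two
fitted references the one with the larger red barycentric coordinate is
stromal (ties broken by the larger mixture weight).

**Unmixing and normalization.** Per pixel, densities solve a non-negative
least-squares problem against the two mixing-matrix columns. With two columns
the NNLS optimum has a closed form — the unconstrained solution when feasible,
otherwise the better of the two clamped single-column projections — which
vectorizes over the whole tile. Density maps are divided by `odScale = 2.5`
and clipped to $[0,1]$: the nucleus-intensity threshold of 0.7 presumes maps
on a fixed $[0,1]$ scale comparable across tiles, and 2.5 OD units is a
practical upper bound for single-stain absorption in well-stained sections
(the raw, unnormalized densities remain available via `normalize = FALSE`).

## The segmentation procedure

The stromal density map drives the segmentation; the epithelial map is used
only to verify nucleus presence. Glands are *low*-stromal-density regions
enclosed by high-density stroma, so the pipeline works from the stromal
border inward — which is what lets it find cribriform and fused patterns that
lumen-outward methods miss.

1. **Opening.** Grayscale morphological opening with a flat rectangular
   6 × 6 px kernel smooths gland boundaries and removes stromal specks. The
   kernel trades gland separation (larger) against gland grouping (smaller).
   Erosion and dilation use properly reflected structuring elements, so the
   operation is a true opening — idempotent and anti-extensive — also for
   even kernel sizes (property-tested).
2. **Mask.** Gradient-maximization thresholding: among 256 candidate levels
   on the map's range, choose the one maximizing the mean Sobel gradient
   magnitude over the boundary pixels (pixels 8-adjacent to the opposite
   class) of the thresholded image. The candidates are bin midpoints, so they
   are strictly interior to the range; ties break toward the lower threshold.
   An exhaustive independently-written search serves as the oracle in the
   tests. The below-threshold side is the gland-candidate mask.
3. **Seeds.** The gland-candidate foreground (the *inverted* stromal map) is
   eroded with per-pixel elliptical structuring elements derived from the
   structure tensor (Gaussian-smoothed outer product of the Sobel gradients,
   `tensorSigma = 3` px). The eigenvector of the smaller eigenvalue points
   along edges; the anisotropy $(\lambda_1-\lambda_2)/(\lambda_1+\lambda_2)$
   interpolates the SE from a disk (isotropic tissue) to an edge-aligned
   ellipse. Eroding the *inverted* map shrinks gland regions and severs thin
   inter-gland bridges — the reading under which "erosion separates weakly
   connected glands" is operative; eroding the stroma-bright map would merge
   them instead. The eroded map is binarized by the same thresholding rule,
   and connected components inside the mask become seeds.
4. **Watershed.** Marker-controlled watershed on the Sobel gradient magnitude
   of the (smoothed) stromal map — the figure-level description of the
   flooding surface — restricted to the mask. The priority queue orders by
   flooding value, then insertion order, making the result bit-deterministic.
5. **Filtering.** Regions smaller than `minObjectSize = 90` px (the mean
   epithelial nucleus size) are rejected as `too_small`; regions without a
   connected cluster of at least `minNucleusPixels = 10` pixels at epithelial
   density ≥ `minNucleusIntensity = 0.7` are rejected as `no_nucleus`
   ("sufficient pixels of high intensity" is not quantified in the source
   description; 10 px — about an eighth of a nucleus — is our configurable
   reading). Every rejection is recorded with its reason.

Relaxing any filter threshold can only grow the accepted set (a tested
monotonicity invariant); accepted regions each contain exactly their seed and
never extend beyond the mask.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `openingKernel` | 6 × 6 | px | boundary smoothing vs gland merging |
| `minObjectSize` | 90 | px | mean epithelial nucleus area |
| `minNucleusIntensity` | 0.7 | — | nucleus threshold in the normalized epithelial map |
| `minNucleusPixels` | 10 | px | smallest pixel cluster accepted as a nucleus |
| `erosionMaxAxis` | 9 | px | maximum **full** axis of the adaptive ellipse |
| `tensorSigma` | 3 | px | structure-tensor integration scale |
| `odScale` | 2.5 | OD | density-map normalization divisor |
| `minTotalOD` | 0.10 | OD | background exclusion for the EM cloud |

`erosionMaxAxis` is read as the full axis (semi-axis 4.5 px): the adaptive
ellipse must exceed the 6 × 6 opening scale but stay below the ~7 px radius
of the smallest meaningful objects (grade-5 single cells, 90–150 px), which a
9 px *semi*-axis disk would erase — defeating the stated purpose of the
adaptive element, preserving small glands.

## The synthetic forward model

`generateTile()` paints per-pixel densities — a spatially varying stromal
field (±10% smooth variation around 1.4 OD), epithelial cytoplasm at 0.9 OD,
nuclei at 2.3 OD, empty lumina — for parametric gland shapes (smoothed
random-radius star polygons; cribriform = gland minus interior disks; fused =
union of overlapping lobes under one instance id; single cells = 90–150 px
blobs with one nucleus), then renders RGB through the Beer–Lambert relation
with default references (0.60, 0.25, 0.15) for PSR-red stroma and
(0.30, 0.30, 0.40) for hematoxylin-purple epithelium — plausible directions
chosen once, since no numeric chromaticities are published. Realism knobs:
smooth multiplicative stain-intensity fields (CV 8%), additive Gaussian
camera noise (2 counts), and 1 px boundary blur. Noise-free, hard-boundary
tiles invert the forward model essentially exactly, which is what the
round-trip checks exploit.

What the generator does **not** emulate: real nuclear texture and chromatin
patterns, stain co-localization within nuclei, tissue folds, scanner
artifacts, out-of-focus regions, and the full morphological variability of
carcinoma. Passing the synthetic suite therefore demonstrates that the
algorithmic chain is implemented correctly and behaves as designed on
well-posed inputs — not that the pipeline reaches any particular accuracy on
clinical material.

The test suite and the acceptance script use tiles of 256–352 px and suites
of 7 tiles (≈ 24 gland instances plus traps), sizes at which every stage's
behavior is already fully exercised while the whole suite runs in well under
a minute.

## Evaluation taxonomy

Each predicted object receives exactly one of four categories. With
$p$ a prediction, $t$ its largest-overlap truth object:

- **over-segmented** — $p$ spans ≥ 2 truth objects, each covering ≥
  `coverageLow = 0.2` of $p$, or $|p| > |t| / 0.7$;
- **correct** (gland or non-gland, per the truth tag) — IoU ≥
  `iouMatch = 0.5` *and* $p$ covers ≥ `coverageHigh = 0.7` of $t$;
- **under-segmented** — otherwise.

Predictions overlapping no truth object are counted as correctly segmented
non-glandular objects (the stroma-resident vessels/nerves class of the
original taxonomy). The published categorization was performed visually by an
expert pathologist; these numeric thresholds are an automated proxy and are
deliberately prominent in the configuration. Summary percentages are
reported with two decimals and dot decimal separators; the headline accuracy
(objects neither over- nor under-segmented) and the gland/non-gland split
among accurate objects are rounded to integers.

## Numerical and degenerate-input conventions

- Coordinates are 0-based `(row, col)` in exported artifacts; connectivity is
  8-connected by default (4 available).
- Watershed ties: flooding value, then insertion order — deterministic.
- Threshold ties: lower candidate wins.
- Flat structure tensor (trace < $10^{-12}$): maximal disk.
- Constant maps cannot be thresholded (degenerate-input error); all-white
  tiles yield an empty chromaticity cloud (degenerate-input); coincident EM
  means or coincident mixing-matrix columns are degenerate-stain errors;
  cluster metrics on effectively single-cluster assignments are
  degenerate-cluster errors. Zero within-cluster scatter with distinct
  centers yields an `Inf` Calinski–Harabasz index with a warning.
- Errors carry condition classes (`glandseg_invalid_input`,
  `glandseg_degenerate_*`, `glandseg_convergence`, `glandseg_invalid_seed`),
  which the CLI maps to exit codes 2 and 3.

## Known limitations

- The two-stain model cannot represent a third chromophore (e.g. heavy
  pigment); a 3-component fit is configurable but unvalidated.
- The $I_0$ estimate assumes some background is visible in the tile; fully
  tissue-covered tiles need an explicit background intensity.
- Whole-slide processing (tiling, stitching, pyramid formats) is out of
  scope; the unit of work is a tile.
- Evaluation thresholds approximate, but cannot reproduce, expert visual
  judgment of segmentation quality.
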