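---
title: "msi2lmd: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{msi2lmd: models, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msi2lmd)
```

This vignette documents the science and engineering behind `msi2lmd`: the
models each module implements, the conventions that downstream results
depend on bit-exactly, the parameters a user may want to change, and what
the synthetic phantoms do and do not demonstrate about real data.

## Coordinate frames and conventions

The pipeline chains four planar pixel frames: the MSI acquisition grid
(`msi`, typically 70 µm pitch), the high-resolution optical scan of the
section with matrix (`optical`, ~2 µm per pixel), the H&E scan after
staining (`he`), and the microdissection stage (`lmd`). Everywhere in the
package:

* pixel indices are **0-based**, `x` is the column and `y` the row, `y`
  increases downward, and a coordinate refers to the **pixel center**;
* rasters are stored as R matrices with `values[r, c]` covering the pixel
  at `x = c - 1`, `y = r - 1`;
* ties in any nearest-integer rounding are resolved as `floor(v + 0.5)`
  (0.5 rounds up). `base::round()` rounds halves to even and would break
  the bit-exact warping and export tests.

These conventions match raster-image practice and make nearest-neighbor
warping unambiguous.

## Affine co-registration and its error budget

Transforms between frames are 2-D affines,
$x' = a x + b y + t_x$, $y' = c x + d y + t_y$, fitted from manually
selected control points by least squares (QR on the design matrix
$[x\; y\; 1]$, one linear model per output axis). Three non-collinear
pairs determine the transform exactly; more pairs are averaged in the
least-squares sense. Collinearity is declared when no triangle of source
points has area above $10^{-9}$ px², since the fit is then rank-deficient.

Registration accuracy is summarized per chain step from landmark
deviations. The estimator takes **signed** per-axis deviations in µm,
summarizes the **absolute** values by their mean, and attaches the
*sample* standard deviation (n − 1 denominator), with SD defined as 0 for
a single measurement. Neither the absolute-value convention nor the SD
denominator is forced by the problem; both are recorded here as the
package's convention, and `self_consistency_error()` (mean Euclidean
displacement after registering an image with itself) is provided for
reproducibility assessments of manual landmark picking.

Whole-chain worst-case errors assume additive effects: per axis, step
means add linearly and step SDs combine in quadrature,
$\sigma = \sqrt{\sum_i \sigma_i^2}$. Quadrature is the standard
combination for independent error components and is the package's
documented inference for the "maximum error" column; it reproduces the
published per-axis combined SDs from the per-step SDs, which the
acceptance suite verifies numerically. `dpi_to_micrometers()` is the
trivial 25 400/dpi conversion used to express optical-image pixels in µm.

## MSI data model, normalization, masking

An `msi_dataset` is a pixel-coordinate table plus a non-negative
pixels × channels intensity matrix and a strictly increasing m/z axis.
Two interchange formats are supported: a minimal **continuous-mode
imzML** reader/writer (shared m/z axis stored once; 64-bit little-endian
floats; standard IMS/MS controlled-vocabulary accessions, so files are
readable by common imzML parsers) and a diffable TSV dialect with the m/z
axis in a `#mz` header line. Processed-mode imzML (per-pixel m/z axes) is
out of scope.

TIC normalization divides each spectrum by its summed intensity, so every
retained spectrum sums to 1. A unit-sum target was chosen over mean-TIC
rescaling because it is the simplest contract consistent with "normalize
to total ion current" and the downstream factorization is scale-invariant
per pixel anyway. Pixels with an all-zero spectrum carry no usable signal
and are dropped with a report rather than propagated as NaN.

Pathologist annotations are vertex polygons in a named frame (usually
`he`). They are transformed into the MSI frame and rasterized by the
**even-odd** rule sampled at pixel centers, with no special casing of
boundary-touching centers. The pipeline default is mask-then-normalize;
since normalization is per-pixel the two orders give identical spectra
for the retained pixels, and the order only matters for the dropped-pixel
report.

## NNMF segmentation and silhouette model selection

Tumor spectra are factorized as $X \approx WH$ with $W, H \ge 0$ by the
classical multiplicative update rules minimizing the Frobenius loss —
the canonical NNMF algorithm. Initialization is uniform random
non-negative scaled to the data magnitude, derived deterministically from
the seed; by default 3 restarts are run and the lowest-loss fit kept.
Iteration stops after `max_iter = 200` sweeps or when the relative loss
improvement drops below `tol = 1e-6`. The loss trace is retained and
tested to be non-increasing (a property of the multiplicative updates).
Each pixel is labeled with its highest-scoring component, ties toward
the lowest component index.

The number of segments is selected in k = 2…5 by maximizing the mean
silhouette coefficient, $s(i) = (b_i - a_i)/\max(a_i, b_i)$ with
Euclidean distances, singleton clusters contributing 0 (the standard
convention, via `cluster::silhouette`). Silhouettes are computed on the
**TIC-normalized spectra**, not on NNMF scores: using the same metric
space for every k keeps the scores comparable across k. This choice is a
package decision; the alternative (scores) would entangle the metric with
the per-k factorization. For large inputs the silhouette is computed on a
seeded subsample of at most 2 000 pixels with every cluster kept
represented. Candidate labelings that collapse to a single non-empty
cluster are recorded with silhouette −∞ and skipped; ties between k
values go to the smaller k.

## Morphological ROI processing

The post-processing chain on the label image is, in order: opening →
per-segment split → small-area removal → hole filling → upscaling →
boundary tracing. Its operators reproduce the MATLAB semantics they are
modeled on, with the ambiguous details pinned down explicitly:

* **Opening** is grayscale (min-then-max filter) on the integer label
  raster with a 2×2 square. An even-sized element has no center; the
  anchor is the **top-left** pixel (erosion over the down-right window,
  dilation with the reflected element over the up-left window), matching
  `strel('square', 2)` whose origin is `floor((size+1)/2)`. Out-of-image
  samples act as +∞/−∞ for erosion/dilation. Opening a label raster as a
  grayscale image makes the result depend on the numeric order of labels
  where segments touch; `smooth_labels(per_segment = TRUE)` opens each
  binary mask independently instead.
* **Small-area removal** deletes 4-connected components of ≤ 30 pixels
  (so 31 pixels survive). The threshold and connectivity follow the
  published processing chain; the keep-rule "area ≥ 31" is tested
  bit-exactly at the 30/31 boundary.
* **Hole filling** fills background components that are 8-connected yet
  unreachable from the image border. Because the background is
  8-connected, an interior pocket that escapes through a diagonal step is
  *not* a hole — a hand-built 5×5 case in the tests checks exactly this.
* **Upscaling** to the H&E dimensions is inverse-mapping nearest-neighbor
  warping: each target pixel center is pulled back through the inverse
  affine and rounded per axis with `floor(v + 0.5)`.
* **Boundary tracing** is Moore-neighbor tracing with backtracking and
  Jacob's stopping criterion, one closed polygon per 8-connected
  component, outer boundary only (holes are ignored; they have been
  filled by this point in the pipeline). An isolated pixel yields the
  degenerate loop `[(x,y), (x,y)]`. Note that, as with any 8-connected
  contour tracer, inner corners whose only background contact is
  diagonal are traversed diagonally and do not appear as vertices.

The mixed connectivities (4 for area filtering, 8 for hole backgrounds
and tracing) are intentional and individually tested against flood-fill
oracles.

## LMD export

Boundary vertices (already in the optical frame) and the two non-origin
teaching points are translated by minus the origin teaching point, so the
origin maps to (0, 0), then rounded to integers. Translation preserves
pairwise vertex differences exactly, so the only distortion is the final
rounding (≤ 0.5 px per axis). The XML dialect is the Leica-style import
vocabulary — `ImageData` root, `GlobalCoordinates`,
`X/Y_CalibrationPoint_1..3`, `ShapeCount`, `Shape_i` with `PointCount`
and `X_j`/`Y_j` — frozen so that golden-file tests are byte-exact; the
writer is deterministic to the byte for a given document. Coordinates are
exported y-down (image convention); instruments expecting y-up can use
`flip_y = TRUE`. Export units are optical-image pixels relative to the
origin; a physical-unit export can be derived via `frame()`'s
`pixel_size`.

## Microproteomics statistics

Protein tables carry MaxQuant-style QC flags; rows flagged reverse, only
identified by site, or potential contaminant are removed (a row with
several flags is removed once, counted under each flag). LFQ intensities
are log2-transformed with zeros treated as **missing**, not log2(0);
rows with fewer than `min_valid` quantified segments are excluded and
reported. How the published workflow reduced its common-protein count to
the standardized set is not specified upstream, which is why the validity
filter is an explicit parameter rather than a guess. Each remaining row
is z-scored with the sample SD (population SD available as an option);
constant rows get z = 0 and are flagged.

A protein is called exclusively over-expressed in a segment when z ≥ +1
there and < +1 everywhere else; under-expression mirrors at −1. With
three segments and sample-SD scoring, the attainable |z| maximum is
$2/\sqrt{3} \approx 1.155$, so the ±1 threshold is attainable while ±1.2
can never fire — both asserted as sanity properties. A consequence worth
knowing: row-wise z-scores are scale-invariant, so with only three
segments *every* non-constant row reaches +1 or −1 and yields a call;
exclusivity at ±1 is therefore only selective jointly with upstream
filtering, effect-size screens, or more segments. The phantom tests
reflect this: planted markers are recovered exactly, while background
noise rows fire at the three-segment null rate (itself checked against a
Monte-Carlo oracle).

Hierarchical clustering follows the conventional Perseus-style recipe:
k-means preprocessing (default 300 clusters, 10 iterations, 1 restart,
seeded) followed by complete-linkage agglomeration of the centroids with
Euclidean distances; proteins inherit their centroid's leaf position.
When the requested pre-cluster count reaches the number of distinct rows,
k-means is skipped and each distinct row is its own centroid (k-means
would be a no-op). Dendrograms can be exported as Newick.

## Phantoms: what they emulate, and what they do not

The generators are pure functions of a `phantom_spec` plus seed and are
bit-reproducible. Defaults emulate the targeted study conditions: a
regular MSI grid at 70 µm pitch, a nominal m/z 350–1600 axis, three
spatially contiguous molecular populations, ~2 µm optical pixels (the
default MSI→optical scale is 35), a small rotation between optical and
H&E scans, and fiducial landmarks related by the ground-truth affines
with optional Gaussian selection jitter. Cluster signatures are sparse
non-negative peak patterns (a few dominant channels each, separation 5
above a 0.2 baseline, truncated-Gaussian noise of SD 0.25) so that NNMF
identifiability holds at a realistic signal-to-noise level.

What the phantoms do **not** emulate: realistic lipid spectral
correlation structures, intensity gradients and matrix effects across a
section, histological texture, tissue deformation during staining (the
affine model cannot absorb elastic distortion), or the
missing-value patterns of real LFQ data. Passing the phantom suite
therefore demonstrates the correctness of the algorithms under the
stated model, not segmentation performance on real tissue.

## Problem sizes and numerical tolerances

Test and acceptance runs use grids of 40×40 pixels × 60 channels for
model-selection recovery (10 seeds), 30×30 for the end-to-end pipeline
property (Jaccard > 0.8 against planted regions through the full
MSI→H&E→optical→LMD chain), up to 200 points for brute-force silhouette
comparisons, and 20-row instances for the O(n³) linkage oracle — sizes at
which the independent oracles stay exact and the full suite completes in
well under a minute. Key tolerances: affine round trips and compositions
1e-9; noiseless parameter recovery 1e-6; silhouette-vs-oracle 1e-10;
z-score normalization 1e-12; NNMF monotonicity slack 1e-10; singular
transforms rejected below |det| = 1e-12.

## Known limitations

* Registration is strictly affine; elastic deformation from staining is
  outside the model and shows up as residual error.
* The imzML support is deliberately minimal (continuous mode, external
  uncompressed float arrays); it is an interchange format, not a general
  mzML parser.
* Grayscale opening of the label raster can favor higher-numbered labels
  at segment contacts (see above).
* NNMF is non-convex: different seeds can yield different local minima;
  restarts mitigate but do not eliminate this.
* The LMD XML dialect covers shape import only; cutting parameters and
  instrument control are out of scope.
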