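---
title: "Methods: pixel-level shape descriptors for single microplastic items"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pixel-level shape descriptors for single microplastic items}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpmorph)
```

## The measurement model

`mpmorph` measures one isolated item per microscope image. The model behind
every descriptor is deliberately plain: after thresholding, the item *is* its
set of foreground pixels. All geometry is carried out on **pixel centers**,
which sit on the integer lattice, with (row, col) coordinates, 0-based,
origin at the top-left, rows increasing downward. No sub-pixel boundary
interpolation and no corner-corrected perimeter estimators are used anywhere;
the point of the approach is that plain pixel counting and chain-length
summation are already far more reproducible than on-screen manual dimension
lines, not that they are unbiased at the half-pixel level.

Assumptions the pipeline makes about its input:

* a single item of interest, darker or lighter than the background — when
  several regions survive thresholding (dust specks, noise), the largest one
  is the item;
* a roughly uniform background, so one global threshold separates the item
  (no illumination correction is attempted);
* square pixels of known physical size, if SI output is wanted.

## Stage by stage

**Grayscale.** ITU-R BT.601 luminance (`0.299 R + 0.587 G + 0.114 B`),
rounded half-up. The choice of weights is a design decision (camera pipelines
vary); it is irrelevant in practice because thresholds are user-chosen per
image against the same transform. Already-gray input passes through
unchanged.

**Thresholding.** A fixed, user-supplied threshold with explicit polarity:
`dark` keeps intensity ≤ th, `light` keeps ≥ th. Both comparisons are
*inclusive* — fixed here by decision, since "above/below" conventions differ
between implementations — which gives the exact duality
`mask(img, dark, th) == mask(255 − img, light, 255 − th)`, property-tested.
The default `th = 127` suits dark items on a bright filter; values between
52 and 127 are typical for that situation. Automatic (Otsu-style) threshold
selection is intentionally out of scope. A contrast report flags images with
foreground fraction 0 (transparent item, color matching the filter) or above
a ceiling (default 0.5 — almost always an inverted polarity), and the batch
pipeline skips those instead of failing.

**Labeling.** Two-pass Union–Find under 8-connectivity, written in C++
(`src/ccl.cpp`): pass one scans the raster top-left to bottom-right, each
foreground pixel inheriting the smallest label among its already-visited
neighbors (NW, N, NE, W) and recording unions otherwise; pass two resolves
roots and compacts labels to 1..K in order of first appearance, so labels
are fully deterministic. Union is by smaller root label with path
compression. Only the four *already-visited* members of the 8-neighborhood
are consulted during the forward scan — the full neighborhood is covered
because the remaining four neighbors examine the current pixel when their
turn comes. Equivalence with an independent flood-fill oracle (connected
components of the explicit 8-neighbor pixel graph, via igraph) is asserted
on hundreds of random masks.

**Background connectivity.** Foreground is 8-connected (fixed by the
method); background is taken 4-connected for hole detection. This is the
standard duality — making both 8-connected creates topological paradoxes
(a diagonal foreground line would both separate and not separate the
background).

**Contours.** Moore-neighbor tracing with Jacob's stopping criterion: start
at the uppermost-leftmost region pixel (its W and N neighbors are
necessarily background), scan the 8-neighborhood clockwise from the
backtrack position, move to the first region pixel found, and stop when the
start pixel is about to be exited in the initial direction a second time.
One-pixel-wide spurs are traversed out and back, so their two sides both
contribute length — exactly what the half-perimeter fiber estimator relies
on. Contour points are reported starting from the lexicographically smallest
(row, col) point; orientation is an internal detail that never affects
lengths.

*Inner contours.* Each hole (enclosed 4-connected background component)
contributes one inner contour, traced over **the hole's own pixels**. The
alternative — tracing the ring of region pixels around the hole — was
rejected because it makes the smallest hole (one pixel) contribute a
spurious 8 px of perimeter; with the chosen convention a one-pixel hole is a
single-point contour of length 0, an annulus still gets its full inner
boundary, and compactness still strictly grows when a hole is punched into a
solid shape (F drops). Total perimeter = outer + all inner lengths; steps
count 1 axially and √2 diagonally.

**Geometry.** Convex hull by Andrew's monotone chain (strict turns, so no
collinear vertices are retained). Maximum Feret from the rotating-calipers
antipodal-pair enumeration; minimum Feret as the smallest hull-edge-normal
width (the minimal width of a convex polygon is attained perpendicular to an
edge). The minimum-area rectangle scans hull-edge directions (the optimum
has a side collinear with an edge), ties broken by the smaller angle;
`length ≥ width` is enforced even though one published table of the method's
output suggests the original software did not sort the sides — imitating
that would be reproducing a defect. Angles are degrees in [0, 180) from the
column axis. Degenerate inputs are defined, not errors: a single point has
Ferets (0, 0); a collinear set has min Feret 0 and rectangle width 0, and
elongatedness is then reported `NA` with a `degenerate_width` flag.

By default geometry sees pixel *centers*, so a 10×10 square region has
max Feret 9√2 and rectangle sides 9×9. The `pixel_extent` option instead
builds the hull over the four corners of every boundary pixel, adding the
physical extent of the pixels (between 1 and √2 px on Feret measures). It is
off by default because the rest of the pipeline (area as count, perimeter as
center-to-center chain) is center-based, and mixing conventions inside one
record should be explicit, not silent.

**Moments and ellipse axes.** Normalized central moments
`M_ij = (1/F) Σ (r₀−r)ⁱ (c₀−c)ʲ` over region pixels give the equivalent
ellipse semi-axes `Ra, Rb = √(8(M20 + M02 ± √((M20−M02)² + 4 M11²)))/2`.
The published formula for these axes is typographically corrupted in its
source; this reconstruction is the standard moment-ellipse form and is
anchored by the analytic check that a continuous disk of radius r
(`M20 = M02 = r²/4`) yields `Ra = Rb = r`. Rasterized rotated ellipses with
semi-axes ≥ 8 px recover both axes within 3% (tested).

**Circularity and compactness.** `F/(d_max² π)` and `P²/(4Fπ)`.
Compactness uses the **total** perimeter (holes make a shape less compact);
`d_max` is the maximum centroid-to-contour distance over outer *and* inner
contours. Digital effects can push a disk's circularity marginally above 1
(the traced contour sits about half a pixel inside the continuous circle),
so the reported value is clamped to [0, 1] with a `clamped_circularity`
flag; the pre-clamp value is what the acceptance targets report. Single
pixels are defined as circularity 1, compactness 0, axes (0, 0), flagged
`single_pixel`, never dropped.

**Fiber length.** Half the outer contour length. The out-and-back traversal
of a thin strand makes this ≈ centerline length; width and end curvature
bias it upward. Holes are excluded on purpose: a fiber coiled into an
internal spiral defeats the estimator, and adding inner contours would make
the estimate worse, not better.

## The synthetic world

The generator emulates what the measurement stages actually consume: one
dark item on a bright, mildly noisy filter. Defaults (chosen once, stated
here, not tuned):

* **canvas 200×200 px** per scene — desk-scale stand-in for 2048×1536
  camera frames; every algorithm is resolution-independent;
* **background 200, item 80, threshold 127 dark** — a dark item on a bright
  filter with the threshold between the modes, matching the regime in which
  fixed-value thresholding is appropriate at all;
* **noise SD 8** — leaves > 5σ between each intensity population and the
  threshold, so thresholding recovers masks essentially exactly (< 0.5%
  pixel error is asserted even at SD 10); the method under test is the
  morphometry, not denoising;
* **particles**: disks r ∈ [8, 30], rectangles 20–70 × 8–50, ellipses with
  semi-axes 10–40 / 5–32, all uniformly rotated; **fibers**: 5-segment
  random-heading polylines (segment 20–45 px, heading increments ±0.9 rad),
  3–7 px wide. These sit in the hundreds-of-pixels range that sub-millimetre
  items occupy at typical stereomicroscope scales.

Rasterization is by **pixel-center inclusion** (a pixel belongs to the shape
iff its center does; rectangles use half-open intervals so integer-sided
axis-aligned rectangles cover exactly length × width centers), matching the
pixel-center convention of the measurement side. Fibers are capsules: pixels
within width/2 of the centerline. Loop ("twisted") fibers close the
centerline into a ring, guaranteeing a hole.

What the generator does **not** emulate: blur/PSF, illumination gradients,
texture, translucency, touching items. A green round-trip test therefore
establishes correctness of the pixel pipeline on well-separated intensities
— it says nothing about segmentation quality on hard real images, which the
contrast report is there to catch and skip.

## Numerical and acceptance-scope decisions

* RNG: every stochastic fixture takes an explicit seed; the generator saves
  and restores the caller's RNG state, so test results cannot depend on
  execution order.
* Ties: largest-region selection breaks area ties by smallest label;
  rectangle fits break area ties (within 1e-9) by smaller angle.
* The min-area-rectangle oracle is a 0.01° rotation scan; agreement is
  asserted to 0.1% with the exact result required to be ≤ the scanned one.
* **Disk-area recovery radii.** Pixel-center disk areas fluctuate by
  O(r^{2/3}) (lattice-point counting), which crosses the 2% band below
  r ≈ 10 (r = 8 counts 197 vs πr² = 201.06, −2.02%). The acceptance check
  uses radii 20–64 — the scale of the worked examples and of real items —
  and this paragraph is the documentation of that boundary.
* **Fiber-length acceptance domain.** The (width + 2) px accuracy band for
  the half-perimeter estimator holds on the estimator's design domain:
  *thin strands* (width ≤ 3 px) along lattice directions, centerline
  endpoints on pixel centers. It cannot hold more generally, for two
  analytic reasons: a continuous capsule's rounded ends alone contribute
  πw/2 of overestimate (> w + 2 once w > ~3.5), and off-lattice
  orientations inflate the unit/√2 chain length by up to ~8% of the
  *length* (worst near 22.5°), which no length-independent band can absorb.
  Both regimes are still tested — at their correct analytic bound
  (0.083·len + πw/2 + 2, overestimation non-negative) — in the regular
  suite; the acceptance block asserts the tight band only where it is true.

## Known limitations

* Perimeter (and everything downstream: compactness, fiber length) carries
  the chain-code orientation bias described above; this is inherent to the
  method's stated no-sub-pixel policy.
* Jacob's stopping criterion has rare pathological shapes on which Moore
  tracing can stop early; an iteration cap turns any such case into a hard
  error rather than a silent truncation (never observed in the suites).
* One item per image: overlapping or touching items are measured as one
  region.
* Fibers with internal spirals: fiber length is reported but known to be
  meaningless (the holes are visible as `n_holes > 0` in the record).
* TIFF input is not supported in this build (no TIFF reader available);
  PNG, JPEG and PGM/PPM are.
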