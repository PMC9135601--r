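---
title: "Methods: fuzzy-transform compression, FGFCM segmentation and metric measurement of wound images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fuzzy-transform compression, FGFCM segmentation and metric measurement of wound images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundimg)
```

`woundimg` implements the server-side analysis of pressure-ulcer
photographs: per-band compression, fuzzy segmentation, contour extraction,
marker-based metric measurement, and a protocol that quantifies how much
quality the compressed analysis path loses relative to the original path.
This vignette is the package's account of the underlying methods, the
choices that were genuinely open, and what the synthetic test bed does and
does not establish.

## Coordinate and intensity conventions

All stages operate on single-band images: matrices of integer intensities
in [0, 255], row-major, origin at the top left, 0-based pixel coordinates,
each pixel a unit square centred on its integer coordinate. Every
intensity rounding in the package is *round half up* (`floor(x + 0.5)`),
chosen once so that denormalized memberships behave predictably
(`0.5 → 128`); base R's half-to-even rounding is never applied to
intensities. Size normalization (`normalize_image`) is a corner-aligned
bilinear stretch to 192×192 — corner pixels are sampled exactly, and
resizing an image to its own size is the identity. Only geometric
normalization is performed: any intensity standardization belongs to
downstream consumers, not to this pipeline.

## Block F-transform compression

A band is cut into `B×B` blocks (`B ∈ {4, 8, 16}`); the last block on an
axis is shrunk when the size is not a multiple — padding would invent
border intensities and bias the fidelity measurements. Each block axis
carries a uniform triangular fuzzy partition with `b` nodes placed from
the first to the last pixel of the block; the triangles overlap so that
memberships sum to one at every pixel (Ruspini condition), which is what
makes the transform exact on constant blocks. The direct transform stores
the `b×b` partition-weighted means; the inverse transform reconstructs
the block as the basis-weighted sum of coefficients. The achieved
compression rate is `ρ = b²/B²`; a requested rate is mapped to the
catalogue pair with the nearest achievable `ρ`, ties toward the smaller
block, and a request of exactly 1 is flagged as an identity pass-through
rather than built as a degenerate `b = B` partition.

Coefficients are kept as reals throughout; rounding to gray levels happens
only when a coefficient image or a reconstruction is materialized. This
keeps the compress→segment path and the brute-force oracle comparisons in
the test suite exact to 1e-9. Because every coefficient is a convex
combination of intensities, coefficients and reconstructions are
automatically inside [0, 255]; clipping is a guard, not a correction.

The coefficient tiles, assembled in block order, form a smaller image
(96×96 for a 192×192 band at `ρ = 0.25`) on which segmentation runs
directly — that is the point of compressing before segmenting: the
expensive per-pixel stages see ¼ of the pixels.

## FGFCM segmentation

Segmentation follows the fast-generalized fuzzy c-means scheme: a local
pre-filter absorbs spatial context once, and clustering then operates on
the gray-level histogram, making its cost independent of image size.

The pre-filter replaces pixel *i* by the weighted mean of its neighbours
(3×3 window by default; the centre pixel carries no weight). A neighbour
*j* at Chebyshev distance *d* contributes
`exp(-d/λ_s) · exp(-(x_j - x_i)²/(λ_g σ_i²))`, where `σ_i²` is the mean
squared deviation of the neighbourhood from the centre. When the whole
neighbourhood equals the centre, `σ_i = 0` and the pixel is left
unchanged — the natural limit of "similar gray → high weight" without a
0/0. Defaults `m = 2`, `λ_s = 3`, `λ_g = 6`, radius 1, tolerance `1e-5`,
100 iterations are the canonical settings for this family and are all
exposed in `fgfcm_params()`.

Clustering minimizes `J = Σ_l Σ_k γ_l u_kl^m (ξ_l − v_k)²` over the gray
levels `ξ_l` present in the filtered image with histogram weights `γ_l`,
by the standard alternating updates. The objective is recorded after each
full update pair, so the trace is provably non-increasing and the test
suite asserts it. Centroids are initialized at the `(k+0.5)/C` quantiles
of the filtered histogram — deterministic, so identical inputs give
bit-identical results; the `seed` parameter is reserved for a future
stochastic initialization. A gray level that coincides with a centroid
receives crisp membership split over the tied centroids. Images with
fewer distinct filtered gray levels than `C` are rejected as degenerate
rather than silently producing duplicate clusters.

Cluster identity everywhere downstream is *ascending centroid order*; the
denormalized cluster image `k` has pixel values `round(255·u_k)`, so the
C images sum to 255 ± 1 pixelwise. The number of clusters is a clinical
choice; 3 is the default used throughout (lesion, transition, skin is the
typical reading on a single band).

## Canny contour extraction

The "denoising window" is an explicit parameter: a Gaussian kernel of
side `w` with `σ = w/6` (the common rule that puts ±3σ at the kernel
edge). Gradients are 3×3 Sobel with replicate padding; the one-pixel
border is excluded from gradient support. Non-maximum suppression
quantizes the gradient direction to four sectors and keeps a pixel only
if it is strictly greater than the neighbour on one side and at least
equal on the other — the asymmetric tie-break keeps an ideal step edge
one pixel wide instead of two. Hysteresis is 8-connected propagation from
strong seeds (`≥ high`) through weak pixels (`≥ low`).

Thresholds are **absolute** gradient magnitudes, not percentiles. The
evaluation protocol requires applying *the same values* to the
original-path and compressed-path images; percentile thresholds would
silently adapt to each image and break that contract. Defaults (window 5,
40/100 on the Sobel scale) suit the near-binary membership images this
pipeline feeds to the detector, where the lesion rim produces gradient
magnitudes far above both thresholds.

## Marker detection and metric measurement

The fiducial is modelled as what the measurement actually needs: a dark
square of known physical side on a light quiet zone. Detection is Otsu
thresholding, connected-component labelling, and a geometric squareness
filter — a component is a candidate only if its pixel count matches the
area of its best-fitting corner quadrilateral within 15%, which accepts
squares at any rotation and rejects disks (ratio ≈ 1.57) and irregular
lesion blobs. Exactly one candidate must survive; zero or several is an
error that reports the count. Decoding the marker's bit payload is out of
scope — the marker serves purely as a metric reference.

Corner pixel centres are pushed half a pixel outward so that corners
refer to the printed square's outer boundary; the recovered pixel side
then equals the true rendered side. The four corners, ordered clockwise
from the corner nearest the image origin, define an exact homography onto
the square `{(0,0),(s,0),(s,s),(0,s)}` in centimetres. Measured polylines
are mapped through this homography and summed as Euclidean lengths in the
metric plane. For a fronto-parallel view the homography reduces exactly
to the scalar `s / side_px` — the plain "scale factor" model — while
oblique views remain correct for lines on the marker's plane. That
planarity assumption is documented, not checked: lengths drawn on tissue
far from the marker plane are biased by the unmodelled depth.

## The synthetic scene generator

No deposited image set exists for this pipeline, so the package generates
its own study material. A scene is a skin-toned background
(RGB 224/172/150), an irregular lesion blob darker and redder than skin
(RGB 150/60/55, about 80 gray levels below skin in the R band), an
optional marker (60 px, 5 cm, 10 px quiet zone), and i.i.d. Gaussian
noise (σ = 3 by default — consumer-camera noise after JPEG-free capture).
The blob is star-convex with radius `r(θ) = R·(1 + 0.25·P(θ))`, `P` a
seeded series of harmonics 2–5 normalized to max |P| = 1: high enough
irregularity to be visibly non-circular, low enough that the boundary
stays simple and closed, which is what makes a ground-truth contour
comparable to edge output. Interior shading is mild (8% radial darkening)
so the lesion occupies one coherent gray mode rather than fragmenting
into several clusters. Scenes are pure functions of their spec; batches
jitter centre and radius from each scene's own seed.

What the generator does **not** emulate: specular highlights, texture,
necrotic/slough appearance, lighting gradients, perspective of the wound
surface, and compression artifacts of the capture device. Passing tests
on these scenes therefore establish the *internal* correctness and
determinism of the pipeline and its qualitative behaviour under
compression — not clinical performance on real photographs.

## The evaluation protocol and its strictness

For each scene and rate, Path A segments the original band and extracts
the darkest-cluster contour; Path B compresses, segments the coefficient
image with identical parameters, extracts the contour with identical
Canny parameters, and enlarges the binary map to the original size by
nearest neighbour. Segmented-image PSNR is computed per
ascending-centroid pair after bringing Path B's cluster images back to
full size through the inverse F-transform. The darkest cluster is the
default contour source because the lesion is darker than skin in the R
band; the choice is a parameter, as it belongs to the expert user.

Two properties of this protocol are worth stating plainly. First, PSNR
between matched segmented images increases with the rate, and the rate
sweep asserts that ordering. Second, the pixel-exact confusion indicators
on *thin* contours are intrinsically harsh: a one-pixel contour detected
at half resolution becomes, after nearest-neighbour enlargement, a
two-pixel-wide contour with about twice the pixel count of the
full-resolution contour, capping precision near 0.5 even under perfect
alignment, and the two paths place the membership midpoint at slightly
different gray levels, shifting the detected rim by about a pixel. On
synthetic scenes, whose edge maps are exactly one thin ring, the four
indicators are therefore structurally far lower than on rich natural
edge maps, and the package reports them as measured. Users comparing
against thicker or denser contours should expect substantially higher
values.

## Problem sizes and determinism

The shipped tests and the evaluation script use 192×192 scenes, batches
of 10, rates {0.0625, 0.25, 0.5625} and C = 3 — sizes at which the full
suite and the protocol each run in well under a minute on one core, while
every stage (block transforms, histogram clustering, contour extraction)
is exercised at its native geometry. All randomness flows from explicit
integer seeds through `withr::with_seed`; identical seeds reproduce every
artifact bit for bit, including PNG output.

## Known limitations

- Wound *area* is not estimated; only polyline lengths are measured.
- Measurements assume the drawn line lies near the marker plane.
- The marker detector expects exactly one clean fiducial; partial
  occlusion or low contrast is a detection error, not a recovery case.
- 16-bit images are rejected rather than rescaled; the pipeline is
  defined on 8-bit intensities.
- C is not selected automatically; degenerate inputs (fewer gray levels
  than C) are errors by design.
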