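# woundimg

Back-end image-analysis toolkit for pressure-ulcer (bedsore) monitoring.
Clinical teams follow chronic wounds from photographs taken at the bedside
or at home; `woundimg` provides the analysis stages such a workflow needs on
the server side:

- **Band decomposition** — the RGB photograph is broken into its R, G and B
  bands and each band is analysed individually, since the lesion can be
  differently recognisable in the three bands.
- **Lossy compression** with the block-partitioning bi-dimensional
  **fuzzy transform (F-transform)**, so that segmentation can run directly
  on the much smaller coefficient image.
- **Fuzzy segmentation** with **FGFCM** (fast generalized fuzzy c-means):
  a spatial/gray pre-filter followed by histogram-weighted fuzzy c-means
  over the 256 gray levels, returning C cluster images whose gray values
  are the denormalized membership degrees (`round(255·u)`).
- **Contour extraction** with **Canny** edge detection under an explicit
  denoising window and absolute hysteresis thresholds, so the same
  parameter values can be applied to the original-image and
  compressed-image paths.
- **Metric measurement** through a printed square fiducial marker of known
  physical side: an exact four-point homography maps drawn polylines from
  pixels to centimetres (reducing to the single scale factor
  `side_cm / side_px` in the fronto-parallel case).
- **Quality evaluation** of the compressed path against the original path:
  PSNR between matched segmented images, and accuracy / precision /
  recall / F1 between the two binary edge maps after nearest-neighbour
  enlargement, swept over compression rates.
- A deterministic **synthetic wound-scene generator** with ground truth
  (lesion boundary, mask, marker corners, true pixel scale), and a
  **command-line interface** (`inst/cli/woundimg.R`) with one subcommand
  per stage.

## The model in brief

For a band image `I` cut into `B×B` blocks, the direct F-transform of a
block over uniform triangular basic functions `A_k`, `B_l` (a Ruspini
partition: memberships sum to 1 at every pixel) is

    F[k,l] = Σ_i Σ_j I(i,j) A_k(i) B_l(j) / (Σ_i A_k(i) · Σ_j B_l(j)),

with `b×b` coefficients per block, giving compression rate `ρ = b²/B²`;
the inverse transform `I'(i,j) = Σ_k Σ_l F[k,l] A_k(i) B_l(j)` reconstructs
each block. FGFCM first replaces every pixel by a neighbour-weighted mean
(spatial weight `exp(-d/λ_s)`, gray weight `exp(-(x_j-x_i)²/(λ_g σ_i²))`)
and then minimizes the histogram-weighted fuzzy c-means objective

    J = Σ_l Σ_k γ_l u_kl^m (ξ_l − v_k)²

over the gray levels `ξ_l` of the filtered image, so its cost is
independent of image size. PSNR is `10·log10(255²/MSE)` (capped at 99 dB
for identical images).

## Worked example

```r
library(woundimg)

sc   <- generate_scene(scene_spec(seed = 1))       # 192x192 synthetic scene
band <- split_bands(sc$image)$R                    # analyse the R band
cb   <- ft_compress(band, block_side = 4, coeff_side = 2)
print(cb)
#> <compressed_blocks 192x192 B=4 b=2 rate=0.2500 band=R>

seg <- fgfcm_segment(coefficients_as_image(cb), fgfcm_params(cluster_count = 3))
print(seg)
#> <fgfcm_result C=3 centroids=[146.13, 182.37, 223.85] iterations=42 J=5.554e+04>

em <- canny(seg$cluster_images[[1]], canny_params(5, 40, 100))
print(em)
#> <edge_map 96x96 edges=184 window=5 low=40 high=100>

psnr(band, ft_decompress(cb))
#> [1] 34.66  # dB, reconstruction fidelity at rate 0.25
```

The compressed representation stores exactly a quarter of the source
pixels (96×96 coefficients for a 192×192 band). Segmenting the coefficient
image places the darkest centroid (146.1) inside the lesion's gray range;
its denormalized cluster image yields a closed lesion contour of 184 edge
pixels at the compressed scale. The measurement stage converts drawn lines
to centimetres:

```r
sp <- scene_spec(seed = 3, lesion_center = c(130, 130), lesion_base_radius = 30,
                 marker = list(side_px = 60, physical_side = 5))
scm <- generate_scene(sp)
mm  <- detect_marker(scm$image, physical_side = 5)
measure_polyline(mm, rbind(c(40, 150), c(160, 150)))$length_cm
#> [1] 10    # 120 px at 60 px / 5 cm
```

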