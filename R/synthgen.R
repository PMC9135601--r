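# Deterministic synthetic wound-scene generator. A scene is a skin-toned
# background carrying an irregular darker-and-redder lesion blob (a
# star-convex region whose radius is modulated by a seeded low-order
# harmonic series), optionally a square fiducial marker of known physical
# side on a light quiet zone, and additive Gaussian noise. Ground truth
# (lesion boundary polygon and mask, marker corners, true pixel scale) is
# recorded at generation time.

#' Specification of a synthetic wound scene
#'
#' Default tones: skin (224, 172, 150), lesion (150, 60, 55) — darker than
#' skin in every band and markedly redder, giving an R-band inside/outside
#' separation of about 80 gray levels before noise.
#'
#' @param seed integer driving every random element of the scene.
#' @param width,height frame size in pixels (default 192x192).
#' @param skin_tone,lesion_tone RGB triples in \[0,255\].
#' @param lesion_center pixel point (x, y), 0-based; default frame centre.
#' @param lesion_base_radius base radius of the blob in pixels (default 45).
#' @param boundary_irregularity relative amplitude of the radial
#'   perturbation, in \[0, 1) (default 0.25).
#' @param noise_sigma standard deviation of the additive Gaussian noise in
#'   gray levels (default 3).
#' @param shading_depth relative darkening of the lesion centre (default
#'   0.08: the interior shades from 0.92 to 1.0 of the lesion tone).
#' @param marker optional list describing the fiducial:
#'   \code{side_px} (default 60), \code{position} top-left pixel of the
#'   square (x, y), \code{physical_side} in cm (default 5),
#'   \code{quiet_zone} width in pixels (default 10), optional 3x3
#'   \code{warp} homography applied to the marker rendering.
#' @return a \code{scene_spec} list.
#' @export
scene_spec <- function(seed = 1L, width = 192L, height = 192L,
                       skin_tone = c(224, 172, 150),
                       lesion_tone = c(150, 60, 55),
                       lesion_center = NULL, lesion_base_radius = 45,
                       boundary_irregularity = 0.25, noise_sigma = 3,
                       shading_depth = 0.08, marker = NULL) {
  if (is.null(lesion_center))
    lesion_center <- c((width - 1) / 2, (height - 1) / 2)
  stopifnot(width >= 1, height >= 1, lesion_base_radius > 0,
            boundary_irregularity >= 0, boundary_irregularity < 1,
            noise_sigma >= 0, length(skin_tone) == 3, length(lesion_tone) == 3)
  if (!is.null(marker)) {
    marker <- utils::modifyList(
      list(side_px = 60L, position = c(10, 10), physical_side = 5,
           quiet_zone = 10L, warp = NULL), marker)
  }
  structure(list(seed = as.integer(seed), width = as.integer(width),
                 height = as.integer(height), skin_tone = skin_tone,
                 lesion_tone = lesion_tone, lesion_center = lesion_center,
                 lesion_base_radius = lesion_base_radius,
                 boundary_irregularity = boundary_irregularity,
                 noise_sigma = noise_sigma, shading_depth = shading_depth,
                 marker = marker),
            class = "scene_spec")
}

#' Generate one synthetic wound scene with ground truth
#'
#' The lesion is a star-convex blob with radius
#' r(theta) = base_radius * (1 + irregularity * P(theta)), P a seeded smooth
#' periodic perturbation with max |P| = 1; its interior is filled with the
#' lesion tone under a mild radial shading. The optional marker is rendered
#' as a dark square on a light quiet zone, optionally warped by a given
#' homography. I.i.d. Gaussian noise is added per channel and clipped.
#' Identical specs produce bit-identical output.
#'
#' @param spec a \code{scene_spec}.
#' @return a \code{wound_scene}: \code{image} (\code{rgb_image}),
#'   \code{truth} (boundary polygon, logical lesion mask, marker corners,
#'   true pixels-per-cm scale) and the \code{spec}.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(spec$seed, generate_scene_impl(spec))
}

generate_scene_impl <- function(spec) {
  w <- spec$width; h <- spec$height
  cx <- spec$lesion_center[1]; cy <- spec$lesion_center[2]
  # radial profile
  amps <- stats::rnorm(4); phases <- stats::runif(4, 0, 2 * pi)
  P_raw <- function(theta) {
    p <- 0
    for (k in 1:4) p <- p + amps[k] * cos((k + 1) * theta + phases[k])
    p
  }
  grid_t <- seq(0, 2 * pi, length.out = 2048)
  pmax_ <- max(abs(P_raw(grid_t)))
  P <- if (pmax_ > 0) function(theta) P_raw(theta) / pmax_ else
    function(theta) 0
  r_of <- function(theta) spec$lesion_base_radius *
    (1 + spec$boundary_irregularity * P(theta))
  rmax <- max(r_of(grid_t))
  if (cx - rmax < 0 || cx + rmax > w - 1 || cy - rmax < 0 ||
      cy + rmax > h - 1)
    stop("lesion does not fit inside the frame")
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), w), h, w)
  dx <- xs - cx; dy <- ys - cy
  d <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  rt <- r_of(theta)
  mask <- d < rt
  boundary_t <- seq(0, 2 * pi, length.out = 361)[-361]
  boundary <- cbind(x = cx + r_of(boundary_t) * cos(boundary_t),
                    y = cy + r_of(boundary_t) * sin(boundary_t))
  shade <- 1 - spec$shading_depth * (1 - pmin(1, d / rt))
  chans <- lapply(1:3, function(ci) {
    m <- matrix(spec$skin_tone[ci], h, w)
    m[mask] <- spec$lesion_tone[ci] * shade[mask]
    m
  })
  truth_corners <- NULL; px_per_cm <- NA_real_
  if (!is.null(spec$marker)) {
    mk <- spec$marker
    s <- mk$side_px; qz <- mk$quiet_zone
    x0 <- mk$position[1]; y0 <- mk$position[2]
    # outer corners in continuous coordinates (pixel i spans [i-0.5, i+0.5])
    corners <- rbind(c(x0 - 0.5, y0 - 0.5), c(x0 + s - 0.5, y0 - 0.5),
                     c(x0 + s - 0.5, y0 + s - 0.5), c(x0 - 0.5, y0 + s - 0.5))
    if (is.null(mk$warp)) {
      qx <- (x0 - qz):(x0 + s + qz - 1); qy <- (y0 - qz):(y0 + s + qz - 1)
      qx <- qx[qx >= 0 & qx < w]; qy <- qy[qy >= 0 & qy < h]
      region_mask <- matrix(FALSE, h, w)
      region_mask[qy + 1, qx + 1] <- TRUE
      square_mask <- matrix(FALSE, h, w)
      square_mask[(y0:(y0 + s - 1)) + 1, (x0:(x0 + s - 1)) + 1] <- TRUE
      truth_corners <- corners
    } else {
      W <- mk$warp
      Winv <- solve(W)
      # candidate region: warped bounding box of the quiet zone, clipped
      outer_sq <- rbind(c(x0 - qz, y0 - qz), c(x0 + s + qz, y0 - qz),
                        c(x0 + s + qz, y0 + s + qz), c(x0 - qz, y0 + s + qz))
      wc <- apply_homography(W, outer_sq)
      xr <- range(wc[, 1]); yr <- range(wc[, 2])
      sel <- xs >= xr[1] - 1 & xs <= xr[2] + 1 &
             ys >= yr[1] - 1 & ys <= yr[2] + 1
      src <- apply_homography(Winv, cbind(xs[sel], ys[sel]))
      inside_sq <- src[, 1] >= x0 - 0.5 & src[, 1] <= x0 + s - 0.5 &
                   src[, 2] >= y0 - 0.5 & src[, 2] <= y0 + s - 0.5
      inside_qz <- src[, 1] >= x0 - qz - 0.5 & src[, 1] <= x0 + s + qz - 0.5 &
                   src[, 2] >= y0 - qz - 0.5 & src[, 2] <= y0 + s + qz - 0.5
      region_mask <- matrix(FALSE, h, w); region_mask[sel][inside_qz] <- TRUE
      square_mask <- matrix(FALSE, h, w); square_mask[sel][inside_sq] <- TRUE
      truth_corners <- apply_homography(W, corners)
    }
    if (any(region_mask & mask))
      stop("marker region overlaps the lesion")
    for (ci in 1:3) {
      chans[[ci]][region_mask] <- 242
      chans[[ci]][square_mask] <- 16
    }
    px_per_cm <- s / mk$physical_side
  }
  if (spec$noise_sigma > 0) {
    for (ci in 1:3)
      chans[[ci]] <- chans[[ci]] +
        matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w)
  }
  chans <- lapply(chans, function(m) clip255(round_half_up(m)))
  structure(list(image = rgb_image(chans[[1]], chans[[2]], chans[[3]]),
                 truth = list(boundary = boundary, mask = mask,
                              marker_corners = truth_corners,
                              px_per_cm = px_per_cm),
                 spec = spec),
            class = "wound_scene")
}

#' @export
print.wound_scene <- function(x, ...) {
  cat(sprintf("<wound_scene seed=%d %dx%d lesion_r=%.0f marker=%s>\n",
              x$spec$seed, x$spec$width, x$spec$height,
              x$spec$lesion_base_radius,
              if (is.null(x$spec$marker)) "no" else "yes"))
  invisible(x)
}

#' Generate a deterministic batch of scenes
#'
#' Scene i uses seed \code{seed_start + i - 1}; its lesion centre and base
#' radius are jittered from the base spec using that same seed, so the batch
#' is a pure function of (base_spec, n, seed_start).
#'
#' @param base_spec a \code{scene_spec} used as template.
#' @param n number of scenes (>= 0).
#' @param seed_start first seed.
#' @return a list of \code{wound_scene} objects.
#' @export
scene_batch <- function(base_spec = scene_spec(), n = 10L, seed_start = 1L) {
  stopifnot(n >= 0)
  lapply(seq_len(n), function(i) {
    sd <- as.integer(seed_start + i - 1)
    jit <- withr::with_seed(sd, list(
      dc = stats::runif(2, -8, 8),
      fr = stats::runif(1, 0.85, 1.15)))
    sp <- base_spec
    sp$seed <- sd
    sp$lesion_center <- base_spec$lesion_center + jit$dc
    sp$lesion_base_radius <- base_spec$lesion_base_radius * jit$fr
    generate_scene(sp)
  })
}
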