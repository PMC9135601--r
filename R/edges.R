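# Canny edge detection with an explicit denoising window: Gaussian smoothing
# (kernel side = window, sigma = window/6), 3x3 Sobel gradients, non-maximum
# suppression with 4-way direction quantization, and double-threshold
# hysteresis with 8-connected propagation from strong seeds. Thresholds are
# absolute gradient magnitudes so that the same values can be applied to an
# original-path and a compressed-path image.

#' Canny parameters
#'
#' @param denoise_window side of the Gaussian smoothing kernel, an odd
#'   integer >= 3 (default 5); sigma is window/6.
#' @param low_threshold,high_threshold hysteresis thresholds on the absolute
#'   Sobel gradient magnitude, 0 <= low < high (defaults 40 and 100).
#' @return a \code{canny_params} list.
#' @export
canny_params <- function(denoise_window = 5L, low_threshold = 40,
                         high_threshold = 100) {
  if (denoise_window < 3 || denoise_window %% 2 == 0)
    stop("denoise_window must be an odd integer >= 3")
  if (low_threshold < 0 || high_threshold <= low_threshold)
    stop("thresholds must satisfy 0 <= low < high")
  structure(list(denoise_window = as.integer(denoise_window),
                 low_threshold = low_threshold,
                 high_threshold = high_threshold),
            class = "canny_params")
}

# Separable convolution with a centred 1D kernel, replicate padding.
conv_sep <- function(m, krow, kcol) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  half <- (length(krow) - 1L) %/% 2L
  for (t in seq_along(krow))
    out <- out + krow[t] * shift_replicate(m, t - 1L - half, 0L)
  m2 <- out; out <- matrix(0, h, w)
  half <- (length(kcol) - 1L) %/% 2L
  for (t in seq_along(kcol))
    out <- out + kcol[t] * shift_replicate(m2, 0L, t - 1L - half)
  out
}

gaussian_kernel1d <- function(side) {
  sigma <- side / 6
  k <- exp(-((seq_len(side) - (side + 1) / 2)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Canny edge detection
#'
#' Stages, in order: Gaussian smoothing with kernel side
#' \code{denoise_window}; Sobel gradients (the one-pixel image border is
#' excluded from gradient support); non-maximum suppression along the
#' quantized gradient direction, with a deterministic tie-break that keeps a
#' ridge of tied magnitudes one pixel wide; double-threshold hysteresis in
#' which weak pixels (magnitude >= low) survive only when 8-connected,
#' possibly through other weak pixels, to a strong pixel
#' (magnitude >= high).
#'
#' @param img a \code{raster_image}, at least window x window.
#' @param params a \code{canny_params} object.
#' @return an \code{edge_map}: logical matrix \code{edges} plus the
#'   parameters that produced it.
#' @export
canny <- function(img, params = canny_params()) {
  stopifnot(inherits(img, "raster_image"))
  w <- params$denoise_window
  h <- image_height(img); wd <- image_width(img)
  if (h < w || wd < w)
    stop("image (", h, "x", wd, ") smaller than denoise_window (", w, ")")
  k <- gaussian_kernel1d(w)
  sm <- conv_sep(img$pixels, k, k)
  # Sobel: separable [1 2 1] smoothing x [-1 0 1] derivative
  gx <- conv_sep(sm, c(1, 2, 1), c(-1, 0, 1))   # derivative along columns (x)
  gy <- conv_sep(sm, c(-1, 0, 1), c(1, 2, 1))   # derivative along rows (y)
  mag <- sqrt(gx^2 + gy^2)
  mag[c(1, h), ] <- 0; mag[, c(1, wd)] <- 0
  ang <- atan2(gy, gx)
  sector <- (round_half_up(ang / (pi / 4)) %% 4)  # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  nms <- matrix(FALSE, h, wd)
  neigh <- list(`0` = c(0L, 1L), `1` = c(1L, 1L),
                `2` = c(1L, 0L), `3` = c(1L, -1L))
  for (s in 0:3) {
    d <- neigh[[as.character(s)]]
    pos <- shift_replicate(mag, d[1], d[2])
    neg <- shift_replicate(mag, -d[1], -d[2])
    keep <- (sector == s) & (mag > neg) & (mag >= pos) & (mag > 0)
    nms <- nms | keep
  }
  weak <- nms & (mag >= params$low_threshold)
  strong <- nms & (mag >= params$high_threshold)
  edges <- propagate8(strong, weak)
  structure(list(edges = edges, width = wd, height = h, params = params),
            class = "edge_map")
}

# Grow `seed` through `mask` by repeated 8-neighbour dilation (both logical
# matrices) until a fixed point.
propagate8 <- function(seed, mask) {
  cur <- seed & mask
  repeat {
    grown <- cur
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      grown <- grown | shift_replicate(cur, dr, dc)
    }
    grown <- grown & mask
    if (identical(grown, cur)) return(cur)
    cur <- grown
  }
}

#' @export
print.edge_map <- function(x, ...) {
  cat(sprintf("<edge_map %dx%d edges=%d window=%d low=%g high=%g>\n",
              x$width, x$height, edge_pixel_count(x),
              x$params$denoise_window, x$params$low_threshold,
              x$params$high_threshold))
  invisible(x)
}

#' Number of edge pixels in an edge map
#'
#' @param em an \code{edge_map}.
#' @return integer count of edge-valued pixels.
#' @export
edge_pixel_count <- function(em) {
  stopifnot(inherits(em, "edge_map"))
  sum(em$edges)
}

#' Convert an edge map to a 0/255 raster image
#'
#' @param em an \code{edge_map}.
#' @return a \code{raster_image} with edges at 255.
#' @export
edge_map_as_image <- function(em) {
  stopifnot(inherits(em, "edge_map"))
  raster_image(matrix(ifelse(em$edges, 255, 0), em$height, em$width), "GRAY")
}
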