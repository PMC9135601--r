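# Intensities are stored as numeric matrices with integer values in [0,255],
# row-major view: pixels[row, col], origin at the top-left, 0-based pixel
# coordinates when coordinates are exchanged with callers (x = col - 1,
# y = row - 1). A pixel is the unit square centred on its integer coordinate.

round_half_up <- function(x) floor(x + 0.5)

clip255 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

#' Single-band raster image
#'
#' Constructs the unit of data all pipeline stages consume and produce: a
#' matrix of integer intensities in \[0,255\] tagged with a band label.
#'
#' @param pixels numeric matrix of intensities in \[0,255\].
#' @param band one of \code{"R"}, \code{"G"}, \code{"B"}, \code{"GRAY"}.
#' @return an object of class \code{raster_image}.
#' @export
raster_image <- function(pixels, band = "GRAY") {
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("pixels must be a matrix with at least one row and one column")
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255) ||
      any(pixels != floor(pixels)))
    stop("intensities must be integers in [0,255]")
  band <- match.arg(band, c("R", "G", "B", "GRAY"))
  structure(list(pixels = matrix(as.numeric(pixels), nrow(pixels)),
                 band = band),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image %dx%d band=%s range=[%d,%d]>\n",
              image_width(x), image_height(x), x$band,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @rdname raster_image
#' @param x a \code{raster_image} or \code{rgb_image}.
#' @export
image_width <- function(x) {
  if (inherits(x, "rgb_image")) ncol(x$R$pixels) else ncol(x$pixels)
}

#' @rdname raster_image
#' @export
image_height <- function(x) {
  if (inherits(x, "rgb_image")) nrow(x$R$pixels) else nrow(x$pixels)
}

#' Three-band RGB image
#'
#' @param R,G,B \code{raster_image} channels (or plain matrices) of identical
#'   dimensions.
#' @return an object of class \code{rgb_image} with channels labelled R, G, B.
#' @export
rgb_image <- function(R, G, B) {
  chan <- function(m, lab) {
    if (inherits(m, "raster_image")) raster_image(m$pixels, lab)
    else raster_image(m, lab)
  }
  out <- list(R = chan(R, "R"), G = chan(G, "G"), B = chan(B, "B"))
  dims <- vapply(out, function(ch) dim(ch$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all three channels must share width and height")
  structure(out, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image %dx%d>\n", image_width(x), image_height(x)))
  invisible(x)
}

#' Read an RGB PNG image
#'
#' Decodes an 8-bit PNG into an \code{rgb_image}. Grayscale files are expanded
#' to three identical channels; an alpha channel, if present, is discarded.
#' 16-bit files are rejected because the pipeline is defined on 8-bit
#' intensities.
#'
#' @param path path to a PNG file.
#' @return an \code{rgb_image}.
#' @export
read_png <- function(path) {
  if (!file.exists(path)) stop("cannot read PNG: no such file: ", path)
  arr <- tryCatch(png::readPNG(path),
                  error = function(e) stop("cannot decode PNG ", path, ": ",
                                           conditionMessage(e)))
  v <- arr * 255
  if (max(abs(v - round(v))) > 1e-6)
    stop("PNG ", path, " is not 8-bit; 16-bit images are rejected")
  v <- round(v)
  if (length(dim(arr)) == 2L) return(rgb_image(v, v, v))
  nch <- dim(arr)[3]
  if (nch == 2L) return(rgb_image(v[, , 1], v[, , 1], v[, , 1]))  # gray+alpha
  rgb_image(v[, , 1], v[, , 2], v[, , 3])
}

#' Write a PNG image
#'
#' Writes an \code{rgb_image} as an 8-bit RGB PNG, or a \code{raster_image}
#' as an 8-bit gray PNG. The round trip through \code{read_png} is bit-exact.
#'
#' @param img an \code{rgb_image} or \code{raster_image}.
#' @param path destination path; the parent directory must exist.
#' @export
write_png <- function(img, path) {
  if (!dir.exists(dirname(path)))
    stop("cannot write PNG: no such directory: ", dirname(path))
  if (inherits(img, "rgb_image")) {
    h <- image_height(img); w <- image_width(img)
    arr <- array(0, c(h, w, 3))
    arr[, , 1] <- img$R$pixels / 255
    arr[, , 2] <- img$G$pixels / 255
    arr[, , 3] <- img$B$pixels / 255
    png::writePNG(arr, path)
  } else if (inherits(img, "raster_image")) {
    png::writePNG(img$pixels / 255, path)
  } else stop("img must be an rgb_image or raster_image")
  invisible(NULL)
}

#' Split an RGB image into its three bands
#'
#' The image is broken down into the Red, Green and Blue bands so that each
#' band can be analysed individually; pixel values are copied unchanged.
#'
#' @param img an \code{rgb_image}.
#' @return a list of three \code{raster_image}s named R, G, B.
#' @export
split_bands <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  list(R = img$R, G = img$G, B = img$B)
}

#' Reassemble bands into an RGB image
#'
#' Inverse of \code{\link{split_bands}}.
#'
#' @param bands list with elements R, G, B.
#' @return an \code{rgb_image}.
#' @export
merge_bands <- function(bands) rgb_image(bands$R, bands$G, bands$B)

# Corner-aligned bilinear resample of one matrix to h x w.
bilinear_resize <- function(m, h, w) {
  src_h <- nrow(m); src_w <- ncol(m)
  coord <- function(n_dst, n_src) {
    if (n_dst == 1L || n_src == 1L) rep(0, n_dst)
    else (0:(n_dst - 1)) * (n_src - 1) / (n_dst - 1)
  }
  ys <- coord(h, src_h); xs <- coord(w, src_w)
  y0 <- pmin(floor(ys), src_h - 1); x0 <- pmin(floor(xs), src_w - 1)
  y1 <- pmin(y0 + 1, src_h - 1); x1 <- pmin(x0 + 1, src_w - 1)
  fy <- ys - y0; fx <- xs - x0
  # outer products of the four corner weights
  a <- m[y0 + 1, x0 + 1, drop = FALSE] * outer(1 - fy, 1 - fx) +
       m[y1 + 1, x0 + 1, drop = FALSE] * outer(fy, 1 - fx) +
       m[y0 + 1, x1 + 1, drop = FALSE] * outer(1 - fy, fx) +
       m[y1 + 1, x1 + 1, drop = FALSE] * outer(fy, fx)
  clip255(round_half_up(a))
}

#' Normalize an image to a square size
#'
#' Geometric size normalization used before any downstream consumption that
#' expects a fixed frame: a plain bilinear stretch to \code{side}×\code{side}
#' pixels (aspect ratio is not preserved). Resampling is corner-aligned, so a
#' resize to the input's own size is the identity. No intensity rescaling is
#' performed.
#'
#' @param img an \code{rgb_image} or \code{raster_image}.
#' @param side output side length in pixels (default 192).
#' @return an image of the same class, \code{side}×\code{side}.
#' @export
normalize_image <- function(img, side = 192L) {
  if (length(side) != 1L || is.na(side) || side < 1)
    stop("side must be a positive integer")
  side <- as.integer(side)
  if (inherits(img, "rgb_image")) {
    rgb_image(bilinear_resize(img$R$pixels, side, side),
              bilinear_resize(img$G$pixels, side, side),
              bilinear_resize(img$B$pixels, side, side))
  } else if (inherits(img, "raster_image")) {
    raster_image(bilinear_resize(img$pixels, side, side), img$band)
  } else stop("img must be an rgb_image or raster_image")
}
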