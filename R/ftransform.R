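# Block-partitioning bi-dimensional fuzzy transform (F-transform) lossy
# compression. Each B x B block of a band image is reduced to a b x b grid
# of direct F-transform coefficients over a uniform triangular Ruspini
# partition of the block axes; the inverse F-transform reconstructs the
# block. The compression rate is rho = b^2 / B^2.

#' Uniform triangular fuzzy partition of a pixel axis
#'
#' Builds \code{node_count} triangular basic functions over pixel coordinates
#' \code{0..axis_length-1}, with nodes equally spaced from the first to the
#' last pixel. The partition satisfies the Ruspini condition: at every pixel
#' the memberships over all nodes sum to 1. Each basic function attains 1 at
#' its own node and vanishes at and beyond the adjacent nodes.
#'
#' @param axis_length number of pixels on the axis (>= node_count).
#' @param node_count number of nodes n >= 2.
#' @return a \code{fuzzy_partition}: list with \code{nodes} (real coordinates)
#'   and \code{basis}, an \code{axis_length} x \code{node_count} matrix of
#'   membership values.
#' @export
build_partition <- function(axis_length, node_count) {
  if (node_count < 2) stop("node_count must be at least 2")
  if (axis_length < node_count)
    stop("node_count (", node_count, ") exceeds axis_length (", axis_length, ")")
  h <- (axis_length - 1) / (node_count - 1)
  nodes <- (seq_len(node_count) - 1) * h
  x <- 0:(axis_length - 1)
  basis <- vapply(nodes, function(nd) pmax(0, 1 - abs(x - nd) / h),
                  numeric(axis_length))
  structure(list(axis_length = axis_length, node_count = node_count,
                 nodes = nodes, basis = basis),
            class = "fuzzy_partition")
}

# Fixed catalogue of block geometries: block side B in {4, 8, 16},
# coefficient side 2 <= b < B.
block_catalogue <- function() {
  out <- do.call(rbind, lapply(c(4L, 8L, 16L), function(B) {
    data.frame(block_side = B, coeff_side = 2:(B - 1L))
  }))
  out$rate <- out$coeff_side^2 / out$block_side^2
  out
}

#' Map a requested compression rate to a block geometry
#'
#' Chooses, from the fixed catalogue (block side B in \{4, 8, 16\}, coefficient
#' side 2 <= b < B), the pair whose achieved rate b^2/B^2 is closest to the
#' request; ties are broken toward the smaller block. A request of exactly 1
#' is an identity pass-through: no compression is performed and the result is
#' flagged.
#'
#' @param requested_rate real in (0, 1].
#' @return list with \code{block_side}, \code{coeff_side}, \code{achieved_rate}
#'   and logical \code{identity}.
#' @export
rate_to_blocks <- function(requested_rate) {
  if (length(requested_rate) != 1L || is.na(requested_rate) ||
      requested_rate <= 0 || requested_rate > 1)
    stop("requested_rate must lie in (0, 1]")
  if (requested_rate == 1)
    return(list(block_side = NA_integer_, coeff_side = NA_integer_,
                achieved_rate = 1, identity = TRUE))
  cat_ <- block_catalogue()
  cat_ <- cat_[order(cat_$block_side, cat_$coeff_side), ]
  i <- which.min(abs(cat_$rate - requested_rate))  # first minimum: smaller B
  list(block_side = cat_$block_side[i], coeff_side = cat_$coeff_side[i],
       achieved_rate = cat_$rate[i], identity = FALSE)
}

# Per-axis block sizes when length n is cut into blocks of side B; the last
# block is shrunk, never padded.
axis_blocks <- function(n, B) {
  k <- n %/% B; r <- n %% B
  sizes <- rep(B, k)
  if (r > 0) sizes <- c(sizes, r)
  sizes
}

# Partition (or degenerate identity) for a block axis of size s with at most
# b nodes. Blocks of size 1 have a single unit basic function.
block_partition <- function(s, b) {
  if (s == 1L) return(list(basis = matrix(1, 1, 1)))
  build_partition(s, min(b, s))
}

#' Compress a band image with the block F-transform
#'
#' Cuts the image into \code{block_side} x \code{block_side} blocks (the last
#' block on each axis is shrunk when the size is not a multiple) and stores,
#' per block, the \code{coeff_side} x \code{coeff_side} direct F-transform
#' coefficients: partition-weighted means of the block intensities. Every
#' coefficient is a convex combination of source intensities and therefore
#' lies in \[0,255\]. Coefficients are kept as reals; rounding happens only
#' when an image is materialized.
#'
#' @param img a \code{raster_image}.
#' @param block_side block side B in pixels.
#' @param coeff_side coefficient side b, 2 <= b < B.
#' @return a \code{compressed_blocks} object.
#' @export
ft_compress <- function(img, block_side, coeff_side) {
  stopifnot(inherits(img, "raster_image"))
  if (coeff_side >= block_side)
    stop("coeff_side must be smaller than block_side")
  if (coeff_side < 2) stop("coeff_side must be at least 2")
  M <- image_height(img); N <- image_width(img)
  if (M < block_side || N < block_side)
    stop("image must be at least block_side in both axes")
  rsz <- axis_blocks(M, block_side); csz <- axis_blocks(N, block_side)
  crs <- pmin(coeff_side, rsz); ccs <- pmin(coeff_side, csz)
  parts <- new.env()
  getpart <- function(s, b) {
    key <- paste(s, b)
    if (is.null(parts[[key]])) parts[[key]] <- block_partition(s, b)
    parts[[key]]
  }
  grid <- matrix(0, sum(crs), sum(ccs))
  r0 <- cumsum(c(0, rsz)); c0 <- cumsum(c(0, csz))
  gr0 <- cumsum(c(0, crs)); gc0 <- cumsum(c(0, ccs))
  X <- img$pixels
  for (i in seq_along(rsz)) {
    Ar <- getpart(rsz[i], coeff_side)$basis         # rsz[i] x crs[i]
    wr <- colSums(Ar)
    for (j in seq_along(csz)) {
      Ac <- getpart(csz[j], coeff_side)$basis
      wc <- colSums(Ac)
      blk <- X[(r0[i] + 1):r0[i + 1], (c0[j] + 1):c0[j + 1], drop = FALSE]
      Fkl <- crossprod(Ar, blk %*% Ac) / outer(wr, wc)
      grid[(gr0[i] + 1):gr0[i + 1], (gc0[j] + 1):gc0[j + 1]] <- Fkl
    }
  }
  structure(list(original_width = N, original_height = M,
                 block_side = as.integer(block_side),
                 coeff_side = as.integer(coeff_side),
                 achieved_rate = coeff_side^2 / block_side^2,
                 band = img$band,
                 coeff_grid = grid,
                 row_sizes = rsz, col_sizes = csz,
                 coeff_row_sizes = crs, coeff_col_sizes = ccs),
            class = "compressed_blocks")
}

#' @export
print.compressed_blocks <- function(x, ...) {
  cat(sprintf("<compressed_blocks %dx%d B=%d b=%d rate=%.4f band=%s>\n",
              x$original_width, x$original_height, x$block_side,
              x$coeff_side, x$achieved_rate, x$band))
  invisible(x)
}

# Inverse F-transform of an arbitrary coefficient grid laid out like cb's,
# returning the real-valued reconstruction before rounding.
inverse_grid <- function(cb, grid) {
  rsz <- cb$row_sizes; csz <- cb$col_sizes
  crs <- cb$coeff_row_sizes; ccs <- cb$coeff_col_sizes
  out <- matrix(0, cb$original_height, cb$original_width)
  r0 <- cumsum(c(0, rsz)); c0 <- cumsum(c(0, csz))
  gr0 <- cumsum(c(0, crs)); gc0 <- cumsum(c(0, ccs))
  for (i in seq_along(rsz)) {
    Ar <- block_partition(rsz[i], cb$coeff_side)$basis
    for (j in seq_along(csz)) {
      Ac <- block_partition(csz[j], cb$coeff_side)$basis
      Fkl <- grid[(gr0[i] + 1):gr0[i + 1], (gc0[j] + 1):gc0[j + 1],
                  drop = FALSE]
      out[(r0[i] + 1):r0[i + 1], (c0[j] + 1):c0[j + 1]] <- Ar %*% Fkl %*% t(Ac)
    }
  }
  out
}

#' Decompress a block F-transform representation
#'
#' Applies the inverse F-transform block by block: each reconstructed pixel is
#' the basis-weighted sum of its block's coefficients. The output has the
#' original image size; values are rounded to the nearest integer and clipped
#' to \[0,255\].
#'
#' @param cb a \code{compressed_blocks} object.
#' @return a \code{raster_image} of the original dimensions.
#' @export
ft_decompress <- function(cb) {
  stopifnot(inherits(cb, "compressed_blocks"))
  raster_image(clip255(round_half_up(inverse_grid(cb, cb$coeff_grid))), cb$band)
}

#' Materialize the coefficient grid as a small image
#'
#' The coefficient tiles, assembled preserving block adjacency, form a smaller
#' image on which segmentation can be run directly, considerably reducing its
#' cost. Coefficients are rounded and clipped to \[0,255\].
#'
#' @param cb a \code{compressed_blocks} object.
#' @return a \code{raster_image} of the coefficient grid.
#' @export
coefficients_as_image <- function(cb) {
  stopifnot(inherits(cb, "compressed_blocks"))
  raster_image(clip255(round_half_up(cb$coeff_grid)), cb$band)
}

#' Serialize / deserialize compressed blocks
#'
#' The sidecar format is a single JSON object: a header (dimensions, block
#' geometry, band, achieved rate) plus the flat coefficient array in
#' column-major order.
#'
#' @param cb a \code{compressed_blocks} object.
#' @param path destination (or source) file path.
#' @return \code{read_ftc} returns a \code{compressed_blocks} object.
#' @export
write_ftc <- function(cb, path) {
  stopifnot(inherits(cb, "compressed_blocks"))
  obj <- list(original_width = cb$original_width,
              original_height = cb$original_height,
              block_side = cb$block_side, coeff_side = cb$coeff_side,
              achieved_rate = cb$achieved_rate, band = cb$band,
              coeff_rows = nrow(cb$coeff_grid),
              coeff_cols = ncol(cb$coeff_grid),
              coefficients = as.numeric(cb$coeff_grid))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' @rdname write_ftc
#' @export
read_ftc <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rsz <- axis_blocks(obj$original_height, obj$block_side)
  csz <- axis_blocks(obj$original_width, obj$block_side)
  structure(list(original_width = obj$original_width,
                 original_height = obj$original_height,
                 block_side = as.integer(obj$block_side),
                 coeff_side = as.integer(obj$coeff_side),
                 achieved_rate = obj$achieved_rate, band = obj$band,
                 coeff_grid = matrix(obj$coefficients, obj$coeff_rows,
                                     obj$coeff_cols),
                 row_sizes = rsz, col_sizes = csz,
                 coeff_row_sizes = pmin(obj$coeff_side, rsz),
                 coeff_col_sizes = pmin(obj$coeff_side, csz)),
            class = "compressed_blocks")
}
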