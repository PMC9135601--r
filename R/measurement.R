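# Marker-based metric measurement. A printed square fiducial of known
# physical side placed near the lesion provides the pixel -> centimetre
# bridge: its four corners are detected and an exact 4-point homography maps
# image coordinates onto the marker's metric plane. In the fronto-parallel
# case this reduces to the single scale factor physical_side / pixel_side;
# oblique views are handled by the full homography. Measurements are valid
# for lines approximately on the marker's plane.

# Otsu threshold over an 8-bit intensity matrix: returns t such that the
# dark class is {x <= t}.
otsu_threshold <- function(m) {
  counts <- tabulate(as.integer(m) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  omega <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- -Inf
  which.max(sb2) - 1L
}

# Pick the 4 convex-hull vertices that maximize quadrilateral area.
best_quad <- function(xy) {
  hull <- grDevices::chull(xy)
  pts <- xy[hull, , drop = FALSE]
  nh <- nrow(pts)
  if (nh < 4) return(NULL)
  if (nh == 4) return(pts)
  best <- NULL; barea <- -1
  comb <- utils::combn(nh, 4)
  for (i in seq_len(ncol(comb))) {
    q <- pts[comb[, i], , drop = FALSE]
    a <- shoelace_area(q)
    if (a > barea) { barea <- a; best <- q }
  }
  best
}

shoelace_area <- function(q) {
  x <- q[, 1]; y <- q[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Order the rows of a 4x2 corner matrix clockwise (in image coordinates,
# y down) starting from the corner nearest the image origin.
order_corners <- function(q) {
  cx <- mean(q[, 1]); cy <- mean(q[, 2])
  ang <- atan2(q[, 2] - cy, q[, 1] - cx)
  q <- q[order(ang), , drop = FALSE]     # clockwise when y points down
  start <- which.min(q[, 1]^2 + q[, 2]^2)
  q[((seq_len(4) + start - 2) %% 4) + 1, , drop = FALSE]
}

#' Detect the square fiducial marker in a scene
#'
#' Thresholds the scene (Otsu on the gray mean of the three bands), labels the
#' dark connected components, and keeps components whose pixel count matches
#' the area of their best-fitting corner quadrilateral within 10% — a
#' geometric squareness filter that rejects irregular lesion blobs. Exactly
#' one candidate must survive. Corner pixel centres are pushed half a pixel
#' outward so the corners refer to the marker's outer boundary, and are
#' ordered clockwise from the corner nearest the image origin.
#'
#' @param img an \code{rgb_image} containing one dark square fiducial on a
#'   light quiet zone.
#' @param physical_side printed side length of the marker in centimetres.
#' @param min_area smallest admissible component, in pixels (default 64).
#' @return a \code{marker_model}: \code{corners} (4x2, 0-based x,y pixel
#'   coordinates), \code{physical_side} and the 3x3 \code{homography} mapping
#'   image pixels to the metric marker plane (cm).
#' @export
detect_marker <- function(img, physical_side, min_area = 64) {
  stopifnot(inherits(img, "rgb_image"), physical_side > 0)
  gray <- (img$R$pixels + img$G$pixels + img$B$pixels) / 3
  dark <- gray <= otsu_threshold(gray)
  lab <- EBImage::bwlabel(dark)
  labs <- setdiff(unique(as.integer(lab)), 0L)
  candidates <- list()
  for (l in labs) {
    idx <- which(lab == l, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    xy <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
    q <- best_quad(xy)
    if (is.null(q)) next
    a <- shoelace_area(q)
    if (a <= 0) next
    # outer-boundary area of a rasterized quad exceeds the corner-centre
    # quad area by roughly one perimeter; compare against both
    if (abs(nrow(idx) / a - 1) <= 0.15)
      candidates[[length(candidates) + 1]] <- q
  }
  if (length(candidates) != 1L)
    stop("marker detection failed: ", length(candidates),
         " candidate quadrilateral(s) found")
  q <- order_corners(candidates[[1]])
  # half-pixel outward correction from pixel centres to the outer boundary
  cx <- mean(q[, 1]); cy <- mean(q[, 2])
  q[, 1] <- q[, 1] + 0.5 * sign(q[, 1] - cx)
  q[, 2] <- q[, 2] + 0.5 * sign(q[, 2] - cy)
  marker_model(q, physical_side)
}

#' Build a marker model from four corners
#'
#' @param corners 4x2 matrix of pixel coordinates, clockwise from top-left.
#' @param physical_side marker side in centimetres.
#' @return a \code{marker_model}.
#' @export
marker_model <- function(corners, physical_side) {
  H <- fit_homography(corners, physical_side)
  s <- physical_side
  target <- rbind(c(0, 0), c(s, 0), c(s, s), c(0, s))
  mapped <- apply_homography(H, corners)
  if (max(abs(mapped - target)) > 1e-6)
    stop("homography fails to reproduce the metric square")
  structure(list(corners = corners, physical_side = physical_side,
                 homography = H),
            class = "marker_model")
}

#' @export
print.marker_model <- function(x, ...) {
  cat(sprintf("<marker_model side=%g cm, corners at (%s)>\n",
              x$physical_side,
              paste(sprintf("%.1f,%.1f", x$corners[, 1], x$corners[, 2]),
                    collapse = " | ")))
  invisible(x)
}

#' Exact four-point homography onto the metric marker square
#'
#' Solves the 8x8 direct linear system mapping the four corners, in order,
#' onto \{(0,0), (s,0), (s,s), (0,s)\} (centimetres). For an axis-aligned
#' square of pixel side p the result is the pure scale s/p.
#'
#' @param corners 4x2 matrix, clockwise from top-left.
#' @param physical_side square side s in centimetres.
#' @return a 3x3 homography matrix with unit bottom-right element.
#' @export
fit_homography <- function(corners, physical_side) {
  stopifnot(is.matrix(corners), nrow(corners) == 4, ncol(corners) == 2,
            physical_side > 0)
  s <- physical_side
  dst <- rbind(c(0, 0), c(s, 0), c(s, s), c(0, s))
  A <- matrix(0, 8, 8); bvec <- numeric(8)
  for (i in 1:4) {
    x <- corners[i, 1]; y <- corners[i, 2]
    X <- dst[i, 1]; Y <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -X * x, -X * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -Y * x, -Y * y)
    bvec[2 * i - 1] <- X; bvec[2 * i] <- Y
  }
  h <- tryCatch(solve(A, bvec),
                error = function(e) stop("degenerate corner configuration: ",
                                         conditionMessage(e)))
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

apply_homography <- function(H, pts) {
  p <- cbind(pts, 1) %*% t(H)
  p[, 1:2, drop = FALSE] / p[, 3]
}

#' Measure a polyline in centimetres
#'
#' Maps each drawn point through the marker homography onto the metric plane
#' and sums Euclidean segment lengths there.
#'
#' @param model a \code{marker_model}.
#' @param points n x 2 matrix (n >= 2) of pixel coordinates.
#' @return a \code{polyline_measurement}: \code{points},
#'   \code{per_segment_cm} and \code{length_cm}.
#' @export
measure_polyline <- function(model, points) {
  stopifnot(inherits(model, "marker_model"))
  if (!is.matrix(points) || nrow(points) < 2 || ncol(points) != 2)
    stop("points must be a matrix of at least 2 pixel coordinates")
  mp <- apply_homography(model$homography, points)
  seg <- sqrt(rowSums((mp[-1, , drop = FALSE] -
                       mp[-nrow(mp), , drop = FALSE])^2))
  structure(list(points = points, per_segment_cm = seg,
                 length_cm = sum(seg)),
            class = "polyline_measurement")
}

#' @export
print.polyline_measurement <- function(x, ...) {
  cat(sprintf("<polyline_measurement %d points, %.3f cm>\n",
              nrow(x$points), x$length_cm))
  invisible(x)
}
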