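# Fast generalized fuzzy c-means (FGFCM) segmentation. A pre-filter replaces
# each pixel by a neighbour-weighted mean whose weights combine spatial
# closeness and gray-level similarity; fuzzy c-means then runs on the 256-bin
# gray-level histogram of the filtered image, so clustering cost is
# independent of image size.

#' FGFCM parameter set
#'
#' @param cluster_count number of clusters C >= 2.
#' @param fuzzifier FCM fuzzifier m > 1 (default 2).
#' @param spatial_scale decay scale of the spatial weight, in pixels
#'   (lambda_s, default 3).
#' @param gray_scale scale of the gray-similarity weight relative to the
#'   local gray spread (lambda_g, default 6).
#' @param neighborhood_radius Chebyshev radius of the filter window in pixels
#'   (default 1, i.e. 3x3).
#' @param max_iterations FCM iteration cap (default 100).
#' @param tolerance convergence threshold on the largest centroid shift,
#'   in gray levels (default 1e-5).
#' @param seed reserved for stochastic initialization; the default
#'   initialization is deterministic, so the seed does not affect results.
#' @return an \code{fgfcm_params} list.
#' @export
fgfcm_params <- function(cluster_count = 3L, fuzzifier = 2,
                         spatial_scale = 3, gray_scale = 6,
                         neighborhood_radius = 1L, max_iterations = 100L,
                         tolerance = 1e-5, seed = 1L) {
  stopifnot(cluster_count >= 2, fuzzifier > 1, spatial_scale > 0,
            gray_scale > 0, neighborhood_radius >= 1, max_iterations >= 1,
            tolerance > 0)
  structure(list(cluster_count = as.integer(cluster_count),
                 fuzzifier = fuzzifier, spatial_scale = spatial_scale,
                 gray_scale = gray_scale,
                 neighborhood_radius = as.integer(neighborhood_radius),
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, seed = as.integer(seed)),
            class = "fgfcm_params")
}

# Shift a matrix by (dr, dc) with replicate padding.
shift_replicate <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) + dr, 1L), h)
  ci <- pmin(pmax(seq_len(w) + dc, 1L), w)
  m[ri, ci, drop = FALSE]
}

#' FGFCM pre-filter
#'
#' Replaces each pixel by the weighted mean of its neighbours (the centre
#' pixel itself carries no weight), where a neighbour at Chebyshev offset d
#' with intensity x_j contributes weight
#' exp(-d/lambda_s) * exp(-(x_j - x_i)^2 / (lambda_g * sigma_i^2)),
#' sigma_i^2 being the mean squared intensity deviation of the neighbourhood
#' from the centre. When the whole neighbourhood equals the centre
#' (sigma_i = 0) the pixel is left unchanged. Output is rounded to \[0,255\].
#'
#' @param img a \code{raster_image}.
#' @param params an \code{fgfcm_params} object.
#' @return the filtered \code{raster_image}.
#' @export
filtered_image <- function(img, params = fgfcm_params()) {
  stopifnot(inherits(img, "raster_image"))
  x <- img$pixels
  r <- params$neighborhood_radius
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  # local gray spread around the centre pixel
  sig2 <- 0
  for (i in seq_len(nrow(offs))) {
    xj <- shift_replicate(x, offs$dr[i], offs$dc[i])
    sig2 <- sig2 + (xj - x)^2
  }
  sig2 <- sig2 / nrow(offs)
  num <- 0; den <- 0
  for (i in seq_len(nrow(offs))) {
    d <- max(abs(offs$dr[i]), abs(offs$dc[i]))
    ws <- exp(-d / params$spatial_scale)
    xj <- shift_replicate(x, offs$dr[i], offs$dc[i])
    d2 <- (xj - x)^2
    wg <- ifelse(d2 == 0, 1,
                 ifelse(sig2 > 0, exp(-d2 / (params$gray_scale * sig2)), 0))
    num <- num + ws * wg * xj
    den <- den + ws * wg
  }
  xi <- num / den
  xi[sig2 == 0] <- x[sig2 == 0]
  raster_image(clip255(round_half_up(xi)), img$band)
}

#' Segment a band image with FGFCM
#'
#' Runs the FGFCM pre-filter, then histogram-weighted fuzzy c-means over the
#' gray levels of the filtered image, minimizing
#' J = sum_l sum_k gamma_l u_kl^m (xi_l - v_k)^2
#' with the standard alternating membership/centroid updates. Centroids are
#' initialized deterministically at evenly spaced quantiles of the filtered
#' histogram; convergence is declared when the largest centroid shift falls
#' below \code{tolerance}. Per-pixel memberships are obtained by looking up
#' each pixel's filtered gray level. Clusters are reported in ascending
#' centroid order.
#'
#' @param img a \code{raster_image}.
#' @param params an \code{fgfcm_params} object.
#' @param init_centroids optional numeric vector of C starting centroids
#'   (gray levels); overrides the quantile initialization.
#' @return an \code{fgfcm_result}: centroids (ascending), per-level and
#'   per-pixel memberships, C denormalized cluster images, the filtered
#'   image, the objective trace, \code{iterations_run} and
#'   \code{final_objective}.
#' @export
fgfcm_segment <- function(img, params = fgfcm_params(),
                          init_centroids = NULL) {
  stopifnot(inherits(img, "raster_image"))
  C <- params$cluster_count; m <- params$fuzzifier
  filt <- filtered_image(img, params)
  xi <- filt$pixels
  gamma_all <- tabulate(as.integer(xi) + 1L, nbins = 256L)
  levels <- which(gamma_all > 0L) - 1L
  gamma <- gamma_all[levels + 1L]
  L <- length(levels)
  if (L < C)
    stop("degenerate input: only ", L, " distinct gray levels after ",
         "filtering, fewer than cluster_count = ", C)
  if (is.null(init_centroids)) {
    cum <- cumsum(gamma) / sum(gamma)
    v <- vapply((seq_len(C) - 0.5) / C,
                function(q) levels[which(cum >= q)[1]], numeric(1))
    if (anyDuplicated(v))  # collapse guard: spread over distinct levels
      v <- levels[unique(pmax(1, round((seq_len(C) - 0.5) / C * L)))][seq_len(C)]
    if (anyDuplicated(v) || anyNA(v))
      v <- levels[round(seq(1, L, length.out = C))]
  } else {
    stopifnot(length(init_centroids) == C)
    v <- as.numeric(init_centroids)
  }
  exp_u <- 2 / (m - 1)
  trace <- numeric(0)
  u <- NULL
  for (it in seq_len(params$max_iterations)) {
    d2 <- outer(levels, v, `-`)^2                 # L x C
    u <- matrix(0, L, C)
    zero <- d2 < 1e-300
    hit <- rowSums(zero) > 0
    if (any(hit))
      u[hit, ] <- zero[hit, , drop = FALSE] /
        rowSums(zero[hit, , drop = FALSE])
    if (any(!hit)) {
      w <- d2[!hit, , drop = FALSE]^(-1 / (m - 1))
      u[!hit, ] <- w / rowSums(w)
    }
    um <- gamma * u^m
    v_new <- colSums(um * levels) / colSums(um)
    trace <- c(trace, sum(um * outer(levels, v_new, `-`)^2))
    shift <- max(abs(v_new - v))
    v <- v_new
    if (shift < params$tolerance) break
  }
  ord <- order(v)
  v <- v[ord]; u <- u[, ord, drop = FALSE]
  # per-pixel memberships by gray-level lookup
  idx <- match(as.integer(xi), levels)
  memberships <- lapply(seq_len(C), function(k) {
    matrix(u[idx, k], nrow(xi), ncol(xi))
  })
  res <- structure(list(centroids = v, level_values = levels,
                        level_weights = gamma, level_memberships = u,
                        memberships = memberships, filtered = filt,
                        iterations_run = length(trace),
                        objective_trace = trace,
                        final_objective = trace[length(trace)],
                        params = params, band = img$band),
                   class = "fgfcm_result")
  res$cluster_images <- denormalize_memberships(res)
  res
}

#' @export
print.fgfcm_result <- function(x, ...) {
  cat(sprintf("<fgfcm_result C=%d centroids=[%s] iterations=%d J=%.4g>\n",
              length(x$centroids),
              paste(sprintf("%.2f", x$centroids), collapse = ", "),
              x$iterations_run, x$final_objective))
  invisible(x)
}

#' Denormalize membership degrees into gray cluster images
#'
#' For each cluster k, the viewable cluster image takes pixel value
#' round(255 * u_k(p)) (round half up), so full membership maps to 255 and
#' zero membership to 0. Images are returned in ascending-centroid order.
#'
#' @param result an \code{fgfcm_result}.
#' @return a list of C \code{raster_image}s.
#' @export
denormalize_memberships <- function(result) {
  stopifnot(inherits(result, "fgfcm_result"))
  lapply(result$memberships, function(u)
    raster_image(clip255(round_half_up(255 * u)), result$band))
}
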