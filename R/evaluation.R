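# Quality-evaluation protocol for the compressed-vs-original pipeline: PSNR
# between the segmented images produced from the compressed path (brought
# back to the original size through the inverse F-transform) and from the
# original path, plus a pixelwise confusion comparison of the two binary
# edge maps after nearest-neighbour enlargement, and a rate-sweep runner
# aggregating both over a batch of scenes.

#' Peak signal-to-noise ratio between two images
#'
#' PSNR = 10 log10(255^2 / MSE) in decibels; identical images return the
#' sentinel cap of 99 dB.
#'
#' @param a,b \code{raster_image}s of identical dimensions.
#' @return PSNR in dB, capped at 99.
#' @export
psnr <- function(a, b) {
  stopifnot(inherits(a, "raster_image"), inherits(b, "raster_image"))
  if (image_width(a) != image_width(b) || image_height(a) != image_height(b))
    stop("psnr: images differ in size")
  mse <- mean((a$pixels - b$pixels)^2)
  if (mse == 0) return(99)
  min(99, 10 * log10(255^2 / mse))
}

#' Enlarge a binary edge map by nearest neighbour
#'
#' Used before comparing an edge map computed on a compressed (smaller) image
#' with one computed at the original size. Output is strictly binary.
#'
#' @param em an \code{edge_map}.
#' @param target_width,target_height output size, each >= the source size.
#' @return an \code{edge_map} of the target size, carrying the same
#'   parameters.
#' @export
enlarge_binary <- function(em, target_width, target_height) {
  stopifnot(inherits(em, "edge_map"))
  if (target_width < em$width || target_height < em$height)
    stop("target size must be at least the source size")
  ri <- floor((0:(target_height - 1)) * em$height / target_height) + 1L
  ci <- floor((0:(target_width - 1)) * em$width / target_width) + 1L
  structure(list(edges = em$edges[ri, ci, drop = FALSE],
                 width = as.integer(target_width),
                 height = as.integer(target_height), params = em$params),
            class = "edge_map")
}

#' Confusion-based comparison of two binary edge maps
#'
#' Pixelwise confusion counts with edge as the positive class, and the four
#' indicators accuracy, precision, recall (sensitivity) and F1. When a
#' denominator is zero the corresponding indicator is reported as 0 and
#' flagged in \code{degenerate}.
#'
#' @param reference the edge map treated as ground truth (original path).
#' @param test the edge map under evaluation (compressed path, enlarged).
#' @return an \code{edge_comparison}: tp, fp, fn, tn, accuracy, precision,
#'   recall, f1, degenerate (character vector of flagged indicators).
#' @export
compare_edge_maps <- function(reference, test) {
  stopifnot(inherits(reference, "edge_map"), inherits(test, "edge_map"))
  if (reference$width != test$width || reference$height != test$height)
    stop("compare_edge_maps: maps differ in size")
  r <- reference$edges; t_ <- test$edges
  tp <- sum(r & t_); fp <- sum(!r & t_)
  fn <- sum(r & !t_); tn <- sum(!r & !t_)
  degenerate <- character(0)
  prec <- if (tp + fp > 0) tp / (tp + fp) else {
    degenerate <- c(degenerate, "precision"); 0
  }
  rec <- if (tp + fn > 0) tp / (tp + fn) else {
    degenerate <- c(degenerate, "recall"); 0
  }
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else {
    degenerate <- c(degenerate, "f1"); 0
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 accuracy = (tp + tn) / (tp + fp + fn + tn),
                 precision = prec, recall = rec, f1 = f1,
                 degenerate = degenerate),
            class = "edge_comparison")
}

#' @export
print.edge_comparison <- function(x, ...) {
  cat(sprintf(paste0("<edge_comparison tp=%d fp=%d fn=%d tn=%d ",
                     "acc=%.3f prec=%.3f rec=%.3f f1=%.3f>\n"),
              x$tp, x$fp, x$fn, x$tn, x$accuracy, x$precision, x$recall,
              x$f1))
  invisible(x)
}

# Index of the cluster used for edge detection.
resolve_cluster_choice <- function(choice, C) {
  if (is.numeric(choice)) {
    stopifnot(choice >= 1, choice <= C)
    return(as.integer(choice))
  }
  switch(match.arg(choice, c("darkest", "brightest")),
         darkest = 1L, brightest = as.integer(C))
}

#' Run the compressed-vs-original quality sweep
#'
#' For each scene and compression rate, executes the two paths on the chosen
#' band: Path A segments the original band image with FGFCM and applies Canny
#' to the chosen cluster image; Path B compresses the band with the block
#' F-transform, segments the coefficient image with identical parameters,
#' applies Canny with identical parameters, and enlarges the binary map to
#' the original size by nearest neighbour before the confusion comparison.
#' For PSNR, each Path-B denormalized cluster image is brought back to full
#' size through the inverse F-transform (with Path B's block geometry) and
#' compared with the Path-A cluster image of the same ascending-centroid
#' rank. A rate of 1 is the identity pass-through: both paths coincide.
#'
#' @param scenes list of scenes as produced by \code{\link{scene_batch}}
#'   (each a list with an \code{image} \code{rgb_image}).
#' @param rates numeric vector of requested compression rates; each must be
#'   achievable exactly by the block catalogue (or be 1).
#' @param params an \code{fgfcm_params} object (cluster count C included).
#' @param canny_par a \code{canny_params} object, applied identically to both
#'   paths.
#' @param cluster_choice \code{"darkest"} (default), \code{"brightest"}, or a
#'   cluster index in ascending-centroid order.
#' @param band which band to analyse: "R", "G" or "B".
#' @return a \code{rate_sweep_report}: \code{details} (one row per scene and
#'   rate, with reconstruction PSNR, mean segmented-image PSNR and the four
#'   edge indicators), \code{cluster_psnr} (one row per scene, rate and
#'   cluster) and \code{summary} (per-rate means).
#' @export
run_rate_sweep <- function(scenes, rates, params = fgfcm_params(),
                           canny_par = canny_params(),
                           cluster_choice = "darkest", band = "R") {
  band <- match.arg(band, c("R", "G", "B"))
  geom <- lapply(rates, function(r) {
    g <- rate_to_blocks(r)
    if (!g$identity && abs(g$achieved_rate - r) > 1e-9)
      stop("rate ", r, " is not achievable by the block catalogue")
    g
  })
  C <- params$cluster_count
  kpick <- resolve_cluster_choice(cluster_choice, C)
  det_rows <- list(); cl_rows <- list()
  for (si in seq_along(scenes)) {
    img <- scenes[[si]]$image
    seed <- scenes[[si]]$spec$seed
    bimg <- split_bands(img)[[band]]
    segA <- fgfcm_segment(bimg, params)
    edgeA <- canny(segA$cluster_images[[kpick]], canny_par)
    for (gi in seq_along(geom)) {
      g <- geom[[gi]]
      if (g$identity) {
        cmp <- compare_edge_maps(edgeA, edgeA)
        recon_psnr <- 99
        seg_psnrs <- rep(99, C)
      } else {
        cb <- ft_compress(bimg, g$block_side, g$coeff_side)
        cimg <- coefficients_as_image(cb)
        segB <- fgfcm_segment(cimg, params)
        edgeB <- canny(segB$cluster_images[[kpick]], canny_par)
        edgeB_full <- enlarge_binary(edgeB, image_width(bimg),
                                     image_height(bimg))
        cmp <- compare_edge_maps(edgeA, edgeB_full)
        recon_psnr <- psnr(bimg, ft_decompress(cb))
        seg_psnrs <- vapply(seq_len(C), function(k) {
          full_k <- raster_image(
            clip255(round_half_up(
              inverse_grid(cb, segB$cluster_images[[k]]$pixels))), band)
          psnr(segA$cluster_images[[k]], full_k)
        }, numeric(1))
      }
      det_rows[[length(det_rows) + 1]] <- data.frame(
        scene = si, seed = if (is.null(seed)) NA_integer_ else seed,
        band = band, rate = g$achieved_rate,
        recon_psnr = recon_psnr, seg_psnr = mean(seg_psnrs),
        accuracy = cmp$accuracy, precision = cmp$precision,
        recall = cmp$recall, f1 = cmp$f1)
      cl_rows[[length(cl_rows) + 1]] <- data.frame(
        scene = si, band = band, rate = g$achieved_rate,
        cluster = seq_len(C), seg_psnr = seg_psnrs)
    }
  }
  details <- if (length(det_rows)) do.call(rbind, det_rows) else
    data.frame(scene = integer(0), seed = integer(0), band = character(0),
               rate = numeric(0), recon_psnr = numeric(0),
               seg_psnr = numeric(0), accuracy = numeric(0),
               precision = numeric(0), recall = numeric(0), f1 = numeric(0))
  summary <- if (nrow(details)) {
    agg <- aggregate(details[c("recon_psnr", "seg_psnr", "accuracy",
                               "precision", "recall", "f1")],
                     by = list(rate = details$rate), FUN = mean)
    agg[order(agg$rate), ]
  } else data.frame(rate = numeric(0))
  structure(list(details = details,
                 cluster_psnr = if (length(cl_rows)) do.call(rbind, cl_rows)
                                else data.frame(),
                 summary = summary, band = band, params = params,
                 canny_params = canny_par, cluster_choice = cluster_choice),
            class = "rate_sweep_report")
}

#' @export
print.rate_sweep_report <- function(x, ...) {
  cat(sprintf("<rate_sweep_report band=%s scenes=%d rates=%s>\n", x$band,
              length(unique(x$details$scene)),
              paste(sort(unique(x$details$rate)), collapse = ", ")))
  if (nrow(x$summary)) print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a sweep report to CSV + JSON
#'
#' @param report a \code{rate_sweep_report}.
#' @param csv_path destination for the per-scene detail rows.
#' @param json_path destination for the per-rate summary.
#' @export
write_sweep_report <- function(report, csv_path, json_path) {
  stopifnot(inherits(report, "rate_sweep_report"))
  utils::write.csv(report$details, csv_path, row.names = FALSE)
  jsonlite::write_json(report$summary, json_path, digits = NA)
  invisible(NULL)
}
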