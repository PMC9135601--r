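# Orchestration of the full dashboard workflow: band split, optional
# F-transform compression, FGFCM segmentation, optional Canny edge
# detection, artifact writing with a run manifest, and a minimal JSON-lines
# lesion-record log standing in for the patient's medical record.

#' Pipeline configuration
#'
#' Bundles every choice the expert makes when analysing a lesion photograph.
#'
#' @param requested_rate compression rate in (0, 1]; 1 disables compression.
#' @param fgfcm an \code{fgfcm_params} object (includes the cluster count C).
#' @param canny a \code{canny_params} object, or NULL to skip edge detection.
#' @param bands bands to analyse: subset of c("R","G","B") or "all".
#' @param cluster_choice cluster used for edge detection: "darkest",
#'   "brightest" or an index.
#' @param marker_physical_side printed marker side in cm (used by the
#'   measurement stage when a marker is present).
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(requested_rate = 0.25, fgfcm = fgfcm_params(),
                            canny = canny_params(), bands = "R",
                            cluster_choice = "darkest",
                            marker_physical_side = 5) {
  if (identical(bands, "all")) bands <- c("R", "G", "B")
  stopifnot(all(bands %in% c("R", "G", "B")),
            requested_rate > 0, requested_rate <= 1)
  structure(list(requested_rate = requested_rate, fgfcm = fgfcm,
                 canny = canny, bands = bands,
                 cluster_choice = cluster_choice,
                 marker_physical_side = marker_physical_side),
            class = "pipeline_config")
}

config_snapshot <- function(config) {
  list(requested_rate = config$requested_rate,
       fgfcm = unclass(config$fgfcm),
       canny = if (is.null(config$canny)) NULL else unclass(config$canny),
       bands = config$bands, cluster_choice = config$cluster_choice,
       marker_physical_side = config$marker_physical_side)
}

#' Run the analysis pipeline on one photograph
#'
#' Per selected band: split, optionally compress (the segmentation then runs
#' on the coefficient image), segment into C clusters, write the C
#' denormalized cluster images, and optionally extract the contour of the
#' chosen cluster with Canny. All artifacts plus a JSON run manifest are
#' written under \code{output_dir}. On a stage failure a FAILED marker file
#' naming the stage is left in the output directory and the error is
#' re-signalled.
#'
#' @param image_path path to an input PNG.
#' @param config a \code{pipeline_config}.
#' @param output_dir directory for artifacts (created if missing).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(image_path, config = pipeline_config(),
                         output_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  stage <- "read"
  stem <- sub("\\.png$", "", basename(image_path), ignore.case = TRUE)
  manifest <- list(input = image_path,
                   input_md5 = unname(tools::md5sum(image_path)),
                   config = config_snapshot(config), bands = list(),
                   artifacts = character(0))
  on_fail <- function(e) {
    writeLines(paste0("FAILED at stage: ", stage, "\n",
                      conditionMessage(e)),
               file.path(output_dir, paste0(stem, ".FAILED")))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    img <- read_png(image_path)
    stage <- "split"
    bands <- split_bands(img)
    for (bn in config$bands) {
      bimg <- bands[[bn]]
      binfo <- list(band = bn)
      seg_input <- bimg
      if (config$requested_rate < 1) {
        stage <- paste0("compress:", bn)
        g <- rate_to_blocks(config$requested_rate)
        cb <- ft_compress(bimg, g$block_side, g$coeff_side)
        binfo$achieved_rate <- cb$achieved_rate
        fp <- file.path(output_dir, paste0(stem, ".", bn, ".ftc.json"))
        write_ftc(cb, fp)
        manifest$artifacts <- c(manifest$artifacts, fp)
        seg_input <- coefficients_as_image(cb)
      } else binfo$achieved_rate <- 1
      stage <- paste0("segment:", bn)
      seg <- fgfcm_segment(seg_input, config$fgfcm)
      binfo$centroids <- seg$centroids
      binfo$iterations <- seg$iterations_run
      for (k in seq_along(seg$cluster_images)) {
        fp <- file.path(output_dir,
                        paste0(stem, ".", bn, ".cluster", k, ".png"))
        write_png(seg$cluster_images[[k]], fp)
        manifest$artifacts <- c(manifest$artifacts, fp)
      }
      if (!is.null(config$canny)) {
        stage <- paste0("edges:", bn)
        kpick <- resolve_cluster_choice(config$cluster_choice,
                                        config$fgfcm$cluster_count)
        em <- canny(seg$cluster_images[[kpick]], config$canny)
        binfo$edge_pixels <- edge_pixel_count(em)
        fp <- file.path(output_dir, paste0(stem, ".", bn, ".edges.png"))
        write_png(edge_map_as_image(em), fp)
        manifest$artifacts <- c(manifest$artifacts, fp)
      }
      manifest$bands[[bn]] <- binfo
    }
    stage <- "manifest"
    mp <- file.path(output_dir, paste0(stem, ".manifest.json"))
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                         null = "null")
    manifest$manifest_path <- mp
    invisible(manifest)
  }, error = on_fail)
}

#' Construct a lesion record
#'
#' One examination of one patient: an opaque patient identifier, a
#' timestamp, the analysed image (path + content hash) and the stage
#' outputs worth keeping for longitudinal review.
#'
#' @param patient opaque patient identifier string.
#' @param timestamp POSIXct or ISO-8601 string.
#' @param image_path analysed image (hashed if the file exists).
#' @param outputs list of stage outputs (achieved rate, centroids, edge
#'   counts, measurements...).
#' @param config a \code{pipeline_config} snapshot to embed.
#' @return a \code{lesion_record} list.
#' @export
lesion_record <- function(patient, timestamp, image_path,
                          outputs = list(), config = NULL) {
  ts <- if (inherits(timestamp, "POSIXt"))
    format(timestamp, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC") else
      as.character(timestamp)
  structure(list(patient = as.character(patient), timestamp = ts,
                 image_path = image_path,
                 image_md5 = if (file.exists(image_path))
                   unname(tools::md5sum(image_path)) else NA_character_,
                 outputs = outputs,
                 config = if (is.null(config)) NULL else
                   config_snapshot(config)),
            class = "lesion_record")
}

#' Append a lesion record to a JSON-lines store
#'
#' Records for one patient must be strictly time-ordered; an out-of-order
#' timestamp is rejected and the store is left unchanged. The append is
#' atomic: the new store is written to a temporary file and renamed over
#' the old one.
#'
#' @param store_path path of the JSON-lines store (created on first append).
#' @param record a \code{lesion_record}.
#' @export
append_record <- function(store_path, record) {
  stopifnot(inherits(record, "lesion_record"))
  existing <- if (file.exists(store_path)) readLines(store_path) else
    character(0)
  for (line in existing) {
    prev <- jsonlite::fromJSON(line)
    if (identical(prev$patient, record$patient) &&
        prev$timestamp >= record$timestamp)
      stop("out-of-order record for patient ", record$patient,
           ": existing timestamp ", prev$timestamp, " >= ", record$timestamp)
  }
  newline <- jsonlite::toJSON(unclass(record), auto_unbox = TRUE,
                              digits = NA, null = "null")
  tmp <- paste0(store_path, ".tmp")
  writeLines(c(existing, newline), tmp)
  file.rename(tmp, store_path)
  invisible(NULL)
}

#' Read all records for a patient, in time order
#'
#' @param store_path path of the JSON-lines store.
#' @param patient patient identifier.
#' @return list of records.
#' @export
read_records <- function(store_path, patient) {
  if (!file.exists(store_path)) return(list())
  recs <- lapply(readLines(store_path), jsonlite::fromJSON)
  recs <- Filter(function(r) identical(r$patient, patient), recs)
  recs[order(vapply(recs, function(r) r$timestamp, character(1)))]
}
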