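# File interchange: multi-page TIFF for stacks and multi-channel scenes
# (intensities rescaled to [0, 1]; the scale factor travels in a YAML/JSON
# sidecar), CSV for tables and traces, JSON for truth records.

#' Write a speckle stack as multi-page TIFF plus YAML metadata
#'
#' @param stack A `speckle_stack`.
#' @param tiff_path Output TIFF path; the metadata YAML goes to the same
#'   path with extension `.yaml`.
#' @return Invisibly, the metadata list.
#' @export
write_speckle_stack <- function(stack, tiff_path) {
  stopifnot(inherits(stack, "speckle_stack"))
  scale <- max(stack$frames, 1e-12)
  pages <- lapply(seq_len(dim(stack$frames)[3]),
                  function(t) stack$frames[, , t] / scale)
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 16L,
                  compression = "none")
  meta <- list(exposure_s = stack$exposure,
               frame_interval_s = stack$frame_interval,
               intensity_scale = scale,
               n_frames = dim(stack$frames)[3])
  yaml::write_yaml(meta, sub("\\.tiff?$", ".yaml", tiff_path))
  invisible(meta)
}

#' Read a speckle stack written by [write_speckle_stack()]
#'
#' @param tiff_path Path to the TIFF; the YAML sidecar must sit alongside.
#' @return A `speckle_stack`.
#' @export
read_speckle_stack <- function(tiff_path) {
  meta <- yaml::read_yaml(sub("\\.tiff?$", ".yaml", tiff_path))
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  frames <- array(0, c(dim(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) {
    frames[, , t] <- pages[[t]] * meta$intensity_scale
  }
  structure(list(frames = frames, exposure = meta$exposure_s,
                 frame_interval = meta$frame_interval_s,
                 timestamps = (seq_along(pages) - 1) * meta$frame_interval_s,
                 window = NULL, beta = NULL, scene = NULL),
            class = "speckle_stack")
}

#' Write a multi-channel scene as multi-page TIFF
#'
#' Channels are written as pages, rescaled to `[0, 1]`; the channel map
#' and scale go to a YAML sidecar.
#'
#' @param image rows x cols x channels array.
#' @param tiff_path Output path.
#' @param channels Character vector of channel names (one per page).
#' @return Invisibly, the metadata list.
#' @export
write_scene_tiff <- function(image, tiff_path,
                             channels = paste0("ch", seq_len(dim(image)[3]))) {
  lo <- min(image); hi <- max(image)
  scale <- max(hi - lo, 1e-12)
  pages <- lapply(seq_len(dim(image)[3]),
                  function(c) (image[, , c] - lo) / scale)
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 16L,
                  compression = "none")
  meta <- list(channels = as.list(channels), offset = lo, scale = scale)
  yaml::write_yaml(meta, sub("\\.tiff?$", ".yaml", tiff_path))
  invisible(meta)
}

#' Read a scene written by [write_scene_tiff()]
#'
#' @param tiff_path Path to the TIFF.
#' @return List with `image` (array) and `channels`.
#' @export
read_scene_tiff <- function(tiff_path) {
  meta <- yaml::read_yaml(sub("\\.tiff?$", ".yaml", tiff_path))
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  img <- array(0, c(dim(pages[[1]]), length(pages)))
  for (c in seq_along(pages)) {
    img[, , c] <- pages[[c]] * meta$scale + meta$offset
  }
  list(image = img, channels = unlist(meta$channels))
}

#' Write a ground-truth record as a JSON sidecar
#'
#' @param truth Any truth object (list-like).
#' @param path Output JSON path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", force = TRUE)
  invisible(path)
}

#' Write/read serial-section area tables
#'
#' @param records A `section_area_records` data.frame.
#' @param path CSV path.
#' @export
write_section_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_section_csv
#' @export
read_section_csv <- function(path) {
  utils::read.csv(path)
}

#' Write/read tail-cuff traces
#'
#' @param trace A `cuff_trace` data.frame.
#' @param path CSV path.
#' @export
write_cuff_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cuff_csv
#' @export
read_cuff_csv <- function(path) {
  utils::read.csv(path)
}

#' Write a pseudocolor map (or any RGB array) as PNG
#'
#' @param rgb rows x cols x 3 array in `[0, 1]`.
#' @param path PNG path.
#' @export
write_map_png <- function(rgb, path) {
  png::writePNG(unclass(rgb), path)
  invisible(path)
}
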