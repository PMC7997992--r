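#' Write a trial raster as columnar text
#'
#' Standard spike-train exchange format: CSV with header
#' `cell_id, stimulus_id, trial, spike_time_s`. Ground truth (when
#' simulating) goes in a JSON sidecar via [write_ground_truth()].
#'
#' @param raster trial raster data.frame.
#' @param path output file path.
#' @export
write_raster <- function(raster, path) {
  stopifnot(all(c("cell_id", "stimulus_id", "trial", "spike_time_s") %in%
                  names(raster)))
  write.csv(raster[, c("cell_id", "stimulus_id", "trial", "spike_time_s")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial raster from columnar text
#'
#' Accepts the schema written by [write_raster()], so externally recorded
#' spike-train exports in the same columnar layout can be dropped in.
#'
#' @param path CSV file with columns `cell_id`, `stimulus_id`, `trial`,
#'   `spike_time_s`.
#' @param n_trials optional trials-per-stimulus count to attach as attribute;
#'   defaults to the maximum trial index observed.
#' @return trial raster data.frame with attribute `n_trials`.
#' @export
read_raster <- function(path, n_trials = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "stimulus_id", "trial", "spike_time_s")
  if (!all(need %in% names(df))) {
    stop("raster file must have columns: ", paste(need, collapse = ", "))
  }
  structure(df[, need], n_trials = n_trials %||% max(df$trial))
}

#' Write simulation ground truth as a JSON sidecar
#'
#' @param truth ground-truth data.frame from [simulate_population()].
#' @param path output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a scene pair as two single-channel TIFF images with a JSON sidecar
#'
#' Intensities are stored as 16-bit rasters scaled by the pair's maximum;
#' the scale factor and channel file names go to a JSON sidecar so that
#' [read_scene()] restores the original values. Requires the `tiff` package.
#'
#' @param scene a [scene_pair()].
#' @param path_prefix output path prefix; writes `<prefix>_green.tif`,
#'   `<prefix>_uv.tif` and `<prefix>.json`.
#' @return the sidecar path, invisibly.
#' @export
write_scene <- function(scene, path_prefix) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("scene raster output requires the 'tiff' package")
  }
  stopifnot(inherits(scene, "scene_pair"))
  scale <- max(scene$green, scene$uv)
  paths <- paste0(path_prefix, c("_green.tif", "_uv.tif"))
  tiff::writeTIFF(scene$green / scale, paths[1], bits.per.sample = 16)
  tiff::writeTIFF(scene$uv / scale, paths[2], bits.per.sample = 16)
  sidecar <- paste0(path_prefix, ".json")
  jsonlite::write_json(list(green = basename(paths[1]),
                            uv = basename(paths[2]),
                            scale = scale, units = "arbitrary intensity"),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a scene pair written by [write_scene()]
#'
#' @param sidecar path to the JSON sidecar.
#' @return a [scene_pair()].
#' @export
read_scene <- function(sidecar) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("scene raster input requires the 'tiff' package")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dir <- dirname(sidecar)
  g <- tiff::readTIFF(file.path(dir, meta$green)) * meta$scale
  u <- tiff::readTIFF(file.path(dir, meta$uv)) * meta$scale
  scene_pair(g, u)
}
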