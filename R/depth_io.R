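# Depth video container: a directory of 16-bit grayscale TIFF frames
# (depth in millimetres, 0 = invalid) plus a JSON sidecar (`video.json`)
# with fps and sensor intrinsics. A reader adapter interface lets other
# on-disk formats (e.g. a converter from proprietary sensor containers) be
# plugged in without touching the pipeline.

#' Construct a depth frame
#'
#' @param depth Numeric matrix of depth values in millimetres (rows = image
#'   rows); 0 marks invalid pixels.
#' @param timestamp Acquisition time in seconds.
#' @param index Frame number (0-based).
#' @return Object of class `ks_depth_frame`.
#' @export
depth_frame <- function(depth, timestamp = 0, index = 0L) {
  depth <- as.matrix(depth)
  if (any(depth < 0)) stop_invalid("depth values must be non-negative")
  structure(list(depth = depth, timestamp = timestamp,
                 index = as.integer(index)),
            class = "ks_depth_frame")
}

frame_depth <- function(frame) {
  if (inherits(frame, "ks_depth_frame")) frame$depth else as.matrix(frame)
}

#' Write a depth video to a frame directory
#'
#' One 16-bit grayscale TIFF per frame (`frame_000000.tif`, depth in mm)
#' plus `video.json` holding fps and the camera model.
#'
#' @param frames List of depth matrices (mm) or `ks_depth_frame` objects.
#' @param dir Output directory (created if missing).
#' @param fps Frames per second.
#' @param camera Optional [camera_model()] stored in the sidecar.
#' @return `dir`, invisibly.
#' @export
write_depth_video <- function(frames, dir, fps, camera = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(frames)) {
    d <- frame_depth(frames[[i]])
    tiff::writeTIFF(pmin(pmax(round(d), 0), 65535) / 65535,
                    file.path(dir, sprintf("frame_%06d.tif", i - 1)),
                    bits.per.sample = 16L, compression = "none")
  }
  meta <- list(format = "kennelscope-depth-v1", fps = fps,
               n_frames = length(frames))
  if (!is.null(camera))
    meta$camera <- list(width = camera$width, height = camera$height,
                        fx = camera$fx, fy = camera$fy,
                        cx = camera$cx, cy = camera$cy,
                        R = camera$R, position = camera$position)
  jsonlite::write_json(meta, file.path(dir, "video.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Frame reader adapter for 16-bit TIFF directories
#'
#' An adapter is a list with elements `list_frames(dir)` returning frame file
#' paths in order, and `read_frame(path)` returning a depth matrix in mm.
#' Supplying a different adapter to [read_depth_video()] plugs in another
#' container format.
#'
#' @export
tiff_frame_adapter <- function() {
  list(
    list_frames = function(dir) sort(list.files(dir, pattern = "^frame_\\d+\\.tif$",
                                                full.names = TRUE)),
    read_frame = function(path) round(tiff::readTIFF(path) * 65535))
}

#' Read a depth video from a frame directory
#'
#' @param dir Directory written by [write_depth_video()] (or any directory
#'   understood by the supplied adapter, with a `video.json` sidecar).
#' @param adapter Reader adapter; see [tiff_frame_adapter()].
#' @return List with `frames` (list of `ks_depth_frame`), `fps`, and `camera`
#'   (a [camera_model()] or `NULL`).
#' @export
read_depth_video <- function(dir, adapter = tiff_frame_adapter()) {
  meta <- jsonlite::read_json(file.path(dir, "video.json"),
                              simplifyVector = TRUE)
  paths <- adapter$list_frames(dir)
  frames <- lapply(seq_along(paths), function(i)
    depth_frame(adapter$read_frame(paths[[i]]),
                timestamp = (i - 1) / meta$fps, index = i - 1L))
  cam <- NULL
  if (!is.null(meta$camera)) {
    cam <- camera_model(width = meta$camera$width, height = meta$camera$height)
    cam$fx <- meta$camera$fx; cam$fy <- meta$camera$fy
    cam$cx <- meta$camera$cx; cam$cy <- meta$camera$cy
    cam$R <- matrix(unlist(meta$camera$R), 3, 3)
    cam$position <- as.numeric(meta$camera$position)
  }
  list(frames = frames, fps = meta$fps, camera = cam)
}
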