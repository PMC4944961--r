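# Ethogram quantification: per-label durations and bouts, interval
# breakdowns, activity level, travelled distance and the nine-square grid
# occupancy of the pen floor.

#' Per-frame annotations
#'
#' @param frame 0-based frame indices.
#' @param time_s Timestamps, seconds (consistent with `fps`).
#' @param posture Posture label per frame (`unknown` frames are counted in
#'   total time but reported as `unscored`).
#' @param x,y Ground position, metres.
#' @param fps Frames per second.
#' @return Data frame of class `ks_annotations` with attribute `fps`.
#' @export
frame_annotations <- function(frame, time_s, posture, x, y, fps) {
  n <- length(frame)
  stopifnot(length(time_s) == n, length(posture) == n,
            length(x) == n, length(y) == n)
  structure(data.frame(frame = frame, time_s = time_s,
                       posture = as.character(posture), x_m = x, y_m = y),
            fps = fps, class = c("ks_annotations", "data.frame"))
}

#' Summarise behaviour durations, bouts and interval breakdown
#'
#' Duration per label is frame count times the frame period; a bout is a
#' maximal run of one label (an optional minimum-bout filter, default off,
#' merges shorter runs into their predecessor). The interval table covers
#' the whole video with a possibly short last interval.
#'
#' @param ann A [frame_annotations()] data frame.
#' @param interval_s Interval length in seconds (default 300, i.e. 5-minute
#'   intervals).
#' @param min_bout_s Minimum bout duration in seconds (0 disables the
#'   filter).
#' @return Object of class `ks_behaviour_summary`: `totals` (label,
#'   duration_s, bouts, frames), `intervals` (interval_id, label,
#'   duration_s), `total_s`, `fps`. Unknown postures appear as label
#'   `unscored`.
#' @export
summarize_behaviour <- function(ann, interval_s = 300, min_bout_s = 0) {
  if (nrow(ann) == 0) stop_invalid("invalid input: empty annotations")
  fps <- attr(ann, "fps")
  period <- 1 / fps
  lab <- ann$posture
  lab[is.na(lab) | lab == "unknown"] <- "unscored"
  if (min_bout_s > 0) {
    r <- rle(lab)
    min_frames <- max(1, round(min_bout_s * fps))
    for (i in seq_along(r$lengths)) {
      if (r$lengths[i] < min_frames && i > 1) r$values[i] <- r$values[i - 1]
    }
    lab <- inverse.rle(r)
  }
  labels <- unique(c(intersect(c(POSTURE_LEVELS, "unscored"), lab),
                     setdiff(lab, c(POSTURE_LEVELS, "unscored"))))
  r <- rle(lab)
  totals <- data.frame(
    label = labels,
    duration_s = vapply(labels, function(l) sum(lab == l) * period, 0),
    bouts = vapply(labels, function(l) sum(r$values == l), 0),
    frames = vapply(labels, function(l) sum(lab == l), 0),
    row.names = NULL)
  iv <- pmin(floor(ann$time_s / interval_s),
             ceiling(nrow(ann) * period / interval_s) - 1)
  grid <- expand.grid(interval_id = sort(unique(iv)), label = labels,
                      stringsAsFactors = FALSE)
  grid$duration_s <- mapply(function(i, l) sum(iv == i & lab == l) * period,
                            grid$interval_id, grid$label)
  structure(list(totals = totals, intervals = grid,
                 total_s = nrow(ann) * period, fps = fps),
            class = "ks_behaviour_summary")
}

#' Activity metrics: time moving and distance travelled
#'
#' Distance is the summed length of consecutive displacements (path length,
#' not net displacement); time moving is the total duration of frames whose
#' instantaneous speed exceeds the threshold.
#'
#' @param traj A `ks_trajectory`.
#' @param speed_threshold Metres/second (default 0.1).
#' @return `c(time_moving_s, distance_m)`.
#' @export
activity_metrics <- function(traj, speed_threshold = 0.1) {
  n <- nrow(traj)
  if (n < 2) return(c(time_moving_s = 0, distance_m = 0))
  fps <- attr(traj, "fps")
  step <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  speed <- step * fps
  c(time_moving_s = sum(speed > speed_threshold) / fps,
    distance_m = sum(step))
}

#' Nine-square grid occupancy
#'
#' The pen floor is divided into a 3x3 grid; each frame's period is credited
#' to the cell containing its position. Cells are half-open `[lo, hi)`
#' intervals (the far edges closed) so boundary positions are never counted
#' twice; the matrix is indexed row-major from the pen origin (rows = y
#' bands, columns = x bands).
#'
#' @param traj A `ks_trajectory`.
#' @param pen_bounds Named bounds (defaults to the trajectory's attribute).
#' @return 3x3 matrix of seconds, class `ks_grid_occupancy`.
#' @export
grid_occupancy <- function(traj, pen_bounds = attr(traj, "pen_bounds")) {
  fps <- attr(traj, "fps")
  occ <- matrix(0, 3, 3)
  if (nrow(traj) > 0) {
    cx <- cut_cell(traj$x, pen_bounds["xmin"], pen_bounds["xmax"])
    cy <- cut_cell(traj$y, pen_bounds["ymin"], pen_bounds["ymax"])
    for (i in seq_len(nrow(traj))) occ[cy[i], cx[i]] <- occ[cy[i], cx[i]] + 1
    occ <- occ / fps
  }
  structure(occ, class = c("ks_grid_occupancy", class(occ)))
}

cut_cell <- function(v, lo, hi) {
  idx <- 1L + pmin(2L, pmax(0L, floor((v - lo) / ((hi - lo) / 3))))
  as.integer(idx)
}

# ---- CSV export -----------------------------------------------------------

#' Export ethogram outputs as CSV
#'
#' Deterministic column orders (dot decimal separator always):
#' annotations `frame,time_s,posture,x_m,y_m`; summary
#' `label,duration_s,bouts,interval_id` (video totals have empty
#' `interval_id` and carry the bout count; per-interval rows have empty
#' `bouts`); grid `row,col,seconds`.
#'
#' @param x Annotations, summary or grid occupancy object.
#' @param path Output file.
#' @export
export_csv <- function(x, path) UseMethod("export_csv")

#' @export
export_csv.ks_annotations <- function(x, path) {
  write.csv(as.data.frame(x)[, c("frame", "time_s", "posture", "x_m", "y_m")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
export_csv.ks_behaviour_summary <- function(x, path) {
  tot <- data.frame(label = x$totals$label, duration_s = x$totals$duration_s,
                    bouts = x$totals$bouts, interval_id = NA_integer_)
  ivl <- data.frame(label = x$intervals$label,
                    duration_s = x$intervals$duration_s,
                    bouts = NA_real_, interval_id = x$intervals$interval_id)
  write.csv(rbind(tot, ivl), path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
export_csv.ks_grid_occupancy <- function(x, path) {
  df <- data.frame(row = rep(1:3, each = 3), col = rep(1:3, times = 3))
  df$seconds <- x[cbind(df$row, df$col)]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back exported annotations
#'
#' @param path CSV written by [export_csv()].
#' @param fps Frames per second of the recording.
#' @export
read_annotations_csv <- function(path, fps) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  frame_annotations(df$frame, df$time_s, df$posture, df$x_m, df$y_m, fps)
}
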