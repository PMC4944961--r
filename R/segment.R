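# Foreground segmentation: remove the calibrated pen planes from the point
# cloud and keep the largest connected off-plane component as the animal.

# 8-connected labelling: EBImage::bwlabel is 4-connected, so diagonally
# adjacent labels are merged afterwards with a small union-find.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab < 2) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  for (sh in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(nr - 1), if (sh[2] > 0) seq_len(nc - 1) else 2:nc]
    b <- lab[2:nr, if (sh[2] > 0) 2:nc else seq_len(nc - 1)]
    keep <- a > 0 & b > 0 & a != b
    if (any(keep)) {
      for (p in unique(cbind(a[keep], b[keep]), MARGIN = 1)[, , drop = FALSE] |>
             asplit(1)) {
        ra <- find(p[1]); rb <- find(p[2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  lab[lab > 0] <- relab[lab[lab > 0]]
  lab
}

#' Segment the animal blob from a depth frame
#'
#' Back-projects valid pixels to 3D, discards everything within `threshold`
#' of any calibrated scene plane or outside the pen volume, and keeps the
#' largest 8-connected component of the remaining pixels.
#'
#' @param frame A [depth_frame()] or depth matrix (mm).
#' @param scene A [scene_model()]; frame dimensions must match its camera.
#' @param threshold Minimum distance from every plane, metres (default 5 cm:
#'   above sensor depth noise, below leg clearance).
#' @param min_pixels Minimum blob size in pixels; smaller components give a
#'   no-detection (default 200 at 320x240).
#' @return An object of class `ks_blob` (`mask` logical matrix, `pixels`
#'   0-based `(row, col)` matrix, `points` camera-frame 3D point cloud in
#'   metres, `points_pen`, `barycentre` camera frame, `barycentre_pen`,
#'   `npix`), or `NULL` for no-detection.
#' @export
segment_frame <- function(frame, scene, threshold = 0.05, min_pixels = 200L) {
  stopifnot(threshold > 0)
  d <- frame_depth(frame)
  cam <- scene$camera
  if (nrow(d) != cam$height || ncol(d) != cam$width)
    stop_invalid("configuration error: frame dimensions inconsistent with scene calibration")
  valid <- d > 0
  if (!any(valid)) return(NULL)
  idx <- which(valid)
  rows <- ((idx - 1) %% nrow(d))        # 0-based
  cols <- ((idx - 1) %/% nrow(d))
  z <- d[idx] / 1000
  pc <- backproject_cam(cols, rows, z, cam)
  pp <- cam_to_pen(pc, cam)
  b <- scene$pen_bounds
  ok <- pp[, 1] >= b["xmin"] - threshold & pp[, 1] <= b["xmax"] + threshold &
    pp[, 2] >= b["ymin"] - threshold & pp[, 2] <= b["ymax"] + threshold &
    pp[, 3] >= -threshold & pp[, 3] <= scene$wall_height
  for (pl in scene$planes) ok <- ok & point_plane_distance(pp, pl) > threshold
  if (!any(ok)) return(NULL)
  fg <- matrix(FALSE, nrow(d), ncol(d))
  fg[idx[ok]] <- TRUE
  lab <- label_components8(fg)
  sizes <- tabulate(lab[lab > 0])
  best <- which.max(sizes)
  if (sizes[best] < min_pixels) return(NULL)
  mask <- lab == best
  sel <- ok & (lab[idx] == best)
  points <- pc[sel, , drop = FALSE]
  bary <- colMeans(points)
  structure(list(mask = mask,
                 pixels = cbind(row = rows[sel], col = cols[sel]),
                 points = points,
                 points_pen = pp[sel, , drop = FALSE],
                 barycentre = bary,
                 barycentre_pen = as.numeric(cam_to_pen(bary, cam)),
                 npix = sizes[best]),
            class = "ks_blob")
}

#' Barycentre of a blob
#'
#' Arithmetic mean of the blob's 3D points (camera frame, metres) — the
#' centre of mass of the blob image.
#'
#' @param blob A `ks_blob`, or an n x 3 point matrix.
#' @export
compute_barycentre <- function(blob) {
  pts <- if (inherits(blob, "ks_blob")) blob$points else rbind(blob)
  if (is.null(pts) || nrow(pts) == 0)
    stop_invalid("invalid input: empty blob has no barycentre")
  colMeans(pts)
}
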