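# Scene geometry: pen coordinate frame, camera model, plane definitions and
# the ground-plane homography.
#
# Conventions (declared once, used everywhere):
#   * Pen frame: metres; origin at the pen corner nearest the sensor's left
#     edge; x runs along the front fence, y into the pen, z up.
#   * Camera frame: x right, y down, z forward (optical axis); depth images
#     store the camera-frame z coordinate in millimetres, 0 = invalid.
#   * Image pixels are 0-based (u = column, v = row).

#' Pinhole camera model
#'
#' Describes the depth sensor: image size, intrinsics and pose in the pen
#' frame. The pose is given look-at style; the world up direction is the pen
#' z axis.
#'
#' @param position Camera centre in pen coordinates (metres), length-3.
#' @param target Point the optical axis passes through (pen frame, metres).
#' @param width,height Image size in pixels.
#' @param fov_h Horizontal field of view in degrees (default 58, typical of
#'   consumer structured-light depth sensors).
#' @return An object of class `ks_camera` with intrinsics (`fx`, `fy`, `cx`,
#'   `cy`) and extrinsics (`R` mapping pen to camera axes, `position`).
#' @export
camera_model <- function(position = c(1.5, -2.0, 1.5),
                         target = c(1.5, 1.5, 0.0),
                         width = 320L, height = 240L, fov_h = 58) {
  position <- as.numeric(position)
  target <- as.numeric(target)
  stopifnot(length(position) == 3, length(target) == 3, width > 0, height > 0)
  fwd <- unit(target - position)
  up <- c(0, 0, 1)
  if (abs(sum(fwd * up)) > 0.999)
    stop_invalid("camera optical axis must not be vertical")
  xc <- unit(cross3(fwd, up))   # right
  yc <- cross3(fwd, xc)         # down
  R <- rbind(xc, yc, fwd)       # pen -> camera rotation (rows = camera axes)
  dimnames(R) <- NULL
  fx <- (width / 2) / tan(fov_h * pi / 360)
  structure(list(width = as.integer(width), height = as.integer(height),
                 fx = fx, fy = fx,
                 cx = (width - 1) / 2, cy = (height - 1) / 2,
                 R = R, position = position),
            class = "ks_camera")
}

#' Scene model of the pen
#'
#' Holds the calibrated planes of the enclosure (floor, walls, wire fence)
#' and the pen bounds on the ground plane, together with the camera. Exactly
#' one plane is tagged `floor`. The fence plane (front of the pen, y = 0) is
#' see-through wire mesh: it takes part in foreground/plane distance tests
#' but is never rendered as a surface.
#'
#' @param pen_size Ground rectangle of the pen, metres, `c(width, depth)`.
#' @param camera A [camera_model()].
#' @param wall_height Height of the solid walls, metres.
#' @return Object of class `ks_scene` with elements `planes` (list of
#'   `list(normal, offset, tag)` with unit normal, plane equation
#'   `normal . x == offset` in pen coordinates), `pen_bounds`
#'   (`c(xmin, xmax, ymin, ymax)`), `wall_height`, `camera`.
#' @export
scene_model <- function(pen_size = c(3, 3), camera = camera_model(),
                        wall_height = 2) {
  stopifnot(length(pen_size) == 2, all(pen_size > 0))
  W <- pen_size[1]; D <- pen_size[2]
  planes <- list(
    list(normal = c(0, 0, 1), offset = 0, tag = "floor"),
    list(normal = c(1, 0, 0), offset = 0, tag = "wall"),
    list(normal = c(1, 0, 0), offset = W, tag = "wall"),
    list(normal = c(0, 1, 0), offset = D, tag = "wall"),
    list(normal = c(0, 1, 0), offset = 0, tag = "fence"))
  structure(list(planes = planes,
                 pen_bounds = c(xmin = 0, xmax = W, ymin = 0, ymax = D),
                 wall_height = wall_height,
                 camera = camera),
            class = "ks_scene")
}

#' Fit a plane through three points
#'
#' Primitive used to define scene planes from user-clicked points.
#'
#' @param p1,p2,p3 Length-3 points (metres).
#' @return `list(normal, offset)` with unit normal and `normal . x == offset`.
#' @export
plane_from_points <- function(p1, p2, p3) {
  n <- cross3(p2 - p1, p3 - p1)
  if (vnorm(n) < 1e-10) stop_invalid("collinear points do not define a plane")
  n <- unit(n)
  list(normal = n, offset = sum(n * p1))
}

# Signed-free distance from points (n x 3) to a plane.
point_plane_distance <- function(points, plane) {
  abs(points %*% plane$normal - plane$offset)[, 1]
}

pen_to_cam <- function(points, camera) {
  points <- rbind(points)
  sweep(points, 2, camera$position) %*% t(camera$R)
}

cam_to_pen <- function(points, camera) {
  points <- rbind(points)
  sweep(points %*% camera$R, 2, camera$position, `+`)
}

# Project camera-frame points (n x 3, z > 0) to 0-based pixel coordinates.
project_cam <- function(points, camera) {
  points <- rbind(points)
  cbind(u = camera$fx * points[, 1] / points[, 3] + camera$cx,
        v = camera$fy * points[, 2] / points[, 3] + camera$cy)
}

# Back-project 0-based pixels with metric depth to camera-frame points.
backproject_cam <- function(u, v, depth_m, camera) {
  cbind((u - camera$cx) / camera$fx * depth_m,
        (v - camera$cy) / camera$fy * depth_m,
        depth_m)
}

#' Fit a homography between point correspondences
#'
#' Normalised DLT estimate of the 3x3 projective map sending `src` to `dst`.
#' Used by [fit_ground_homography()]; exported because it is also the natural
#' entry point when floor correspondences come from manual annotation.
#'
#' @param src,dst n x 2 matrices of corresponding points (n >= 4, no
#'   duplicates, not all collinear).
#' @return 3x3 homography matrix `H` with `H %*% c(x, y, 1)` proportional to
#'   the destination point.
#' @export
fit_homography_points <- function(src, dst) {
  src <- rbind(src); dst <- rbind(dst)
  if (nrow(src) != nrow(dst)) stop_invalid("correspondence counts differ")
  if (nrow(unique(round(src, 9))) < 4 || nrow(unique(round(dst, 9))) < 4)
    stop_invalid("calibration error: fewer than 4 distinct correspondences")
  norm_t <- function(p) {
    ctr <- colMeans(p)
    s <- sqrt(2) / mean(sqrt(rowSums(sweep(p, 2, ctr)^2)))
    if (!is.finite(s)) stop_invalid("calibration error: degenerate points")
    rbind(c(s, 0, -s * ctr[1]), c(0, s, -s * ctr[2]), c(0, 0, 1))
  }
  Ts <- norm_t(src); Td <- norm_t(dst)
  hs <- cbind(src, 1) %*% t(Ts)
  hd <- cbind(dst, 1) %*% t(Td)
  A <- do.call(rbind, lapply(seq_len(nrow(src)), function(i) {
    x <- hs[i, 1]; y <- hs[i, 2]; xp <- hd[i, 1]; yp <- hd[i, 2]
    rbind(c(-x, -y, -1, 0, 0, 0, xp * x, xp * y, xp),
          c(0, 0, 0, -x, -y, -1, yp * x, yp * y, yp))
  }))
  sv <- svd(A, nv = 9)
  if (sv$d[8] / sv$d[1] < 1e-10)
    stop_invalid("calibration error: degenerate plane configuration")
  H <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(Td) %*% H %*% Ts
  H / H[3, 3]
}

apply_homography <- function(H, pts) {
  pts <- rbind(pts)
  ph <- cbind(pts, 1) %*% t(H)
  cbind(ph[, 1] / ph[, 3], ph[, 2] / ph[, 3])
}

#' Fit the ground-plane homography
#'
#' Computes the projective map from image coordinates to metric pen-floor
#' coordinates, without manual calibration: a grid of floor points implied by
#' the scene model is projected through the camera and a normalised DLT fit
#' is performed on the correspondences.
#'
#' @param scene A [scene_model()].
#' @param frames Optional list of depth frames; when supplied their
#'   dimensions are checked against the camera calibration.
#' @return Object of class `ks_homography`: `matrix` (3x3, image -> pen
#'   floor), plus the camera and the floor plane expressed in the camera
#'   frame (used to drop barycentres to the ground before projection).
#' @export
fit_ground_homography <- function(scene, frames = NULL) {
  cam <- scene$camera
  if (!is.null(frames)) {
    for (f in frames) {
      d <- frame_depth(f)
      if (nrow(d) != cam$height || ncol(d) != cam$width)
        stop_invalid("configuration error: frame dimensions inconsistent with scene calibration")
    }
  }
  b <- scene$pen_bounds
  gx <- seq(b["xmin"] + 0.2, b["xmax"] - 0.2, length.out = 6)
  gy <- seq(b["ymin"] + 0.4, b["ymax"] - 0.2, length.out = 6)
  floor_pts <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)), 0)
  pc <- pen_to_cam(floor_pts, cam)
  if (any(pc[, 3] <= 0.05))
    stop_invalid("calibration error: floor grid behind the camera")
  img <- project_cam(pc, cam)
  H <- fit_homography_points(img, floor_pts[, 1:2])
  # floor plane in camera frame: n_c . x == d_c
  fl <- scene$planes[[which(vapply(scene$planes, `[[`, "", "tag") == "floor")]]
  n_c <- as.numeric(cam$R %*% fl$normal)
  d_c <- fl$offset - sum(fl$normal * cam$position)
  corners <- cbind(b[c("xmin", "xmax", "xmax", "xmin")],
                   b[c("ymin", "ymin", "ymax", "ymax")])
  corner_img <- project_cam(pen_to_cam(cbind(corners, 0), cam), cam)
  err <- sqrt(rowSums((apply_homography(H, corner_img) - corners)^2))
  if (max(err) > 0.01)
    stop_invalid("calibration error: corner reprojection error exceeds 1 cm")
  structure(list(matrix = H, camera = cam,
                 floor_normal_cam = n_c, floor_offset_cam = d_c,
                 pen_bounds = b, corner_error_m = max(err)),
            class = "ks_homography")
}

#' Project barycentres onto the pen floor as a trajectory
#'
#' Each camera-frame barycentre is dropped orthogonally onto the floor plane,
#' projected into the image and mapped through the ground homography, giving
#' the bird's-eye (x, y) position in metres. Positions outside the pen bounds
#' are clamped to the bounds and flagged, so trajectories stay gap-free for
#' downstream alignment.
#'
#' @param barycentres n x 3 matrix of camera-frame barycentres (metres), or a
#'   list of length-3 points (`NULL` entries, from undetected frames, are
#'   carried through as `NA` rows).
#' @param H A [fit_ground_homography()] result.
#' @param fps Frames per second (> 0).
#' @return A data frame of class `ks_trajectory` with columns `t`, `x`, `y`,
#'   `clamped`; attributes `fps` and `pen_bounds`.
#' @export
project_trajectory <- function(barycentres, H, fps) {
  stopifnot(fps > 0)
  if (is.list(barycentres) && !is.matrix(barycentres)) {
    barycentres <- do.call(rbind, lapply(barycentres, function(p)
      if (is.null(p)) c(NA_real_, NA_real_, NA_real_) else as.numeric(p)))
  }
  if (is.null(barycentres) || length(barycentres) == 0)
    return(new_trajectory(data.frame(t = numeric(), x = numeric(),
                                     y = numeric(), clamped = logical()),
                          fps, H$pen_bounds))
  barycentres <- rbind(barycentres)
  n <- nrow(barycentres)
  drop_d <- barycentres %*% H$floor_normal_cam - H$floor_offset_cam
  ground <- barycentres - drop_d %*% rbind(H$floor_normal_cam)
  img <- project_cam(ground, H$camera)
  xy <- apply_homography(H$matrix, img)
  b <- H$pen_bounds
  cx <- pmin(pmax(xy[, 1], b["xmin"]), b["xmax"])
  cy <- pmin(pmax(xy[, 2], b["ymin"]), b["ymax"])
  clamped <- (abs(cx - xy[, 1]) > 1e-12) | (abs(cy - xy[, 2]) > 1e-12)
  new_trajectory(data.frame(t = (seq_len(n) - 1) / fps, x = cx, y = cy,
                            clamped = clamped & !is.na(xy[, 1])),
                 fps, b)
}

new_trajectory <- function(df, fps, pen_bounds) {
  structure(df, fps = fps, pen_bounds = pen_bounds,
            class = c("ks_trajectory", "data.frame"))
}

#' Build a trajectory directly from ground coordinates
#'
#' Convenience constructor used by the synthetic generator and by tests when
#' ground-truth floor positions are already known.
#'
#' @param x,y Ground coordinates, metres.
#' @param fps Frames per second.
#' @param pen_bounds Named bounds vector as in [scene_model()].
#' @export
trajectory_from_xy <- function(x, y, fps,
                               pen_bounds = c(xmin = 0, xmax = 3,
                                              ymin = 0, ymax = 3)) {
  stopifnot(length(x) == length(y), fps > 0)
  new_trajectory(data.frame(t = (seq_along(x) - 1) / fps, x = x, y = y,
                            clamped = FALSE), fps, pen_bounds)
}

#' Write / read a scene description file
#'
#' Human-editable JSON holding the pen size, wall height and camera model.
#'
#' @param scene A [scene_model()].
#' @param path File path.
#' @export
write_scene <- function(scene, path) {
  cam <- scene$camera
  jsonlite::write_json(list(
    pen_size = unname(c(scene$pen_bounds["xmax"], scene$pen_bounds["ymax"])),
    wall_height = scene$wall_height,
    camera = list(width = cam$width, height = cam$height,
                  fx = cam$fx, fy = cam$fy, cx = cam$cx, cy = cam$cy,
                  R = cam$R, position = cam$position)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cam <- camera_model(width = j$camera$width, height = j$camera$height)
  cam$fx <- j$camera$fx; cam$fy <- j$camera$fy
  cam$cx <- j$camera$cx; cam$cy <- j$camera$cy
  cam$R <- matrix(unlist(j$camera$R), 3, 3)
  cam$position <- as.numeric(j$camera$position)
  scene_model(pen_size = as.numeric(j$pen_size), camera = cam,
              wall_height = j$wall_height)
}
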