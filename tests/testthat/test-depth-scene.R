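# Scene geometry, segmentation, homography and trajectory projection.

test_that("plane fitting and point-plane distances behave", {
  pl <- plane_from_points(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(abs(pl$normal), c(0, 0, 1))
  expect_equal(pl$offset, 0)
  expect_error(plane_from_points(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               "collinear")
  d <- kennelscope:::point_plane_distance(rbind(c(0, 0, 2), c(1, 1, -3)), pl)
  expect_equal(d, c(2, 3))
})

test_that("empty pen gives no detection and a rendered animal is recovered", {
  sc <- ks_test_scene()
  bg <- kennelscope:::render_background(sc)
  empty <- bg
  empty[!is.finite(empty)] <- 0
  expect_null(segment_frame(empty * 1000, sc))

  clip <- ks_stand_clip()
  blob <- segment_frame(clip$frames[[1]], sc, min_pixels = 100)
  expect_s3_class(blob, "ks_blob")
  gt <- clip$masks[[1]]
  iou <- sum(blob$mask & gt) / sum(blob$mask | gt)
  expect_gte(iou, 0.9)
  # noiseless render: tighter mask agreement
  quiet <- render_sequence(quadruped_model(),
    motion_script(script_step(0.1, "stand",
                              list(type = "stay", at = c(1.5, 1.8),
                                   heading = 0.4))),
    sc, fps = 10, noise_sd_mm = 0, seed = 3)
  b2 <- segment_frame(quiet$frames[[1]], sc, min_pixels = 100)
  iou2 <- sum(b2$mask & quiet$masks[[1]]) / sum(b2$mask | quiet$masks[[1]])
  expect_gte(iou2, 0.95)
})

test_that("segmentation is idempotent and respects the plane threshold", {
  sc <- ks_test_scene()
  clip <- ks_stand_clip()
  b1 <- segment_frame(clip$frames[[2]], sc, min_pixels = 100)
  b2 <- segment_frame(clip$frames[[2]], sc, min_pixels = 100)
  expect_identical(b1$mask, b2$mask)
  # every retained 3D point is farther than the threshold from every plane
  for (pl in sc$planes) {
    expect_gt(min(kennelscope:::point_plane_distance(b1$points_pen, pl)), 0.05)
  }
  expect_error(segment_frame(matrix(1000, 5, 5), sc), "configuration error")
})

test_that("barycentre is the arithmetic mean and errors on empty input", {
  expect_equal(compute_barycentre(rbind(c(0, 0, 1), c(2, 0, 1))), c(1, 0, 1))
  expect_equal(compute_barycentre(rbind(c(0.3, -0.2, 4))), c(0.3, -0.2, 4))
  expect_error(compute_barycentre(matrix(numeric(0), 0, 3)), "empty blob")
})

test_that("ground homography matches the analytic camera model", {
  sc <- ks_test_scene()
  H <- fit_ground_homography(sc)
  cam <- sc$camera
  # grid of floor points not used in the fit
  gx <- seq(0.31, 2.71, by = 0.4)
  pts <- as.matrix(expand.grid(x = gx, y = gx))
  img <- kennelscope:::project_cam(kennelscope:::pen_to_cam(cbind(pts, 0), cam), cam)
  back <- kennelscope:::apply_homography(H$matrix, img)
  expect_lt(max(sqrt(rowSums((back - pts)^2))), 0.01)
  # composed with its inverse: identity on the pen corners
  corners <- rbind(c(0, 0), c(3, 0), c(3, 3), c(0, 3))
  ci <- kennelscope:::apply_homography(solve(H$matrix), corners)
  cc <- kennelscope:::apply_homography(H$matrix, ci)
  expect_lt(max(abs(cc - corners)), 1e-6)
})

test_that("degenerate homography correspondences raise a calibration error", {
  src <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 0))   # one duplicated
  dst <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
  expect_error(fit_homography_points(src, dst), "calibration error|distinct")
})

test_that("trajectory projection recovers scripted ground motion", {
  sc <- ks_test_scene()
  H <- fit_ground_homography(sc)
  # stationary: all projected samples near one point
  clip <- ks_stand_clip()
  bl <- lapply(1:10, function(i)
    segment_frame(clip$frames[[i]], sc, min_pixels = 100)$barycentre)
  tr <- project_trajectory(do.call(rbind, bl), H, 10)
  expect_lt(max(dist(cbind(tr$x, tr$y))), 0.02)
  # scripted 2 m straight walk, ground-truth body centres projected:
  # endpoint separation 2 m +- 2 cm
  walk <- render_sequence(quadruped_model(),
    motion_script(script_step(5, "locomotion",
                              list(type = "line", from = c(0.5, 2.0),
                                   to = c(2.5, 2.0), speed = 0.5))),
    sc, fps = 10, noise_sd_mm = 0, seed = 2)
  centres <- kennelscope:::pen_to_cam(
    cbind(walk$trajectory$x, walk$trajectory$y, 0.45), sc$camera)
  trw <- project_trajectory(centres, H, 10)
  n <- nrow(trw)
  d <- sqrt((trw$x[n] - trw$x[1])^2 + (trw$y[n] - trw$y[1])^2)
  expect_lt(abs(d - 2), 0.02)
  # end-to-end via segmentation: the visible-surface barycentre carries a
  # small view-dependent parallax bias (documented limitation)
  bw <- lapply(walk$frames, function(f)
    segment_frame(f, sc, min_pixels = 100)$barycentre)
  tre <- project_trajectory(do.call(rbind, bw), H, 10)
  de <- sqrt((tre$x[n] - tre$x[1])^2 + (tre$y[n] - tre$y[1])^2)
  expect_lt(abs(de - 2), 0.06)
  # empty input
  expect_equal(nrow(project_trajectory(list(), H, 10)), 0)
})

test_that("depth video container round-trips through the TIFF adapter", {
  clip <- ks_stand_clip()
  dir <- withr::local_tempdir()
  write_depth_video(clip$frames[1:3], dir, fps = 10,
                    camera = clip$scene$camera)
  v <- read_depth_video(dir)
  expect_length(v$frames, 3)
  expect_equal(v$fps, 10)
  expect_equal(v$frames[[2]]$depth, clip$frames[[2]], ignore_attr = TRUE)
  expect_equal(v$camera$fx, clip$scene$camera$fx)
})

test_that("scene files round-trip", {
  sc <- ks_test_scene()
  f <- withr::local_tempfile(fileext = ".json")
  write_scene(sc, f)
  sc2 <- read_scene(f)
  expect_equal(sc2$pen_bounds, sc$pen_bounds)
  expect_equal(sc2$camera$R, sc$camera$R, tolerance = 1e-12)
  expect_equal(sum(vapply(sc2$planes, function(p) p$tag == "floor", TRUE)), 1)
})
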