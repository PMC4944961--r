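# Synthetic articulated quadruped: scripted postures and motion rendered
# into depth frames (z-buffered capsule primitives over the pen planes),
# with ground-truth skeletons, posture labels and trajectories. Emulates a
# single animal in a 3 x 3 m pen viewed by a side-mounted depth sensor at
# 1.5 m height, 10 frames per second.

#' Quadruped body model
#'
#' Segment lengths and posture template heights, metres. Defaults describe a
#' medium dog; proportions can be randomised (within anatomical plausibility)
#' to emulate animals of different shape and size.
#'
#' @param torso_length,torso_height Torso segment length and standing
#'   shoulder height.
#' @param head_length,tail_length,leg_length Remaining segment lengths
#'   (head and tail differ so front and back are distinguishable).
#' @param half_width Lateral half-spacing of the leg pairs.
#' @param radii Capsule radii per part group used by the renderer.
#' @export
quadruped_model <- function(torso_length = 0.6, torso_height = 0.45,
                            head_length = 0.28, tail_length = 0.22,
                            leg_length = 0.42, half_width = 0.08,
                            radii = c(torso = 0.09, head = 0.05,
                                      tail = 0.025, leg = 0.03)) {
  stopifnot(torso_length > 0, torso_height > 0, head_length > 0,
            tail_length > 0, leg_length > 0)
  structure(list(torso_length = torso_length, torso_height = torso_height,
                 head_length = head_length, tail_length = tail_length,
                 leg_length = leg_length, half_width = half_width,
                 radii = radii),
            class = "ks_quadruped")
}

#' Pose the quadruped skeleton in the pen
#'
#' Returns the seven posed segments in pen coordinates for a posture
#' template. `sit` raises the front and drops the rear (rear legs folded,
#' zero-length); `lie` puts the torso near the floor with all legs folded;
#' `locomotion` uses the stand template with a leg-swing phase. `lambda`
#' interpolates continuously from canonical sit (0) to canonical lie (1)
#' for ambiguous-posture fixtures.
#'
#' @param model A [quadruped_model()].
#' @param posture `stand`, `locomotion`, `sit` or `lie`.
#' @param x,y Ground position of the body centre, metres.
#' @param heading Direction of travel/facing, radians in the floor plane.
#' @param phase Gait phase (radians), used by `locomotion`.
#' @param lambda Sit-to-lie interpolation parameter in [0, 1] (only used
#'   when `posture` is `sit` or `lie`; the label is the nearest template).
#' @return A [skeleton()] with 3D pen-frame segments.
#' @export
pose_skeleton <- function(model, posture, x, y, heading = 0, phase = 0,
                          lambda = NULL) {
  if (!is.null(lambda)) {
    s1 <- pose_skeleton(model, "sit", x, y, heading)
    s2 <- pose_skeleton(model, "lie", x, y, heading)
    segs <- lapply(PART_NAMES, function(p)
      (1 - lambda) * s1$segments[[p]] + lambda * s2$segments[[p]])
    names(segs) <- PART_NAMES
    return(skeleton(segs, if (lambda < 0.5) "sit" else "lie"))
  }
  u <- c(cos(heading), sin(heading), 0)
  lat <- c(-sin(heading), cos(heading), 0)
  up <- c(0, 0, 1)
  L <- model$torso_length
  segs <- list()
  zero_seg <- function(a) rbind(a, a)
  if (posture %in% c("stand", "locomotion")) {
    h <- model$torso_height
    mid <- c(x, y, h)
    front <- mid + u * L / 2; back <- mid - u * L / 2
    segs$torso <- rbind(back, front)
    segs$head <- rbind(front, front + (u * cos(0.7) + up * sin(0.7)) *
                         model$head_length)
    segs$tail <- rbind(back, back + (-u * cos(0.6) - up * sin(0.6)) *
                         model$tail_length)
    swing <- if (posture == "locomotion") 0.08 * sin(phase) else 0
    foot_z <- max(0, h - model$leg_length)
    af <- mid + u * L * 0.35; ab <- mid - u * L * 0.35
    segs$leg_fl <- rbind(af + lat * model$half_width,
                         c(af[1:2] + lat[1:2] * model$half_width +
                             u[1:2] * swing, foot_z))
    segs$leg_fr <- rbind(af - lat * model$half_width,
                         c(af[1:2] - lat[1:2] * model$half_width -
                             u[1:2] * swing, foot_z))
    segs$leg_bl <- rbind(ab + lat * model$half_width,
                         c(ab[1:2] + lat[1:2] * model$half_width -
                             u[1:2] * swing, foot_z))
    segs$leg_br <- rbind(ab - lat * model$half_width,
                         c(ab[1:2] - lat[1:2] * model$half_width +
                             u[1:2] * swing, foot_z))
  } else if (posture == "sit") {
    # rump on the floor, shoulders nearly at standing height
    z_front <- model$torso_height * 0.93
    z_back <- model$radii[["torso"]] * 1.3
    horiz <- sqrt(max(L^2 - (z_front - z_back)^2, 0.01)) / 2
    front <- c(x + u[1] * horiz, y + u[2] * horiz, z_front)
    back <- c(x - u[1] * horiz, y - u[2] * horiz, z_back)
    segs$torso <- rbind(back, front)
    segs$head <- rbind(front, front + (u * cos(1.1) + up * sin(1.1)) *
                         model$head_length)
    segs$tail <- rbind(back, back + (-u * cos(0.2) - up * sin(0.2)) *
                         model$tail_length)
    af <- back + 0.75 * (front - back)
    segs$leg_fl <- rbind(af + lat * model$half_width,
                         c(af[1:2] + lat[1:2] * model$half_width, 0))
    segs$leg_fr <- rbind(af - lat * model$half_width,
                         c(af[1:2] - lat[1:2] * model$half_width, 0))
    segs$leg_bl <- zero_seg(back + lat * model$half_width)
    segs$leg_br <- zero_seg(back - lat * model$half_width)
  } else if (posture == "lie") {
    h <- model$radii["torso"] * 1.4
    mid <- c(x, y, h)
    front <- mid + u * L / 2; back <- mid - u * L / 2
    segs$torso <- rbind(back, front)
    segs$head <- rbind(front, front + (u * cos(0.25) + up * sin(0.25)) *
                         model$head_length)
    segs$tail <- rbind(back, back - u * model$tail_length)
    segs$leg_fl <- zero_seg(front + lat * model$half_width)
    segs$leg_fr <- zero_seg(front - lat * model$half_width)
    segs$leg_bl <- zero_seg(back + lat * model$half_width)
    segs$leg_br <- zero_seg(back - lat * model$half_width)
  } else stop_invalid("unknown posture: ", posture)
  segs <- lapply(segs, function(s) { dimnames(s) <- NULL; s })
  skeleton(segs[PART_NAMES], posture)
}

# ---- motion scripts -------------------------------------------------------

#' Build a motion script
#'
#' An ordered list of steps, each holding a duration (s), a posture and a
#' path primitive. Primitives: `stay(at, heading)`, `line(from, to)`,
#' `circle(center, radius, speed, start_angle, ccw)`, `perimeter(margin,
#' speed, start_s)` (an inset rectangle walked counter-clockwise),
#' `pace(from, to, speed)` (back-and-forth along a line).
#'
#' @param ... Steps created with [script_step()].
#' @export
motion_script <- function(...) {
  steps <- list(...)
  stopifnot(length(steps) > 0)
  structure(steps, class = "ks_motion_script")
}

#' @rdname motion_script
#' @param duration Step duration, seconds (> 0).
#' @param posture Posture held during the step.
#' @param path Path primitive: a `list(type = ..., ...)`; see
#'   [motion_script()].
#' @export
script_step <- function(duration, posture, path) {
  stopifnot(duration > 0)
  list(duration = duration, posture = posture, path = path)
}

# Position and heading at time t (within a step).
eval_path <- function(path, t) {
  switch(path$type,
    stay = list(x = path$at[1], y = path$at[2],
                heading = path$heading %||% 0),
    line = {
      d <- path$to - path$from
      len <- vnorm(d)
      sp <- path$speed %||% (len / path$duration)
      s <- min(t * sp, len)
      p <- path$from + if (len > 0) d / len * s else c(0, 0)
      list(x = p[1], y = p[2],
           heading = if (len > 0) atan2(d[2], d[1]) else 0)
    },
    circle = {
      w <- (path$speed / path$radius) * (if (isTRUE(path$ccw)) 1 else -1)
      a <- (path$start_angle %||% 0) + w * t
      list(x = path$center[1] + path$radius * cos(a),
           y = path$center[2] + path$radius * sin(a),
           heading = a + (if (isTRUE(path$ccw)) 1 else -1) * pi / 2)
    },
    perimeter = {
      m <- path$margin; b <- path$bounds
      w <- b[2] - 2 * m; h <- b[4] - 2 * m   # bounds = c(xmin,xmax,ymin,ymax)
      per <- 2 * (w + h)
      s <- ((path$start_s %||% 0) + path$speed * t) %% per
      if (s < w) list(x = m + s, y = m, heading = 0)
      else if (s < w + h) list(x = m + w, y = m + (s - w), heading = pi / 2)
      else if (s < 2 * w + h) list(x = m + w - (s - w - h), y = m + h,
                                   heading = pi)
      else list(x = m, y = m + h - (s - 2 * w - h), heading = -pi / 2)
    },
    pace = {
      d <- path$to - path$from
      len <- vnorm(d)
      s <- (path$speed * t) %% (2 * len)
      fwd <- s <= len
      p <- path$from + d / len * (if (fwd) s else 2 * len - s)
      list(x = p[1], y = p[2],
           heading = atan2(d[2], d[1]) + (if (fwd) 0 else pi))
    },
    stop_invalid("unknown path primitive: ", path$type))
}

# ---- depth rendering ------------------------------------------------------

# Static background: depth (m) of the nearest solid surface along each
# pixel ray; 0 where no surface is hit. Cached per scene in the dataset.
render_background <- function(scene) {
  cam <- scene$camera
  W <- cam$width; H <- cam$height
  u <- matrix(rep(0:(W - 1), each = H), H, W)
  v <- matrix(rep(0:(H - 1), times = W), H, W)
  # ray directions in pen frame, camera-frame z component = 1
  dx <- (u - cam$cx) / cam$fx
  dy <- (v - cam$cy) / cam$fy
  Rt <- t(cam$R)
  rx <- Rt[1, 1] * dx + Rt[1, 2] * dy + Rt[1, 3]
  ry <- Rt[2, 1] * dx + Rt[2, 2] * dy + Rt[2, 3]
  rz <- Rt[3, 1] * dx + Rt[3, 2] * dy + Rt[3, 3]
  C <- cam$position
  b <- scene$pen_bounds
  Z <- matrix(Inf, H, W)
  tol <- 1e-9
  for (pl in scene$planes) {
    if (pl$tag == "fence") next  # see-through wire mesh
    n <- pl$normal
    denom <- n[1] * rx + n[2] * ry + n[3] * rz
    tt <- (pl$offset - sum(n * C)) / denom
    px <- C[1] + tt * rx; py <- C[2] + tt * ry; pz <- C[3] + tt * rz
    ok <- is.finite(tt) & tt > 0.05 &
      px >= b["xmin"] - tol & px <= b["xmax"] + tol &
      py >= b["ymin"] - tol & py <= b["ymax"] + tol &
      pz >= -tol & pz <= scene$wall_height + tol
    Z[ok & tt < Z] <- tt[ok & tt < Z]
  }
  Z
}

# Splat one skeleton into a copy of the background z-buffer; returns the
# depth map (m) and the exact foreground mask.
render_skeleton_depth <- function(scene, skel, model, background) {
  cam <- scene$camera
  Z <- background
  M <- matrix(FALSE, nrow(Z), ncol(Z))
  radii <- model$radii
  part_radius <- function(p) {
    if (p == "torso") radii["torso"]
    else if (p == "head") radii["head"]
    else if (p == "tail") radii["tail"]
    else radii["leg"]
  }
  for (p in names(skel$segments)) {
    seg <- skel$segments[[p]]
    r <- part_radius(p)
    len <- vnorm(seg[2, ] - seg[1, ])
    if (len < 1e-9) next
    ns <- max(2L, ceiling(len / (r / 2)))
    fr <- seq(0, 1, length.out = ns)
    for (f in fr) {
      cpen <- seg[1, ] + f * (seg[2, ] - seg[1, ])
      cc <- as.numeric(cam$R %*% (cpen - cam$position))
      if (cc[3] < 0.15) next
      uc <- cam$fx * cc[1] / cc[3] + cam$cx
      vc <- cam$fy * cc[2] / cc[3] + cam$cy
      pr <- ceiling(r * cam$fx / cc[3]) + 1
      c0 <- max(1, floor(uc) - pr + 1); c1 <- min(ncol(Z), ceiling(uc) + pr + 1)
      r0 <- max(1, floor(vc) - pr + 1); r1 <- min(nrow(Z), ceiling(vc) + pr + 1)
      if (c0 > c1 || r0 > r1) next
      uu <- ((c0:c1) - 1 - cam$cx) / cam$fx * cc[3]
      vv <- ((r0:r1) - 1 - cam$cy) / cam$fy * cc[3]
      ox <- outer(rep(1, length(vv)), uu - cc[1])
      oy <- outer(vv - cc[2], rep(1, length(uu)))
      d2 <- ox^2 + oy^2
      inside <- d2 <= r^2
      if (!any(inside)) next
      zs <- cc[3] - sqrt(pmax(r^2 - d2, 0))
      sub <- Z[r0:r1, c0:c1]
      upd <- inside & zs < sub
      sub[upd] <- zs[upd]
      Z[r0:r1, c0:c1] <- sub
      Msub <- M[r0:r1, c0:c1]
      Msub[upd] <- TRUE
      M[r0:r1, c0:c1] <- Msub
    }
  }
  list(depth = Z, mask = M)
}

#' Render an annotated depth-video dataset
#'
#' Plays a [motion_script()] with a [quadruped_model()] inside the scene and
#' renders every frame: pen planes plus the posed animal, z-buffered capsule
#' primitives, optional additive Gaussian depth noise. Deterministic given
#' the seed. The path is validated to stay inside the pen.
#'
#' @param model A [quadruped_model()].
#' @param script A [motion_script()].
#' @param scene A [scene_model()].
#' @param fps Frames per second (default 10).
#' @param noise_sd_mm Depth noise standard deviation in mm (default 5; 0
#'   for noiseless frames).
#' @param seed RNG seed for the noise.
#' @return Object of class `ks_annotated_dataset`: `frames` (depth matrices,
#'   mm), `masks` (exact foreground masks), `skeletons` (pen-frame GT),
#'   `postures`, `trajectory` (`ks_trajectory` of GT body-centre positions),
#'   `scene`, `model`, `fps`, `seed`.
#' @export
render_sequence <- function(model, script, scene = scene_model(), fps = 10,
                            noise_sd_mm = 5, seed = 1) {
  stopifnot(fps > 0)
  b <- scene$pen_bounds
  background <- render_background(scene)
  frames <- list(); masks <- list(); skels <- list()
  postures <- character(0); xs <- numeric(0); ys <- numeric(0)
  t0 <- 0
  with_seed(seed, {
    for (st in script) {
      if (st$path$type == "perimeter") st$path$bounds <- unname(b)
      if (st$path$type == "line") st$path$duration <- st$duration
      nfr <- max(1L, round(st$duration * fps))
      for (i in seq_len(nfr)) {
        tt <- (i - 1) / fps
        pos <- eval_path(st$path, tt)
        margin <- 0.15
        if (pos$x < b["xmin"] + margin || pos$x > b["xmax"] - margin ||
            pos$y < b["ymin"] + margin || pos$y > b["ymax"] - margin)
          stop_invalid("script error: path exits the pen at t=", t0 + tt)
        sk <- pose_skeleton(model, st$posture, pos$x, pos$y, pos$heading,
                            phase = 2 * pi * 2 * (t0 + tt))
        rend <- render_skeleton_depth(scene, sk, model, background)
        d <- rend$depth
        d[!is.finite(d)] <- 0
        dmm <- d * 1000
        if (noise_sd_mm > 0) {
          nz <- dmm > 0
          dmm[nz] <- pmax(1, dmm[nz] + rnorm(sum(nz), 0, noise_sd_mm))
        }
        frames[[length(frames) + 1]] <- round(dmm)
        masks[[length(masks) + 1]] <- rend$mask
        skels[[length(skels) + 1]] <- sk
        postures <- c(postures, st$posture)
        xs <- c(xs, pos$x); ys <- c(ys, pos$y)
      }
      t0 <- t0 + nfr / fps
    }
  })
  structure(list(frames = frames, masks = masks, skeletons = skels,
                 postures = postures,
                 trajectory = trajectory_from_xy(xs, ys, fps, b),
                 scene = scene, model = model, fps = fps, seed = seed),
            class = "ks_annotated_dataset")
}

#' Trajectory windows with planted motion patterns
#'
#' Generates fixed-length ground-trajectory windows drawn from four scripted
#' pen-movement patterns — circling along the pen perimeter, circling in the
#' front half of the pen, pacing along one side, and standing in one corner —
#' with optional positional jitter, plus the planted pattern labels for
#' recovery tests. Instances of a pattern are phase-shifted copies of its
#' path.
#'
#' @param n_per_pattern Window counts, in the order perimeter, half-pen
#'   circle, side pacing, corner standing (default `c(3, 2, 3, 2)`).
#' @param window_s Window length in seconds (default 5).
#' @param fps Frames per second (default 10).
#' @param jitter Positional jitter standard deviation, metres (0 = none).
#' @param seed RNG seed.
#' @param pen_bounds Pen bounds.
#' @return `list(windows, labels)`.
#' @export
planted_pattern_windows <- function(n_per_pattern = c(3, 2, 3, 2),
                                    window_s = 5, fps = 10, jitter = 0,
                                    seed = 1,
                                    pen_bounds = c(xmin = 0, xmax = 3,
                                                   ymin = 0, ymax = 3)) {
  stopifnot(all(n_per_pattern >= 1), length(n_per_pattern) == 4)
  wlen <- round(window_s * fps)
  paths <- list(
    perimeter = function(phase) list(type = "perimeter", margin = 0.4,
                                     speed = 0.6, start_s = phase,
                                     bounds = unname(pen_bounds)),
    half_circle = function(phase) list(type = "circle",
                                       center = c(1.5, 0.95), radius = 0.55,
                                       speed = 0.5, start_angle = phase,
                                       ccw = TRUE),
    side_pace = function(phase) list(type = "pace", from = c(0.4, 0.5),
                                     to = c(0.4, 2.5), speed = 0.5),
    corner_stand = function(phase) list(type = "stay", at = c(2.6, 2.6)))
  labels <- rep(names(paths), times = n_per_pattern)
  windows <- with_seed(seed, {
    lapply(seq_along(labels), function(i) {
      pat <- labels[i]
      inst <- sum(labels[seq_len(i)] == pat) - 1     # 0-based within pattern
      phase <- inst * 0.25
      path <- paths[[pat]](phase)
      tt <- (seq_len(wlen) - 1) / fps +
        (if (pat %in% c("side_pace")) inst * 0.5 else 0)
      xy <- t(vapply(tt, function(t) {
        p <- eval_path(path, t)
        c(p$x, p$y)
      }, numeric(2)))
      if (jitter > 0) {
        xy <- xy + matrix(rnorm(length(xy), 0, jitter), ncol = 2)
        xy[, 1] <- pmin(pmax(xy[, 1], pen_bounds["xmin"]), pen_bounds["xmax"])
        xy[, 2] <- pmin(pmax(xy[, 2], pen_bounds["ymin"]), pen_bounds["ymax"])
      }
      sequence_window(xy, id = i, start = 0, end = window_s,
                      feature = "trajectory")
    })
  })
  list(windows = windows, labels = labels)
}

#' Ambiguous sit/lie posture fixtures
#'
#' Renders frames whose joint configuration interpolates between the
#' canonical sit and lie templates (lower body on the ground, head and torso
#' progressively higher), labelled by the nearest template. Used to probe
#' the sit/lie confusion structure of the posture classifiers.
#'
#' @param n Number of frames (>= 1); interpolation parameters are spread
#'   over [0, 1].
#' @param seed RNG seed (position/heading jitter and depth noise).
#' @param model,scene,fps,noise_sd_mm As in [render_sequence()].
#' @return An `ks_annotated_dataset` with attribute `lambda`.
#' @export
ambiguous_posture_frames <- function(n, seed = 1, model = quadruped_model(),
                                     scene = scene_model(), fps = 10,
                                     noise_sd_mm = 5) {
  stopifnot(n >= 1)
  lambdas <- if (n == 1) 0.5 else seq(0, 1, length.out = n)
  background <- render_background(scene)
  frames <- list(); masks <- list(); skels <- list()
  postures <- character(0); xs <- numeric(0); ys <- numeric(0)
  with_seed(seed, {
    pos_x <- runif(n, 1.0, 2.0)
    pos_y <- runif(n, 1.2, 2.4)
    headings <- runif(n, -pi, pi)
    for (i in seq_len(n)) {
      sk <- pose_skeleton(model, "sit", pos_x[i], pos_y[i], headings[i],
                          lambda = lambdas[i])
      rend <- render_skeleton_depth(scene, sk, model, background)
      d <- rend$depth
      d[!is.finite(d)] <- 0
      dmm <- d * 1000
      if (noise_sd_mm > 0) {
        nz <- dmm > 0
        dmm[nz] <- pmax(1, dmm[nz] + rnorm(sum(nz), 0, noise_sd_mm))
      }
      frames[[i]] <- round(dmm)
      masks[[i]] <- rend$mask
      skels[[i]] <- sk
      postures <- c(postures, sk$posture)
      xs <- c(xs, pos_x[i]); ys <- c(ys, pos_y[i])
    }
  })
  out <- structure(list(frames = frames, masks = masks, skeletons = skels,
                        postures = postures,
                        trajectory = trajectory_from_xy(xs, ys, fps,
                                                        scene$pen_bounds),
                        scene = scene, model = model, fps = fps, seed = seed),
                   class = "ks_annotated_dataset")
  attr(out, "lambda") <- lambdas
  out
}
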