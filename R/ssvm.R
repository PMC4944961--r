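# Structured max-margin body-part labelling.
#
# A frame's input x bundles the segmented blob, the depth image and the
# barycentre motion vector. The output y is a 16-value solution vector
# (7 parts x (angle, length) + motion). Candidates are enumerated on a
# quantised grid under posture-specific anatomical constraints (torso through
# the barycentre, legs below the torso, no legs when lying), scored by
# F(x, y) = w . phi(x, y), and the argmax is the fitted skeleton. Training is
# an online passive-aggressive approximation of max-margin structured
# learning with a margin scaled by the candidate's loss.

#' Candidate-grid configuration
#'
#' Discretisation of the anatomically constrained solution space. The
#' number of candidates for the stand class is the product
#' `n_torso_angles * n_torso_lengths * n_headtail_angles^2 *
#' n_leg_placements`.
#'
#' @param n_torso_angles Torso orientations spanning the full circle.
#' @param n_torso_lengths Torso lengths spanning `length_span` times the
#'   blob's in-plane extent.
#' @param n_headtail_angles Relative orientations for head (about the torso
#'   direction) and tail (about the backward direction), each.
#' @param n_leg_placements Joint leg poses (front/rear splay combinations)
#'   for the stand class; front-leg poses for the sit class.
#' @param head_ratio,tail_ratio,leg_ratio Segment lengths as fractions of
#'   the torso length (head and tail differ to break front/back symmetry).
#' @param length_span Torso length range as fractions of the blob extent.
#' @param n_samples Sample points per segment for the appearance features.
#' @export
candidate_config <- function(n_torso_angles = 24, n_torso_lengths = 5,
                             n_headtail_angles = 8, n_leg_placements = 6,
                             head_ratio = 0.45, tail_ratio = 0.35,
                             leg_ratio = 0.7, length_span = c(0.5, 1.1),
                             n_samples = 7) {
  structure(list(n_torso_angles = n_torso_angles,
                 n_torso_lengths = n_torso_lengths,
                 n_headtail_angles = n_headtail_angles,
                 n_leg_placements = n_leg_placements,
                 head_ratio = head_ratio, tail_ratio = tail_ratio,
                 leg_ratio = leg_ratio, length_span = length_span,
                 n_samples = n_samples),
            class = "ks_candidate_config")
}

#' Bundle the per-frame classifier input
#'
#' @param blob A `ks_blob` from [segment_frame()] (or `NULL` for
#'   no-detection).
#' @param motion Ground-plane barycentre displacement `c(dx, dy)` in
#'   metres/frame (zero for the first frame of a video).
#' @param camera The [camera_model()] (used to project candidate geometry
#'   into the image and to express the motion vector in the image plane).
#' @param depth Depth frame or matrix (mm) the blob came from.
#' @export
ssvm_input <- function(blob, motion, camera, depth) {
  depth_m <- frame_depth(depth) / 1000
  # height-above-floor map (pen z, metres) of the observed surface at every
  # valid pixel; appearance feature for the posture-sensitive blocks of phi
  height <- matrix(0, nrow(depth_m), ncol(depth_m))
  idx <- which(depth_m > 0)
  if (length(idx) > 0) {
    rows <- (idx - 1) %% nrow(depth_m)
    cols <- (idx - 1) %/% nrow(depth_m)
    pc <- backproject_cam(cols, rows, depth_m[idx], camera)
    height[idx] <- cam_to_pen(pc, camera)[, 3]
  }
  structure(list(blob = blob, motion = as.numeric(motion), camera = camera,
                 depth_m = depth_m, height = height,
                 z_bar = if (is.null(blob)) NA_real_ else blob$barycentre[3]),
            class = "ks_ssvm_input")
}

# Posture-specific torso orientation grid (image plane, y down). The
# bodyparts class spans the full circle; stand and lie constrain the torso
# near horizontal (two arcs, facing either way); sit raises the front: the
# torso direction points diagonally upward, facing either way.
torso_angle_grid <- function(posture_class, na) {
  if (posture_class == "bodyparts") return(-pi + seq_len(na) * 2 * pi / na)
  arcs <- if (posture_class == "sit") {
    list(c(-1.15, -0.45), c(-pi + 0.45, -pi + 1.15))
  } else {
    list(c(-0.35, 0.35), c(pi - 0.35, pi + 0.35))
  }
  k1 <- ceiling(na / 2); k2 <- na - k1
  wrap_angle(c(seq(arcs[[1]][1], arcs[[1]][2], length.out = k1),
               if (k2 > 0) seq(arcs[[2]][1], arcs[[2]][2], length.out = k2)))
}

leg_placements <- function(n) {
  # n joint (front splay, rear splay) combinations, radians from vertical
  front <- seq(-0.3, 0.3, length.out = n)
  rear <- -front / 2
  cbind(front = front, rear = rear)
}

#' Enumerate candidate solutions for a blob
#'
#' @param blob A `ks_blob`.
#' @param motion Motion vector `c(dx, dy)`, metres/frame.
#' @param posture_class `bodyparts` (same constraints as `stand`), `stand`,
#'   `sit` (front legs only, fixed length), or `lie` (legs omitted).
#' @param config A [candidate_config()].
#' @return Object of class `ks_candidates`: `values` (n x 16 matrix of
#'   solution vectors), `barycentre`, `posture_class`, `config`, `extent`.
#' @export
generate_candidates <- function(blob, motion = c(0, 0),
                                posture_class = "bodyparts",
                                config = candidate_config()) {
  if (is.null(blob) || nrow(blob$points) == 0)
    stop_invalid("invalid input: empty blob")
  posture_class <- match.arg(posture_class,
                             c("bodyparts", "stand", "sit", "lie"))
  pts <- blob$points[, 1:2, drop = FALSE]
  extent <- max(diff(range(pts[, 1])), diff(range(pts[, 2])), 0.1)
  na <- config$n_torso_angles; nl <- config$n_torso_lengths
  nh <- config$n_headtail_angles
  nlegs <- if (posture_class == "lie") 1L else config$n_leg_placements
  tang <- torso_angle_grid(posture_class, na)
  tlen <- seq(config$length_span[1], config$length_span[2],
              length.out = nl) * extent
  rel <- -pi + (seq_len(nh)) * 2 * pi / nh
  g <- expand.grid(ia = seq_len(na), il = seq_len(nl), ih = seq_len(nh),
                   it = seq_len(nh), ilg = seq_len(nlegs))
  thetat <- tang[g$ia]; Lt <- tlen[g$il]
  V <- matrix(0, nrow(g), 16)
  V[, 3] <- thetat; V[, 4] <- Lt
  V[, 1] <- wrap_angle(thetat + rel[g$ih]); V[, 2] <- config$head_ratio * Lt
  V[, 5] <- wrap_angle(thetat + pi + rel[g$it]); V[, 6] <- config$tail_ratio * Lt
  lp <- leg_placements(config$n_leg_placements)
  if (posture_class %in% c("bodyparts", "stand")) {
    V[, 7] <- V[, 9] <- pi / 2 + lp[g$ilg, "front"]
    V[, 11] <- V[, 13] <- pi / 2 + lp[g$ilg, "rear"]
    V[, 8] <- V[, 10] <- V[, 12] <- V[, 14] <- config$leg_ratio * Lt
  } else if (posture_class == "sit") {
    V[, 7] <- V[, 9] <- pi / 2 + lp[g$ilg, "front"]
    V[, 8] <- V[, 10] <- config$leg_ratio * Lt
    # rear legs folded: zero-length sentinel (columns stay 0)
  }
  V[, 15] <- motion[1]; V[, 16] <- motion[2]
  structure(list(values = V, barycentre = blob$barycentre,
                 posture_class = posture_class, config = config,
                 extent = extent),
            class = "ks_candidates")
}

# In-plane endpoint matrix (n x 28: 7 parts x (x1, y1, x2, y2)) for every
# candidate; same anchoring rules as decode_solution, fully vectorised.
candidate_endpoints <- function(values, barycentre) {
  V <- rbind(values)
  mid_x <- barycentre[1]; mid_y <- barycentre[2]
  tt <- V[, 3]; Lt <- V[, 4]
  ux <- cos(tt); uy <- sin(tt)
  fx <- mid_x + ux * Lt / 2; fy <- mid_y + uy * Lt / 2
  bx <- mid_x - ux * Lt / 2; by <- mid_y - uy * Lt / 2
  afx <- mid_x + ux * Lt / 4; afy <- mid_y + uy * Lt / 4
  abx <- mid_x - ux * Lt / 4; aby <- mid_y - uy * Lt / 4
  E <- matrix(0, nrow(V), 28)
  seg <- function(k, sx, sy, tx, ty) {
    E[, 4 * k - 3] <<- sx; E[, 4 * k - 2] <<- sy
    E[, 4 * k - 1] <<- tx; E[, 4 * k] <<- ty
  }
  seg(1, fx, fy, fx + cos(V[, 1]) * V[, 2], fy + sin(V[, 1]) * V[, 2])  # head
  seg(2, bx, by, fx, fy)                                                # torso
  seg(3, bx, by, bx + cos(V[, 5]) * V[, 6], by + sin(V[, 5]) * V[, 6])  # tail
  anchors <- list(cbind(afx, afy), cbind(afx, afy),
                  cbind(abx, aby), cbind(abx, aby))
  for (l in 1:4) {
    a <- anchors[[l]]
    th <- V[, 5 + 2 * l]; ln <- V[, 6 + 2 * l]
    seg(3 + l, a[, 1], a[, 2], a[, 1] + cos(th) * ln, a[, 2] + sin(th) * ln)
  }
  E
}

# Joint feature matrix for all candidates: per part, occupancy and relative
# depth at n_samples points along the segment (appearance block), then the
# motion block (dx, dy, torso/motion alignment, |alignment|).
phi_candidates <- function(x, candset) {
  V <- candset$values
  n <- nrow(V)
  P <- candset$config$n_samples
  cam <- x$camera
  z <- x$z_bar
  mask <- x$blob$mask
  depth <- x$depth_m
  nr <- nrow(mask); nc <- ncol(mask)
  E <- candidate_endpoints(V, candset$barycentre)
  fr <- seq(0, 1, length.out = P)
  Phi <- matrix(0, n, 4 * P * 7 + 2 * P + 4)
  hgt <- x$height
  for (k in 1:7) {
    sx <- E[, 4 * k - 3]; sy <- E[, 4 * k - 2]
    tx <- E[, 4 * k - 1]; ty <- E[, 4 * k]
    present <- V[, 2 * k] > 1e-9
    for (p in seq_len(P)) {
      X <- sx + fr[p] * (tx - sx)
      Y <- sy + fr[p] * (ty - sy)
      col <- round(cam$fx * X / z + cam$cx) + 1
      row <- round(cam$fy * Y / z + cam$cy) + 1
      inside <- row >= 1 & row <= nr & col >= 1 & col <= nc & present
      occ <- numeric(n); dep <- numeric(n)
      hlo <- numeric(n); hhi <- numeric(n)
      if (any(inside)) {
        idx <- (col[inside] - 1) * nr + row[inside]
        on <- mask[idx]
        occ[inside] <- as.numeric(on)
        dz <- (z - depth[idx]) / 0.3
        dep[inside] <- ifelse(on, pmin(1, pmax(-1, dz)), 0)
        # rectified height split: how far the observed surface sits below
        # (h_low) or above (h_high) mid-height; each posture's model earns
        # weight on its own band, which vanishes on wrong-class blobs
        hrel <- hgt[idx] / 0.6 - 0.5
        hlo[inside] <- ifelse(on, pmin(1, pmax(0, -hrel)), 0)
        hhi[inside] <- ifelse(on, pmin(1, pmax(0, hrel)), 0)
      }
      Phi[, (k - 1) * 4 * P + p] <- occ
      Phi[, (k - 1) * 4 * P + P + p] <- dep
      Phi[, (k - 1) * 4 * P + 2 * P + p] <- hlo
      Phi[, (k - 1) * 4 * P + 3 * P + p] <- hhi
    }
  }
  # torso flank block: occupancy at points offset perpendicular to the
  # torso, below (+) and above (-) in the image; a standing torso shows an
  # under-belly gap below, a sitting/lying one shows floor-contact mass
  off <- 0.3 * V[, 4]
  px <- -sin(V[, 3]) * off; py <- cos(V[, 3]) * off
  sx <- E[, 5]; sy <- E[, 6]; tx <- E[, 7]; ty <- E[, 8]
  for (p in seq_len(P)) {
    X0 <- sx + fr[p] * (tx - sx)
    Y0 <- sy + fr[p] * (ty - sy)
    for (side in 1:2) {
      sgn <- if (side == 1) 1 else -1
      col <- round(cam$fx * (X0 + sgn * px) / z + cam$cx) + 1
      row <- round(cam$fy * (Y0 + sgn * py) / z + cam$cy) + 1
      inside <- row >= 1 & row <= nr & col >= 1 & col <= nc
      occ <- numeric(n)
      if (any(inside)) {
        idx <- (col[inside] - 1) * nr + row[inside]
        occ[inside] <- as.numeric(mask[idx])
      }
      Phi[, 4 * P * 7 + (side - 1) * P + p] <- occ
    }
  }
  m0 <- 4 * P * 7 + 2 * P
  dx <- V[1, 15]; dy <- V[1, 16]
  speed <- sqrt(dx^2 + dy^2)
  Phi[, m0 + 1] <- dx
  Phi[, m0 + 2] <- dy
  if (speed > 1e-9) {
    m_cam <- as.numeric(cam$R %*% c(dx, dy, 0))
    phi_m <- atan2(m_cam[2], m_cam[1])
    align <- cos(V[, 3] - phi_m) * min(speed / 0.05, 1)
    Phi[, m0 + 3] <- align
    Phi[, m0 + 4] <- abs(align)
  }
  Phi
}

#' Joint feature map phi(x, y)
#'
#' Deterministic d-vector (d = 151 at the default 7 samples/segment)
#' concatenating, per part, blob-appearance statistics sampled along the
#' part's candidate geometry — mask occupancy, barycentre-relative depth and
#' height of the observed surface above the pen floor — plus the motion
#' components and a torso/motion alignment term. A frame with an
#' all-background blob yields an all-zero appearance block with the motion
#' block passed through.
#'
#' @param x An [ssvm_input()].
#' @param y Length-16 solution vector.
#' @param config A [candidate_config()] (controls `n_samples`).
#' @export
joint_feature_map <- function(x, y, config = candidate_config()) {
  candset <- structure(list(values = rbind(y), barycentre = x$blob$barycentre,
                            posture_class = "bodyparts", config = config),
                       class = "ks_candidates")
  as.numeric(phi_candidates(x, candset))
}

#' Compatibility score F(x, y) = w . phi(x, y)
#'
#' @param w Weight vector (or a trained `ks_ssvm_model`).
#' @param x An [ssvm_input()].
#' @param y Solution vector.
#' @export
ssvm_score <- function(w, x, y) {
  if (inherits(w, "ks_ssvm_model")) {
    cfg <- w$config; w <- w$w
  } else cfg <- candidate_config()
  phi <- joint_feature_map(x, y, cfg)
  if (length(w) != length(phi)) stop_invalid("invalid input: dimension mismatch")
  sum(w * phi)
}

# Compact descriptor of a fitted solution on a blob, used for the
# across-class posture decision: each posture model records the Gaussian
# statistics of this descriptor over its own training fits, and a test fit
# is scored by its class-conditional log-likelihood. Dimensions:
# torso inclination |sin(theta)|; barycentre height above the floor (m);
# fraction of blob points below 0.2 m; 95th percentile of blob height;
# fitted torso length relative to the blob extent; mean mask occupancy
# along the fitted legs.
fit_descriptor <- function(x, values, extent) {
  blob <- x$blob
  cam <- x$camera
  z <- x$z_bar
  zs <- blob$points_pen[, 3]
  E <- candidate_endpoints(rbind(values), blob$barycentre)[1, ]
  P <- 5
  legocc <- 0; nleg <- 0
  for (l in 4:7) {
    if (values[2 * l] < 1e-9) next
    fr <- seq(0, 1, length.out = P)
    X <- E[4 * l - 3] + fr * (E[4 * l - 1] - E[4 * l - 3])
    Y <- E[4 * l - 2] + fr * (E[4 * l] - E[4 * l - 2])
    col <- round(cam$fx * X / z + cam$cx) + 1
    row <- round(cam$fy * Y / z + cam$cy) + 1
    ok <- row >= 1 & row <= nrow(blob$mask) & col >= 1 & col <= ncol(blob$mask)
    occ <- numeric(P)
    occ[ok] <- as.numeric(blob$mask[cbind(row[ok], col[ok])])
    legocc <- legocc + mean(occ); nleg <- nleg + 1
  }
  c(incl = abs(sin(values[3])),
    zbar = blob$barycentre_pen[3],
    lowfrac = mean(zs < 0.2),
    zq95 = as.numeric(quantile(zs, 0.95)),
    rel_len = values[4] / extent,
    legocc = if (nleg > 0) legocc / nleg else 0)
}

# Robust class-typicality score: negative Mahalanobis-style penalty with a
# variance floor. The blob-shape dimensions (barycentre height, low-mass
# fraction, height extent: 2-4) count in full; the fit-dependent dimensions
# (inclination, relative length, leg occupancy: 1, 5, 6) are capped so a
# single implausible fit facet cannot dominate the across-class decision.
descriptor_loglik <- function(g, mu, sd) {
  sd <- pmax(sd, 0.03)
  z2 <- (((g - mu) / sd)^2) / 2
  z2[c(1, 5, 6)] <- pmin(z2[c(1, 5, 6)], 2)
  -sum(z2)
}

# Loss: mean in-plane endpoint distance to the ground truth, normalised by
# the GT torso length.
candidate_losses <- function(candset, y_gt) {
  E <- candidate_endpoints(candset$values, candset$barycentre)
  Eg <- candidate_endpoints(rbind(y_gt), candset$barycentre)[1, ]
  lt <- max(y_gt[4], 1e-6)
  acc <- matrix(0, nrow(E), 14)
  for (e in 1:14) {
    dx <- E[, 2 * e - 1] - Eg[2 * e - 1]
    dy <- E[, 2 * e] - Eg[2 * e]
    acc[, e] <- sqrt(dx^2 + dy^2)
  }
  rowMeans(acc) / lt
}

#' Train a structured classifier
#'
#' Online passive-aggressive approximation of max-margin structured
#' learning: per pair, the loss-augmented argmax over the candidate set is
#' found and the weights are moved so the (grid-snapped) ground truth
#' outscores it by a margin equal to its loss; the step is capped at `C`.
#' Pair order is shuffled with a fixed seed each epoch.
#'
#' @param pairs List of `list(x = ssvm_input, y = <16-vector or ks_skeleton>)`.
#' @param posture_class Candidate constraint class; see
#'   [generate_candidates()].
#' @param config A [candidate_config()].
#' @param epochs,C,seed Training hyperparameters.
#' @return Object of class `ks_ssvm_model`: `w`, `w_unit` (L2-normalised,
#'   used for across-class posture scoring), `posture_class`, `trained_on`,
#'   `config`, `epoch_loss`.
#' @export
train_ssvm <- function(pairs, posture_class = "bodyparts",
                       config = candidate_config(),
                       epochs = 3, C = 1, seed = 1) {
  if (length(pairs) == 0) stop_invalid("invalid input: no training pairs")
  prep <- lapply(pairs, function(pr) {
    y <- pr$y
    if (inherits(y, "ks_skeleton"))
      y <- encode_solution(y, pr$x$motion)
    cs <- generate_candidates(pr$x$blob, pr$x$motion, posture_class, config)
    Phi <- phi_candidates(pr$x, cs)
    losses <- candidate_losses(cs, y)
    gt <- which.min(losses)
    list(Phi = Phi, losses = losses - losses[gt], gt = gt)
  })
  d <- ncol(prep[[1]]$Phi)
  w <- numeric(d)
  wsum <- numeric(d)   # running sum for weight averaging
  nvisit <- 0
  epoch_loss <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(prep))
      hinge <- 0
      for (i in ord) {
        pp <- prep[[i]]
        s <- pp$Phi %*% w
        aug <- s + pp$losses
        yhat <- which.max(aug)
        viol <- aug[yhat] - s[pp$gt]
        if (yhat != pp$gt && viol > 1e-12) {
          dphi <- pp$Phi[pp$gt, ] - pp$Phi[yhat, ]
          nrm2 <- sum(dphi^2)
          if (nrm2 > 1e-12) {
            tau <- min(C, viol / nrm2)
            w <- w + tau * dphi
          }
        }
        hinge <- hinge + max(0, viol)
        wsum <- wsum + w
        nvisit <- nvisit + 1
      }
      epoch_loss[ep] <- hinge / length(prep)
    }
  })
  # averaged weights: the mean iterate generalises more stably than the
  # last one under online updates
  w <- wsum / max(nvisit, 1)
  nw <- sqrt(sum(w^2))
  # self-score calibration (typical ground-truth score on the training
  # frames) and the class-conditional fit-descriptor statistics used by
  # classify_posture for the across-class decision.
  self_score <- mean(vapply(prep, function(pp) sum(pp$Phi[pp$gt, ] * w),
                            numeric(1)))
  G <- t(vapply(seq_along(pairs), function(i) {
    pp <- prep[[i]]
    cs <- generate_candidates(pairs[[i]]$x$blob, pairs[[i]]$x$motion,
                              posture_class, config)
    ihat <- which.max(as.numeric(pp$Phi %*% w))
    fit_descriptor(pairs[[i]]$x, cs$values[ihat, ], cs$extent)
  }, numeric(6)))
  structure(list(w = w, w_unit = if (nw > 0) w / nw else w,
                 self_score = self_score,
                 g_mu = colMeans(G), g_sd = apply(G, 2, sd),
                 posture_class = posture_class, trained_on = length(pairs),
                 config = config, epochs = epochs, C = C, seed = seed,
                 epoch_loss = epoch_loss),
            class = "ks_ssvm_model")
}

#' Infer the body-part skeleton for a frame
#'
#' Exhaustive argmax of the compatibility score over the candidate set; ties
#' break to the lowest candidate index.
#'
#' @param x An [ssvm_input()]; a `NULL` blob yields posture `unknown` and an
#'   empty skeleton.
#' @param model A trained `ks_ssvm_model`.
#' @param normalised Score with the unit-norm weights (used when comparing
#'   across posture classifiers).
#' @return `list(skeleton, score, index)`.
#' @export
infer_bodyparts <- function(x, model, normalised = FALSE) {
  if (!inherits(model, "ks_ssvm_model"))
    stop_invalid("state error: untrained model")
  if (is.null(x$blob))
    return(list(skeleton = empty_skeleton(), score = NA_real_,
                index = NA_integer_, solution = NULL))
  cs <- generate_candidates(x$blob, x$motion, model$posture_class,
                            model$config)
  Phi <- phi_candidates(x, cs)
  w <- if (normalised) model$w_unit else model$w
  s <- as.numeric(Phi %*% w)
  i <- which.max(s)
  post <- if (model$posture_class %in% c("stand", "sit", "lie"))
    model$posture_class else "unknown"
  sk <- decode_solution(cs$values[i, ], x$blob$barycentre, posture = post)
  list(skeleton = sk, score = s[i], index = i, solution = cs$values[i, ],
       extent = cs$extent)
}

#' Classify the posture of a frame
#'
#' Runs skeleton inference under each posture's constraint class and returns
#' the posture whose classifier attains the best (unit-norm) score, plus its
#' skeleton. Ties break in the documented order stand > sit > lie.
#'
#' @param x An [ssvm_input()].
#' @param models Named list with trained `stand`, `sit` and `lie` models.
#' @param offsets Optional per-model additive score offsets (calibration
#'   knob; default 0).
#' @return `list(posture, skeleton, scores)`.
#' @export
classify_posture <- function(x, models, offsets = c(stand = 0, sit = 0, lie = 0)) {
  for (m in c("stand", "sit", "lie"))
    if (!inherits(models[[m]], "ks_ssvm_model"))
      stop_invalid("state error: model '", m, "' is not trained")
  if (is.null(x$blob))
    return(list(posture = "unknown", skeleton = empty_skeleton(),
                scores = c(stand = NA, sit = NA, lie = NA)))
  res <- lapply(c(stand = "stand", sit = "sit", lie = "lie"), function(m)
    infer_bodyparts(x, models[[m]]))
  # across-class decision: maximised linear scores of independently trained
  # structured models are not on a shared scale, so each model scores its
  # own fitted solution by the class-conditional log-likelihood of a
  # compact fit descriptor whose statistics were recorded at training time;
  # offsets are an additional user knob
  scores <- vapply(names(res), function(m) {
    g <- fit_descriptor(x, res[[m]]$solution, res[[m]]$extent)
    descriptor_loglik(g, models[[m]]$g_mu, models[[m]]$g_sd) + offsets[[m]]
  }, numeric(1))
  best <- names(scores)[which.max(scores)]   # order stand, sit, lie breaks ties
  list(posture = best, skeleton = res[[best]]$skeleton, scores = scores)
}

#' Split stand frames into stand and locomotion
#'
#' Frames labelled `stand` are relabelled `locomotion` when the barycentre
#' speed, measured over a centred sliding window, exceeds the threshold;
#' `sit` and `lie` are never relabelled.
#'
#' @param postures Per-frame posture labels.
#' @param traj A `ks_trajectory` aligned with `postures`.
#' @param speed_threshold Metres/second (default 0.1).
#' @param window_s Width of the centred speed window in seconds (default
#'   0.5).
#' @export
derive_locomotion <- function(postures, traj, speed_threshold = 0.1,
                              window_s = 0.5) {
  n <- length(postures)
  if (n != nrow(traj))
    stop_invalid("invalid input: label/trajectory length mismatch")
  if (n == 0) return(postures)
  fps <- attr(traj, "fps")
  k <- max(1L, round(window_s * fps / 2))
  out <- postures
  for (i in seq_len(n)) {
    j1 <- max(1L, i - k); j2 <- min(n, i + k)
    if (j2 == j1) next
    v <- sqrt((traj$x[j2] - traj$x[j1])^2 + (traj$y[j2] - traj$y[j1])^2) /
      ((j2 - j1) / fps)
    if (identical(out[i], "stand") && is.finite(v) && v > speed_threshold)
      out[i] <- "locomotion"
  }
  out
}

# ---- pipeline glue --------------------------------------------------------

#' Skeleton coordinate transforms
#'
#' `skeleton_to_camera` re-expresses a pen-frame skeleton in the camera
#' frame; `skeleton_solution` encodes a camera-frame skeleton as the
#' in-plane solution vector used by the classifier.
#'
#' @param skel A [skeleton()].
#' @param camera A [camera_model()].
#' @export
skeleton_to_camera <- function(skel, camera) {
  segs <- lapply(skel$segments, function(s) pen_to_cam(s, camera))
  skeleton(segs, skel$posture)
}

#' @rdname skeleton_to_camera
#' @param motion Motion vector `c(dx, dy)`.
#' @export
skeleton_solution <- function(skel, motion = c(0, 0)) {
  segs <- skel$segments
  for (p in setdiff(PART_NAMES, names(segs))) {
    a <- segs$torso[1, , drop = FALSE]
    segs[[p]] <- rbind(a, a)
  }
  encode_solution(skeleton(segs[PART_NAMES], skel$posture), motion)
}

#' Build training pairs from an annotated synthetic dataset
#'
#' Segments every requested frame, attaches the ground-truth motion vector,
#' and encodes the ground-truth skeleton (camera frame, in-plane) as the
#' training target. Frames with no detection are dropped.
#'
#' @param dataset An `ks_annotated_dataset` from [render_sequence()].
#' @param frames Frame indices to use (default all).
#' @param threshold,min_pixels Passed to [segment_frame()].
#' @return List of training pairs; kept frame indices as attribute `frames`.
#' @export
build_training_pairs <- function(dataset, frames = seq_along(dataset$frames),
                                 threshold = 0.05, min_pixels = 100L) {
  scene <- dataset$scene
  cam <- scene$camera
  tr <- dataset$trajectory
  pairs <- list(); kept <- integer(0)
  for (i in frames) {
    blob <- segment_frame(dataset$frames[[i]], scene, threshold, min_pixels)
    if (is.null(blob)) next
    motion <- if (i == 1) c(0, 0) else
      c(tr$x[i] - tr$x[i - 1], tr$y[i] - tr$y[i - 1])
    x <- ssvm_input(blob, motion, cam, dataset$frames[[i]])
    y <- skeleton_solution(skeleton_to_camera(dataset$skeletons[[i]], cam),
                           motion)
    pairs[[length(pairs) + 1]] <- list(x = x, y = y,
                                       posture = dataset$postures[i])
    kept <- c(kept, i)
  }
  attr(pairs, "frames") <- kept
  pairs
}
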