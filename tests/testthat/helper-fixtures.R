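# Shared fixtures: small scenes and rendered clips, built once per test run.
# A reduced camera resolution and candidate grid keep the suite fast; the
# geometry (3 x 3 m pen, sensor at 1.5 m) matches the package defaults.

ks_test_scene <- function() scene_model()

# Reduced candidate grid used throughout the tests (the vertical leg
# placement and 45-degree head/tail steps cover the generator's canonical
# poses).
ks_test_config <- function() {
  candidate_config(n_torso_angles = 12, n_torso_lengths = 3,
                   n_headtail_angles = 4, n_leg_placements = 3)
}

# Memoised stand clip: one quadruped standing at six spots/headings.
ks_stand_clip <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spots <- list(c(1.2, 1.5, 0.3), c(2.2, 2.2, 2.2), c(1.0, 2.3, -1.2),
                    c(1.9, 1.2, -2.6), c(2.4, 1.7, 1.6), c(1.5, 2.0, 0.0))
      steps <- lapply(spots, function(s)
        script_step(1, "stand", list(type = "stay", at = s[1:2],
                                     heading = s[3])))
      cache <<- render_sequence(quadruped_model(), do.call(motion_script, steps),
                                ks_test_scene(), fps = 10, noise_sd_mm = 5,
                                seed = 21)
    }
    cache
  }
})

# A deterministic valid skeleton (stand pose at the pen centre).
ks_demo_skeleton <- function(posture = "stand", heading = 0.4) {
  pose_skeleton(quadruped_model(), posture, 1.5, 1.8, heading)
}

# Random in-plane skeleton on the candidate parameter grid.
ks_random_solution <- function() {
  v <- numeric(16)
  ang <- stats::runif(7, -pi, pi)
  len <- stats::runif(7, 0.1, 0.8)
  v[seq(1, 13, 2)] <- ang
  v[seq(2, 14, 2)] <- len
  v[15:16] <- stats::rnorm(2, 0, 0.02)
  v
}

# Independent brute-force NW score: enumerate every global alignment as a
# lattice path and take the maximum total score. Exponential; lengths <= 6.
ks_nw_bruteforce <- function(S, gap = 0) {
  omega <- function(cb) if (cb >= 0.5) 2 * cb else 2 * (cb - 0.5)
  n <- nrow(S); m <- ncol(S)
  rec <- function(a, b) {
    if (a == 0 && b == 0) return(0)
    best <- -Inf
    if (a > 0 && b > 0) best <- max(best, rec(a - 1, b - 1) + omega(S[a, b]))
    if (a > 0) best <- max(best, rec(a - 1, b) + gap)
    if (b > 0) best <- max(best, rec(a, b - 1) + gap)
    best
  }
  rec(n, m)
}

ks_part_names <- c("head", "torso", "tail", "leg_fl", "leg_fr",
                   "leg_bl", "leg_br")

# Random skeleton with all seven parts (3D, generic angles).
ks_random_skeleton <- function() {
  segs <- lapply(ks_part_names, function(p) {
    a <- stats::runif(3, -1, 1)
    rbind(a, a + stats::runif(3, -1, 1))
  })
  names(segs) <- ks_part_names
  skeleton(segs, "unknown")
}

ks_random_skelgraph <- function() build_skeleton_graph(ks_random_skeleton())

# Rigidly rotate a skeleton about the z axis (and optionally tilt) around
# its torso midpoint.
ks_rotate_skeleton <- function(skel, yaw, pitch = 0) {
  Rz <- rbind(c(cos(yaw), -sin(yaw), 0), c(sin(yaw), cos(yaw), 0), c(0, 0, 1))
  Ry <- rbind(c(cos(pitch), 0, sin(pitch)), c(0, 1, 0),
              c(-sin(pitch), 0, cos(pitch)))
  R <- Rz %*% Ry
  ctr <- colMeans(skel$segments$torso)
  segs <- lapply(skel$segments, function(s)
    sweep(sweep(s, 2, ctr) %*% t(R), 2, ctr, `+`))
  skeleton(segs, skel$posture)
}
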