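# Structured classifier: feature map, scoring, candidate constraints,
# training behaviour and locomotion derivation. (The learning-curve and
# confusion-structure experiments live in the acceptance suite.)

make_input <- function(i = 1) {
  clip <- ks_stand_clip()
  sc <- ks_test_scene()
  blob <- segment_frame(clip$frames[[i]], sc, min_pixels = 100)
  ssvm_input(blob, c(0, 0), sc$camera, clip$frames[[i]])
}

test_that("joint feature map is deterministic, finite and blob-gated", {
  x <- make_input()
  y <- skeleton_solution(
    skeleton_to_camera(ks_stand_clip()$skeletons[[1]], ks_test_scene()$camera))
  f1 <- joint_feature_map(x, y)
  f2 <- joint_feature_map(x, y)
  expect_identical(f1, f2)
  expect_true(all(is.finite(f1)))
  # zero blob: appearance block all-zero, motion passthrough
  x0 <- x
  x0$blob$mask[] <- FALSE
  x0$motion <- c(0.03, -0.01)
  y0 <- y; y0[15:16] <- x0$motion
  f0 <- joint_feature_map(x0, y0)
  d <- length(f0)
  expect_true(all(f0[seq_len(d - 4)] == 0))
  expect_equal(f0[d - 3], 0.03)
  expect_equal(f0[d - 2], -0.01)
  # norm bounded over random solutions
  set.seed(61)
  norms <- vapply(1:200, function(i)
    sqrt(sum(joint_feature_map(x, ks_random_solution())^2)), 0)
  expect_true(all(norms < sqrt(length(f1)) + 1))
})

test_that("score is the inner product and linear in the weights", {
  x <- make_input()
  y <- ks_random_solution()
  d <- length(joint_feature_map(x, y))
  expect_equal(ssvm_score(numeric(d), x, y), 0)
  phi <- joint_feature_map(x, y)
  expect_equal(ssvm_score(phi, x, y), sum(phi^2))
  set.seed(67)
  w1 <- rnorm(d); w2 <- rnorm(d)
  expect_equal(ssvm_score(2 * w1 + 3 * w2, x, y),
               2 * ssvm_score(w1, x, y) + 3 * ssvm_score(w2, x, y),
               tolerance = 1e-9)
  expect_error(ssvm_score(numeric(3), x, y), "dimension")
})

test_that("candidate sets obey posture constraints and counts", {
  x <- make_input()
  cfg <- ks_test_config()
  cs <- generate_candidates(x$blob, c(0, 0), "stand", cfg)
  expect_equal(nrow(cs$values), 12 * 3 * 4 * 4 * 3)
  # every torso midpoint at the barycentre (anchored by construction)
  E <- kennelscope:::candidate_endpoints(cs$values, cs$barycentre)
  mid <- cbind((E[, 5] + E[, 7]) / 2, (E[, 6] + E[, 8]) / 2)
  expect_lt(max(abs(sweep(mid, 2, cs$barycentre[1:2]))), 1e-9)
  # lie: all legs at the zero-length sentinel
  cl <- generate_candidates(x$blob, c(0, 0), "lie", cfg)
  expect_true(all(cl$values[, c(8, 10, 12, 14)] == 0))
  # sit: front legs present, rear legs folded
  csit <- generate_candidates(x$blob, c(0, 0), "sit", cfg)
  expect_true(all(csit$values[, 8] > 0))
  expect_true(all(csit$values[, c(12, 14)] == 0))
  # stand legs point below the torso (image y grows downwards)
  expect_true(all(sin(cs$values[, c(7, 9, 11, 13)]) > 0))
  expect_error(generate_candidates(NULL), "empty blob")
})

test_that("a single memorised frame is recovered exactly by inference", {
  clip <- ks_stand_clip()
  pairs <- build_training_pairs(clip, frames = 1, min_pixels = 100)
  cfg <- ks_test_config()
  m <- train_ssvm(pairs, "stand", cfg, epochs = 20, C = 1, seed = 1)
  inf <- infer_bodyparts(pairs[[1]]$x, m)
  cs <- generate_candidates(pairs[[1]]$x$blob, pairs[[1]]$x$motion, "stand",
                            cfg)
  losses <- kennelscope:::candidate_losses(cs, pairs[[1]]$y)
  expect_equal(inf$index, which.min(losses))
  # training loss reaches zero on the memorised frame
  expect_equal(tail(m$epoch_loss, 1), 0)
  expect_error(train_ssvm(list()), "no training pairs")
})

test_that("inference equals an explicit brute-force candidate loop", {
  clip <- ks_stand_clip()
  pairs <- build_training_pairs(clip, frames = c(1, 21), min_pixels = 100)
  cfg <- ks_test_config()
  m <- train_ssvm(pairs, "stand", cfg, epochs = 3, C = 0.5, seed = 2)
  for (p in pairs) {
    cs <- generate_candidates(p$x$blob, p$x$motion, "stand", cfg)
    best_i <- 1; best_s <- -Inf
    for (i in seq_len(nrow(cs$values))) {
      s <- sum(m$w * joint_feature_map(p$x, cs$values[i, ], cfg))
      if (s > best_s) { best_s <- s; best_i <- i }
    }
    inf <- infer_bodyparts(p$x, m)
    expect_equal(inf$index, best_i)
    expect_equal(inf$score, best_s, tolerance = 1e-9)
  }
})

test_that("no-detection frames yield unknown posture and empty skeleton", {
  clip <- ks_stand_clip()
  pairs <- build_training_pairs(clip, frames = 1, min_pixels = 100)
  m <- train_ssvm(pairs, "stand", ks_test_config(), epochs = 2, seed = 1)
  x0 <- pairs[[1]]$x
  x0$blob <- NULL
  inf <- infer_bodyparts(x0, m)
  expect_length(inf$skeleton$segments, 0)
  expect_true(is.na(inf$score))
  res <- classify_posture(x0, list(stand = m, sit = m, lie = m))
  expect_equal(res$posture, "unknown")
  expect_error(classify_posture(x0, list(stand = m, sit = NULL, lie = m)),
               "state error")
  expect_error(infer_bodyparts(x0, "not a model"), "state error")
})

test_that("locomotion derivation follows the speed rule", {
  postures <- rep("stand", 50)
  still <- trajectory_from_xy(rep(1, 50), rep(1, 50), 10)
  expect_equal(derive_locomotion(postures, still), postures)
  walk <- trajectory_from_xy(seq(0, 2.45, by = 0.05), rep(1, 50), 10)
  out <- derive_locomotion(postures, walk, speed_threshold = 0.1)
  expect_true(all(out == "locomotion"))
  # sit/lie never relabelled; infinite threshold leaves labels unchanged
  mixed <- c(rep("sit", 25), rep("lie", 25))
  expect_equal(derive_locomotion(mixed, walk), mixed)
  expect_equal(derive_locomotion(postures, walk, speed_threshold = Inf),
               postures)
  expect_error(derive_locomotion(postures[1:10], walk), "mismatch")
})

test_that("training loss is non-increasing on average across epochs", {
  clip <- ks_stand_clip()
  pairs <- build_training_pairs(clip, frames = seq(1, 60, by = 6),
                                min_pixels = 100)
  m <- train_ssvm(pairs, "stand", ks_test_config(), epochs = 6, C = 0.5,
                  seed = 3)
  half <- length(m$epoch_loss) / 2
  expect_lt(mean(tail(m$epoch_loss, half)), mean(head(m$epoch_loss, half)))
})
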