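# Symbol similarities, the alignment scoring scheme, NW alignment and
# K-medoids pattern discovery.

test_that("trajectory symbol similarity is the negative exponential of distance", {
  expect_equal(traj_symbol_similarity(c(1, 2), c(1, 2)), 1)
  expect_equal(traj_symbol_similarity(c(0, 0), c(1, 0)), exp(-1))
  expect_equal(traj_symbol_similarity(c(0, 0), c(0, 2), scale = 2), exp(-1))
  # monotone decreasing in distance
  d <- seq(0, 3, by = 0.1)
  s <- vapply(d, function(dd) traj_symbol_similarity(c(0, 0), c(dd, 0)), 0)
  expect_true(all(diff(s) < 0))
})

test_that("action symbol similarity is a Gramian determinant in [0, 1]", {
  set.seed(3)
  for (rep in 1:10) {
    g <- ks_random_skelgraph()
    expect_equal(action_symbol_similarity(g, g), 1, tolerance = 1e-9)
  }
  # orthogonal eigenbases give 0
  Ba <- cbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  Bb <- cbind(c(0, 0, 1, 0), c(0, 0, 0, 1))
  expect_equal(action_symbol_similarity(Ba, Bb), 0)
  # symmetry
  for (rep in 1:10) {
    ga <- ks_random_skelgraph(); gb <- ks_random_skelgraph()
    expect_equal(action_symbol_similarity(ga, gb),
                 action_symbol_similarity(gb, ga), tolerance = 1e-10)
  }
})

test_that("symbol score reproduces the +2 / -1 / 0 scheme", {
  expect_equal(symbol_score(1), 2)      # perfect match
  expect_equal(symbol_score(0), -1)     # complete mismatch
  expect_equal(symbol_score(NA), 0)     # gap
  expect_equal(symbol_score(0.5), 1)    # boundary branch 2 * 0.5
  expect_equal(symbol_score(0.25), -0.5)
  expect_error(symbol_score(1.2), "outside")
})

test_that("self-alignment of an n-symbol self-similar window scores 2n", {
  for (n in c(1, 4, 9)) {
    xy <- cbind(rep(1.1, n), rep(0.7, n))
    w <- sequence_window(xy, feature = "trajectory")
    al <- nw_align(w, w)
    expect_equal(al$score, 2 * n)
  }
  # empty vs length-n: all gaps, score 0
  e <- sequence_window(matrix(numeric(0), 0, 2), feature = "trajectory")
  w <- sequence_window(cbind(1:3, 1:3), feature = "trajectory")
  expect_equal(nw_align(e, w)$score, 0)
})

test_that("NW table equals brute-force enumeration over all alignments", {
  set.seed(17)
  for (rep in 1:60) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    Ta <- sequence_window(cbind(runif(n, 0, 3), runif(n, 0, 3)),
                          feature = "trajectory")
    Tb <- sequence_window(cbind(runif(m, 0, 3), runif(m, 0, 3)),
                          feature = "trajectory")
    S <- kennelscope:::window_similarity_matrix(Ta, Tb)
    expect_equal(nw_align(Ta, Tb)$score, ks_nw_bruteforce(S),
                 tolerance = 1e-9)
  }
})

test_that("alignment tolerates temporal shift (the low gap penalty)", {
  # same path sampled at 1x and 2x speed scores higher than two different
  # patterns of equal length
  t1 <- seq(0, 1, length.out = 20)
  path <- cbind(0.5 + 2 * t1, 1.5)
  slow <- sequence_window(path, feature = "trajectory")
  fast <- sequence_window(path[seq(1, 20, by = 2), ], feature = "trajectory")
  other <- sequence_window(cbind(0.5, 0.5 + 2 * t1[1:10]),
                           feature = "trajectory")
  expect_gt(nw_align(slow, fast)$score, nw_align(slow, other)$score)
  # inserting dwell (gap-worth symbols) cannot decrease the score by more
  # than the gap cost (0)
  base <- nw_align(slow, slow)$score
  dwell <- sequence_window(rbind(path[1:10, ],
                                 matrix(path[10, ], 5, 2, byrow = TRUE),
                                 path[11:20, ]), feature = "trajectory")
  expect_gte(nw_align(slow, dwell)$score, base)
})

test_that("pairwise similarity matrix is symmetric with dominant diagonal", {
  pw <- planted_pattern_windows(c(1, 1, 1, 1), window_s = 2, jitter = 0,
                                seed = 4)
  S <- pairwise_similarity_matrix(pw$windows)
  expect_equal(S, t(S), tolerance = 1e-9)
  expect_equal(dim(S), c(4, 4))
  for (i in 1:4) expect_equal(which.max(S[i, ]), i)
})

test_that("K-medoids recovers planted patterns and the trivial partitions", {
  pw <- planted_pattern_windows(c(3, 2, 3, 2), window_s = 5, jitter = 0,
                                seed = 9)
  S <- pairwise_similarity_matrix(pw$windows)
  res <- kmedoids_cluster(S, 4, seed = 1)
  expect_length(res$assignment, 10)
  expect_true(all(res$assignment[res$medoids] == seq_along(res$medoids)))
  # perfect recovery of the planted partition
  expect_equal(mclust::adjustedRandIndex(res$assignment, pw$labels), 1)
  # objective trace non-increasing
  expect_true(all(diff(res$objective_trace) <= 1e-9))
  # n_clusters = n: every window its own medoid
  triv <- kmedoids_cluster(S, 10, seed = 2)
  expect_equal(sort(triv$medoids), 1:10)
  expect_error(kmedoids_cluster(S, 0), "n_clusters")
  # independent cross-check: PAM from the cluster package agrees at k = 4
  D <- max(S) - S
  pam <- cluster::pam(stats::as.dist(D), 4, nstart = 5)
  expect_equal(mclust::adjustedRandIndex(res$assignment, pam$clustering), 1)
})

test_that("video partitioning follows the half-window trailing rule", {
  tr <- trajectory_from_xy(runif(500, 0, 3), runif(500, 0, 3), fps = 10)
  expect_length(partition_video(tr, window_s = 5), 10)      # 50 s -> 10
  tr2 <- trajectory_from_xy(runif(520, 0, 3), runif(520, 0, 3), fps = 10)
  expect_length(partition_video(tr2, window_s = 5), 10)     # 2 s dropped
  tr3 <- trajectory_from_xy(runif(530, 0, 3), runif(530, 0, 3), fps = 10)
  expect_length(partition_video(tr3, window_s = 5), 11)     # 3 s kept
  tr4 <- trajectory_from_xy(runif(30, 0, 3), runif(30, 0, 3), fps = 10)
  expect_length(partition_video(tr4, window_s = 60), 1)
})

test_that("action windows of rotated skeleton sequences align like self", {
  set.seed(23)
  sks <- lapply(1:5, function(i) ks_random_skeleton())
  rots <- lapply(sks, ks_rotate_skeleton, yaw = 1.1, pitch = 0.4)
  wa <- sequence_window(lapply(sks, build_skeleton_graph), feature = "action")
  wb <- sequence_window(lapply(rots, build_skeleton_graph), feature = "action")
  self <- nw_align(wa, wa)$score
  cross <- nw_align(wa, wb)$score
  expect_equal(cross, self, tolerance = 1e-6)
  expect_equal(self, 2 * 5)
})
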