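# Unsupervised discovery of movement patterns: fixed-length windows of
# either ground coordinates or spectral skeleton-graph descriptors are
# compared by Needleman-Wunsch global alignment with a match/mismatch/gap
# scheme (+2 perfect match, -1 mismatch, 0 gap), and the resulting
# similarity matrix is partitioned by K-medoids.

#' Symbol similarity for trajectory windows
#'
#' Negative exponential of the Euclidean distance between two ground
#' positions: `c_b = exp(-||p - q|| / scale)`, in (0, 1].
#'
#' @param p,q Length-2 positions (metres), or n x 2 / m x 2 matrices (then a
#'   full n x m similarity matrix is returned).
#' @param scale Length scale in metres (default 1; the bare negative
#'   exponential of the distance).
#' @export
traj_symbol_similarity <- function(p, q, scale = 1) {
  stopifnot(scale > 0)
  p <- rbind(p); q <- rbind(q)
  d2 <- outer(p[, 1], q[, 1], `-`)^2 + outer(p[, 2], q[, 2], `-`)^2
  s <- exp(-sqrt(d2) / scale)
  if (nrow(p) == 1 && nrow(q) == 1) as.numeric(s) else s
}

#' Symbol similarity for action (skeleton-graph) windows
#'
#' The leading `k` non-trivial Laplacian eigenvectors of each graph form
#' orthonormal bases `Ba`, `Bb`; with `M = t(Ba) %*% Bb`, the similarity is
#' the square root of the Gramian determinant, `c_b = sqrt(det(t(M) %*% M))
#' = |det M|`, clipped to [0, 1] against round-off. Identical subspaces give
#' 1, orthogonal subspaces 0.
#'
#' @param Ga,Gb `ks_skelgraph` objects (see [build_skeleton_graph()]), or
#'   precomputed eigenbasis matrices.
#' @param k Number of retained eigenvectors (default 3).
#' @export
action_symbol_similarity <- function(Ga, Gb, k = 3) {
  Ba <- if (inherits(Ga, "ks_skelgraph")) leading_eigenvectors(Ga, k) else Ga
  Bb <- if (inherits(Gb, "ks_skelgraph")) leading_eigenvectors(Gb, k) else Gb
  if (!all(dim(Ba) == dim(Bb)))
    stop_invalid("invalid input: graphs have mismatching vertex sets")
  M <- t(Ba) %*% Bb
  min(1, max(0, abs(det(M))))
}

#' Symbol-to-symbol alignment score
#'
#' The piecewise scheme: `2 * c_b` when `c_b >= 0.5`, `2 * (c_b - 0.5)` when
#' `c_b < 0.5`, and 0 when either symbol is a gap — i.e. +2 for a perfect
#' match, -1 for a complete mismatch, 0 for a gap.
#'
#' @param cb Similarity in [0, 1], or `NA` for a gap.
#' @export
symbol_score <- function(cb) {
  if (length(cb) == 1 && is.na(cb)) return(0)
  if (any(cb < 0 | cb > 1)) stop_invalid("invalid input: c_b outside [0, 1]")
  ifelse(cb >= 0.5, 2 * cb, 2 * (cb - 0.5))
}

#' Fixed-length temporal window of symbols
#'
#' @param symbols For `feature = "trajectory"`, an n x 2 matrix of ground
#'   coordinates; for `feature = "action"`, a list of `ks_skelgraph`s or of
#'   precomputed eigenbasis matrices.
#' @param id,source Window identifier and source video id.
#' @param start,end Start/end time in seconds.
#' @param feature `trajectory` or `action`.
#' @export
sequence_window <- function(symbols, id = NA, source = NA,
                            start = NA_real_, end = NA_real_,
                            feature = c("trajectory", "action")) {
  feature <- match.arg(feature)
  structure(list(id = id, source = source, start = start, end = end,
                 feature = feature, symbols = symbols),
            class = "ks_window")
}

window_length <- function(w) {
  if (w$feature == "trajectory") nrow(w$symbols) else length(w$symbols)
}

# n x m matrix of symbol similarities between two windows.
window_similarity_matrix <- function(Ta, Tb, scale = 1, k = 3) {
  if (Ta$feature != Tb$feature)
    stop_invalid("invalid input: windows carry different features")
  if (Ta$feature == "trajectory") {
    S <- traj_symbol_similarity(Ta$symbols, Tb$symbols, scale)
    matrix(S, nrow(Ta$symbols), nrow(Tb$symbols))
  } else {
    Ba <- lapply(Ta$symbols, function(g)
      if (inherits(g, "ks_skelgraph")) leading_eigenvectors(g, k) else g)
    Bb <- lapply(Tb$symbols, function(g)
      if (inherits(g, "ks_skelgraph")) leading_eigenvectors(g, k) else g)
    outer(seq_along(Ba), seq_along(Bb),
          Vectorize(function(i, j) action_symbol_similarity(Ba[[i]], Bb[[j]])))
  }
}

#' Needleman-Wunsch global alignment of two windows
#'
#' Fills the (n+1) x (m+1) score table (base condition: cumulative gap
#' scores along row and column 0 — all zero under the 0 gap score), takes
#' the three-way maximum recursion, and returns the bottom-right optimal
#' alignment score with one traceback path (tie order: diagonal > up >
#' left).
#'
#' @param Ta,Tb [sequence_window()]s sharing a feature type.
#' @param scale Trajectory length scale, metres.
#' @param k Retained eigenvectors for action windows.
#' @return Object of class `ks_alignment`: `score`, `table` (the score
#'   table `V`), `pairs` (two-column matrix of aligned symbol indices, `NA`
#'   against a gap).
#' @export
nw_align <- function(Ta, Tb, scale = 1, k = 3) {
  n <- window_length(Ta); m <- window_length(Tb)
  gap <- symbol_score(NA)
  V <- matrix(0, n + 1, m + 1)
  V[1, ] <- gap * (0:m)
  V[, 1] <- gap * (0:n)
  if (n > 0 && m > 0) {
    S <- window_similarity_matrix(Ta, Tb, scale, k)
    Om <- symbol_score(S)
    for (a in seq_len(n)) {
      diagv <- V[a, seq_len(m)] + Om[a, ]
      upv <- V[a, 2:(m + 1)] + gap
      # left moves depend on the row being filled: sequential scan
      row <- numeric(m)
      prev <- V[a + 1, 1]
      for (b in seq_len(m)) {
        row[b] <- max(diagv[b], upv[b], prev + gap)
        prev <- row[b]
      }
      V[a + 1, 2:(m + 1)] <- row
    }
  }
  pairs <- nw_traceback(V, if (n > 0 && m > 0) Om else NULL, gap, n, m)
  structure(list(score = V[n + 1, m + 1], table = V, pairs = pairs),
            class = "ks_alignment")
}

nw_traceback <- function(V, Om, gap, n, m) {
  pairs <- matrix(integer(0), 0, 2)
  a <- n; b <- m
  while (a > 0 || b > 0) {
    if (a > 0 && b > 0 &&
        abs(V[a + 1, b + 1] - (V[a, b] + Om[a, b])) < 1e-9) {
      pairs <- rbind(c(a, b), pairs); a <- a - 1; b <- b - 1
    } else if (a > 0 && abs(V[a + 1, b + 1] - (V[a, b + 1] + gap)) < 1e-9) {
      pairs <- rbind(c(a, NA), pairs); a <- a - 1
    } else {
      pairs <- rbind(c(NA, b), pairs); b <- b - 1
    }
  }
  colnames(pairs) <- c("a", "b")
  pairs
}

#' Pairwise alignment similarity matrix over windows
#'
#' Each unordered pair is aligned once; the matrix is symmetric by
#' construction.
#'
#' @param windows List of [sequence_window()]s.
#' @param scale,k Passed to [nw_align()].
#' @export
pairwise_similarity_matrix <- function(windows, scale = 1, k = 3) {
  n <- length(windows)
  if (n < 2) stop_invalid("invalid input: need at least 2 windows")
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- nw_align(windows[[i]], windows[[j]], scale, k)$score
      S[i, j] <- S[j, i] <- s
    }
  }
  S
}

#' K-medoids clustering of a similarity matrix
#'
#' Similarities are turned into distances by the monotone-decreasing
#' transform `d = max(S) - S`, then a PAM-style search runs: `n_clusters`
#' distinct medoids are drawn with a seeded RNG and single-medoid swaps are
#' applied greedily while they reduce the sum of within-cluster distances
#' to the medoid. Windows are reported ordered by distance from their
#' cluster medoid (the most representative sequence first).
#'
#' @param S Square symmetric similarity matrix.
#' @param n_clusters Number of clusters, `1 <= n_clusters <= nrow(S)`.
#' @param seed RNG seed for the initial medoid draw (recorded in the
#'   output).
#' @return Object of class `ks_kmedoids`: `assignment`, `medoids`,
#'   `distance_to_medoid`, `ordering` (list per cluster, nearest first),
#'   `objective_trace` (non-increasing), `seed`.
#' @export
kmedoids_cluster <- function(S, n_clusters, seed = 1) {
  n <- nrow(S)
  if (is.null(n) || n != ncol(S)) stop_invalid("invalid input: S must be square")
  if (n_clusters < 1 || n_clusters > n)
    stop_invalid("invalid input: n_clusters must be in [1, n]")
  D <- max(S) - S
  objective <- function(med) sum(apply(D[, med, drop = FALSE], 1, min))
  med <- sort(with_seed(seed, sample(n, n_clusters)))
  trace <- objective(med)
  repeat {
    best <- trace[length(trace)]
    swap <- NULL
    for (mi in seq_along(med)) {
      for (cand in setdiff(seq_len(n), med)) {
        trial <- med; trial[mi] <- cand
        o <- objective(trial)
        if (o < best - 1e-12) { best <- o; swap <- trial }
      }
    }
    if (is.null(swap)) break
    med <- sort(swap)
    trace <- c(trace, best)
  }
  dmat <- D[, med, drop = FALSE]
  assignment <- apply(dmat, 1, which.min)
  assignment[med] <- seq_along(med)   # each medoid belongs to its own cluster
  dist_to_med <- dmat[cbind(seq_len(n), assignment)]
  ordering <- lapply(seq_along(med), function(cl) {
    idx <- which(assignment == cl)
    idx[order(dist_to_med[idx])]
  })
  structure(list(assignment = assignment, medoids = med,
                 distance_to_medoid = dist_to_med, ordering = ordering,
                 objective_trace = trace, seed = seed),
            class = "ks_kmedoids")
}

#' Partition a recording into fixed-length windows
#'
#' Contiguous non-overlapping windows of nominal length `window_s`. A
#' trailing remainder shorter than half a window is dropped; a longer one is
#' kept as a truncated window. The trajectory feature windows ground
#' coordinates; the action feature windows skeleton-graph descriptors (the
#' skeleton's movement in time, not its position in the pen).
#'
#' @param traj A `ks_trajectory` (required for `feature = "trajectory"`).
#' @param skeletons List of per-frame [skeleton()]s (required for
#'   `feature = "action"`).
#' @param window_s Window length in seconds (default 5).
#' @param fps Frames per second (defaults to the trajectory's).
#' @param feature `trajectory` or `action`.
#' @param source Source video id stamped on the windows.
#' @return List of [sequence_window()]s.
#' @export
partition_video <- function(traj = NULL, skeletons = NULL, window_s = 5,
                            fps = if (!is.null(traj)) attr(traj, "fps") else 10,
                            feature = c("trajectory", "action"),
                            source = NA) {
  feature <- match.arg(feature)
  stopifnot(window_s > 0)
  nf <- if (feature == "trajectory") nrow(traj) else length(skeletons)
  if (nf == 0) return(list())
  wlen <- max(1L, round(window_s * fps))
  n_full <- nf %/% wlen
  rem <- nf - n_full * wlen
  starts <- (seq_len(n_full) - 1) * wlen + 1
  ends <- starts + wlen - 1
  if (n_full == 0 || rem >= 0.5 * wlen) {
    starts <- c(starts, n_full * wlen + 1)
    ends <- c(ends, nf)
  }
  lapply(seq_along(starts), function(i) {
    idx <- starts[i]:ends[i]
    symbols <- if (feature == "trajectory") {
      cbind(traj$x[idx], traj$y[idx])
    } else {
      lapply(skeletons[idx], build_skeleton_graph)
    }
    sequence_window(symbols, id = i, source = source,
                    start = (starts[i] - 1) / fps, end = ends[i] / fps,
                    feature = feature)
  })
}

#' Write a cluster manifest CSV
#'
#' Columns `window_id, start_s, end_s, cluster, distance_to_medoid,
#' is_medoid`, ordered by cluster then by distance from the medoid.
#'
#' @param windows The clustered [sequence_window()]s.
#' @param result A [kmedoids_cluster()] result.
#' @param path Output file.
#' @export
write_cluster_manifest <- function(windows, result, path) {
  rows <- do.call(rbind, lapply(seq_along(result$ordering), function(cl) {
    idx <- result$ordering[[cl]]
    data.frame(window_id = vapply(windows[idx], function(w) w$id, numeric(1)),
               start_s = vapply(windows[idx], function(w) w$start, numeric(1)),
               end_s = vapply(windows[idx], function(w) w$end, numeric(1)),
               cluster = cl,
               distance_to_medoid = result$distance_to_medoid[idx],
               is_medoid = idx %in% result$medoids)
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
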