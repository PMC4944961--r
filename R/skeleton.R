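# Seven-part skeleton: head, torso, tail, four legs. Each part is a line
# segment; missing parts (folded legs in sit/lie) use the zero-length
# sentinel so the 16-value solution vector is total for all postures.

#' Construct a skeleton
#'
#' @param segments Named list (names from `head, torso, tail, leg_fl,
#'   leg_fr, leg_bl, leg_br`) of 2 x d matrices (rows = the two endpoints,
#'   d = 2 or 3 coordinates in metres). Zero-length segments encode omitted
#'   parts.
#' @param posture One of `stand`, `sit`, `lie`, `locomotion`, `unknown`.
#' @return Object of class `ks_skeleton`.
#' @export
skeleton <- function(segments, posture = "unknown") {
  stopifnot(is.list(segments))
  if (!all(names(segments) %in% PART_NAMES))
    stop_invalid("unknown part name(s): ",
                 paste(setdiff(names(segments), PART_NAMES), collapse = ", "))
  if (length(segments) > 0 && !("torso" %in% names(segments)))
    stop_invalid("torso must be present whenever any part is present")
  segments <- lapply(segments, function(s) {
    s <- rbind(s)
    stopifnot(nrow(s) == 2)
    s
  })
  structure(list(segments = segments, posture = posture),
            class = "ks_skeleton")
}

empty_skeleton <- function() skeleton(list(), "unknown")

segment_length <- function(seg, dims = seq_len(ncol(seg))) {
  vnorm(seg[2, dims] - seg[1, dims])
}

# In-plane (first two coordinates) orientation of a directed segment.
segment_angle <- function(seg) {
  d <- seg[2, 1:2] - seg[1, 1:2]
  if (vnorm(d) < 1e-12) 0 else atan2(d[2], d[1])
}

#' Encode a skeleton and motion vector as a 16-value solution vector
#'
#' Two values per part — the in-plane orientation angle (radians, from the
#' first endpoint to the second) and the projected length (metres) — in the
#' canonical part order head, torso, tail, leg_fl, leg_fr, leg_bl, leg_br,
#' followed by the two motion-vector components (ground-plane barycentre
#' displacement, metres/frame). Omitted parts contribute the `(0, 0)`
#' sentinel. Round-trips with [decode_solution()] on the quantised candidate
#' grid.
#'
#' @param skel A [skeleton()] with all seven parts present (zero-length
#'   allowed).
#' @param motion Length-2 motion vector `c(dx, dy)`.
#' @return Numeric vector of length 16.
#' @export
encode_solution <- function(skel, motion = c(0, 0)) {
  stopifnot(length(motion) == 2)
  if (!all(PART_NAMES %in% names(skel$segments)))
    stop_invalid("all seven parts must be present (use zero-length sentinels)")
  v <- numeric(16)
  for (i in seq_along(PART_NAMES)) {
    seg <- skel$segments[[PART_NAMES[i]]]
    len <- segment_length(seg, 1:2)
    v[2 * i - 1] <- if (len < 1e-12) 0 else segment_angle(seg)
    v[2 * i] <- len
  }
  v[15:16] <- motion
  v
}

#' Decode a solution vector into a skeleton anchored at a barycentre
#'
#' Reconstructs the candidate-grid geometry: the torso midpoint sits at the
#' barycentre; the head is attached at the torso front end, the tail at the
#' rear end, front legs at the front-quarter point and rear legs at the
#' rear-quarter point of the torso. All segments lie in the plane z =
#' barycentre z.
#'
#' @param values Length-16 solution vector (see [encode_solution()]).
#' @param barycentre Length-2 or -3 anchor point; a third coordinate is
#'   carried through as the constant plane depth.
#' @param posture Posture label for the returned skeleton.
#' @return A [skeleton()], plus the motion vector as attribute `motion`.
#' @export
decode_solution <- function(values, barycentre, posture = "unknown") {
  stopifnot(length(values) == 16)
  bc <- as.numeric(barycentre)
  z <- if (length(bc) >= 3) bc[3] else NULL
  mid <- bc[1:2]
  ang <- values[seq(1, 13, by = 2)]
  len <- values[seq(2, 14, by = 2)]
  names(ang) <- names(len) <- PART_NAMES
  ut <- c(cos(ang["torso"]), sin(ang["torso"]))
  front <- mid + ut * len["torso"] / 2
  back <- mid - ut * len["torso"] / 2
  anchor <- list(head = front, torso = back, tail = back,
                 leg_fl = mid + ut * len["torso"] / 4,
                 leg_fr = mid + ut * len["torso"] / 4,
                 leg_bl = mid - ut * len["torso"] / 4,
                 leg_br = mid - ut * len["torso"] / 4)
  segs <- lapply(PART_NAMES, function(p) {
    a <- anchor[[p]]
    tip <- if (p == "torso") front
      else a + c(cos(ang[p]), sin(ang[p])) * len[p]
    seg <- rbind(a, tip)
    if (!is.null(z)) seg <- cbind(seg, z)
    dimnames(seg) <- NULL
    seg
  })
  names(segs) <- PART_NAMES
  sk <- skeleton(segs, posture)
  attr(sk, "motion") <- values[15:16]
  sk
}

# ---- junction graph -------------------------------------------------------

JUNCTIONS <- c("j_head", "j_fl", "j_fr", "j_bl", "j_br", "j_tail")
# segment incident at each junction (besides the torso)
JUNCTION_SEG <- c(j_head = "head", j_fl = "leg_fl", j_fr = "leg_fr",
                  j_bl = "leg_bl", j_br = "leg_br", j_tail = "tail")
# edges: consecutive attachment points along the torso axis, plus the two
# legs sharing an attachment point
GRAPH_EDGES <- rbind(
  c("j_head", "j_fl"), c("j_head", "j_fr"),
  c("j_fl", "j_bl"), c("j_fr", "j_br"),
  c("j_bl", "j_tail"), c("j_br", "j_tail"),
  c("j_fl", "j_fr"), c("j_bl", "j_br"))

# 3D (or 2D) angle between two segments' direction vectors, in [0, pi];
# zero-length sentinel segments contribute angle 0.
segment_pair_angle <- function(sa, sb) {
  da <- sa[2, ] - sa[1, ]
  db <- sb[2, ] - sb[1, ]
  na <- vnorm(da); nb <- vnorm(db)
  if (na < 1e-12 || nb < 1e-12) return(0)
  acos(pmin(1, pmax(-1, sum(da * db) / (na * nb))))
}

#' Build the junction graph of a skeleton
#'
#' Vertices are the six body-part junctions (head-torso, tail-torso and the
#' four leg attachment points); edges join junctions that are consecutive
#' along the torso axis or share an attachment point. The weight of an edge
#' is `exp(-delta_theta)` where `delta_theta` is the unsigned angle (radians)
#' between the two non-torso segments incident at its endpoints, so weights
#' lie in (0, 1] and depend only on the skeleton's internal angles — the
#' descriptor is invariant to rigid rotation and uniform scaling.
#'
#' @param skel A [skeleton()] with a torso.
#' @return Object of class `ks_skelgraph`: `vertices`, `W` (symmetric,
#'   zero-diagonal weight matrix), `L` (normalised Laplacian
#'   `I - D^(-1/2) W D^(-1/2)`).
#' @export
build_skeleton_graph <- function(skel) {
  if (!("torso" %in% names(skel$segments)))
    stop_invalid("invalid input: torso missing")
  segs <- skel$segments
  get_seg <- function(p) {
    if (p %in% names(segs)) segs[[p]]
    else rbind(c(0, 0), c(0, 0))   # omitted part: zero-length sentinel
  }
  n <- length(JUNCTIONS)
  W <- matrix(0, n, n, dimnames = list(JUNCTIONS, JUNCTIONS))
  for (e in seq_len(nrow(GRAPH_EDGES))) {
    a <- GRAPH_EDGES[e, 1]; b <- GRAPH_EDGES[e, 2]
    dth <- segment_pair_angle(get_seg(JUNCTION_SEG[[a]]),
                              get_seg(JUNCTION_SEG[[b]]))
    W[a, b] <- W[b, a] <- exp(-dth)
  }
  D <- rowSums(W)
  Dm <- diag(1 / sqrt(D))
  L <- diag(n) - Dm %*% W %*% Dm
  L <- (L + t(L)) / 2
  dimnames(L) <- dimnames(W)
  structure(list(vertices = JUNCTIONS, W = W, L = L),
            class = "ks_skelgraph")
}

#' Leading non-trivial eigenvectors of a normalised Laplacian
#'
#' Eigenvectors sorted by ascending eigenvalue; the first (trivial,
#' smallest-eigenvalue) component is discarded and the next `k` returned.
#' Each vector's sign is fixed so that its largest-magnitude entry is
#' positive, making the basis deterministic.
#'
#' @param L Normalised Laplacian matrix (or a `ks_skelgraph`).
#' @param k Number of eigenvectors to retain, `1 <= k < nrow(L)`.
#' @return n x k orthonormal matrix with attribute `eigenvalues`.
#' @export
leading_eigenvectors <- function(L, k = 3) {
  if (inherits(L, "ks_skelgraph")) L <- L$L
  n <- nrow(L)
  if (k < 1 || k >= n)
    stop_invalid("invalid input: need 1 <= k < number of vertices")
  e <- eigen(L, symmetric = TRUE)
  ord <- order(e$values)            # ascending
  vecs <- e$vectors[, ord, drop = FALSE][, 1 + seq_len(k), drop = FALSE]
  vals <- e$values[ord][1 + seq_len(k)]
  for (j in seq_len(k)) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  attr(vecs, "eigenvalues") <- vals
  vecs
}

# ---- serialisation --------------------------------------------------------

#' Write / read skeletons as CSV
#'
#' One row per frame: `frame`, `posture`, then for each part in canonical
#' order the in-plane endpoint coordinates `<part>_x1, <part>_y1, <part>_x2,
#' <part>_y2` (7 parts x 4 values). Dot decimal separator always.
#'
#' @param skeletons List of [skeleton()]s.
#' @param path Output file.
#' @export
write_skeletons_csv <- function(skeletons, path) {
  rows <- lapply(seq_along(skeletons), function(i) {
    sk <- skeletons[[i]]
    vals <- unlist(lapply(PART_NAMES, function(p) {
      if (p %in% names(sk$segments)) {
        s <- sk$segments[[p]]
        c(s[1, 1], s[1, 2], s[2, 1], s[2, 2])
      } else c(0, 0, 0, 0)
    }))
    c(list(frame = i - 1L, posture = sk$posture), as.list(vals))
  })
  cols <- unlist(lapply(PART_NAMES, function(p)
    paste0(p, c("_x1", "_y1", "_x2", "_y2"))))
  df <- do.call(rbind.data.frame, rows)
  names(df) <- c("frame", "posture", cols)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_skeletons_csv
#' @export
read_skeletons_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    segs <- lapply(PART_NAMES, function(p) {
      rbind(c(df[i, paste0(p, "_x1")], df[i, paste0(p, "_y1")]),
            c(df[i, paste0(p, "_x2")], df[i, paste0(p, "_y2")]))
    })
    names(segs) <- PART_NAMES
    skeleton(segs, df$posture[i])
  })
}
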