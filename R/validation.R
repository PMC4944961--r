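# Evaluation surface: percentage of correctly estimated body parts (PCP),
# per-frame posture confusion matrix, and rank-correlation agreement between
# automated and manual per-clip behaviour durations.

#' Percentage of correctly estimated body parts
#'
#' A part is correct when both predicted endpoints lie within
#' `alpha * (GT part length)` of the matching ground-truth endpoints (the
#' endpoint correspondence minimising the summed distance is used, since
#' segments are stored with arbitrary endpoint order). Parts with zero
#' ground-truth length are excluded. Per-part fractions average over
#' frames; the overall score averages parts within each frame, then over
#' frames (the per-part view is also exposed).
#'
#' @param predicted,gt Single [skeleton()]s or lists of them (same length).
#' @param alpha Threshold as a fraction of the part length (default 0.5,
#'   the usual convention for pose estimation).
#' @return Object of class `ks_pcp`: `per_part` (named fractions),
#'   `per_frame`, `overall` (mean of per-frame values), `overall_by_part`,
#'   `alpha`, `n_frames`.
#' @export
pcp <- function(predicted, gt, alpha = 0.5) {
  if (inherits(predicted, "ks_skeleton")) predicted <- list(predicted)
  if (inherits(gt, "ks_skeleton")) gt <- list(gt)
  if (length(predicted) != length(gt))
    stop_invalid("invalid input: prediction/GT length mismatch")
  part_hits <- setNames(rep(0, length(PART_NAMES)), PART_NAMES)
  part_n <- part_hits
  per_frame <- numeric(length(gt))
  for (f in seq_along(gt)) {
    pg <- gt[[f]]$segments
    pp <- predicted[[f]]$segments
    evaluated <- names(pg)[vapply(pg, function(s) segment_length(s) > 1e-9,
                                  TRUE)]
    if (!all(evaluated %in% names(pp)))
      stop_invalid("invalid input: predicted skeleton misses part(s) ",
                   paste(setdiff(evaluated, names(pp)), collapse = ", "))
    if (length(evaluated) == 0) { per_frame[f] <- NA; next }
    ok <- vapply(evaluated, function(p)
      part_correct(pp[[p]], pg[[p]], alpha), TRUE)
    part_hits[evaluated] <- part_hits[evaluated] + ok
    part_n[evaluated] <- part_n[evaluated] + 1
    per_frame[f] <- mean(ok)
  }
  keep <- part_n > 0
  structure(list(per_part = part_hits[keep] / part_n[keep],
                 per_frame = per_frame,
                 overall = mean(per_frame, na.rm = TRUE),
                 overall_by_part = mean(part_hits[keep] / part_n[keep]),
                 alpha = alpha, n_frames = length(gt)),
            class = "ks_pcp")
}

part_correct <- function(pred_seg, gt_seg, alpha) {
  d <- min(ncol(pred_seg), ncol(gt_seg))
  p1 <- pred_seg[1, 1:d]; p2 <- pred_seg[2, 1:d]
  g1 <- gt_seg[1, 1:d]; g2 <- gt_seg[2, 1:d]
  len <- vnorm(g2 - g1)
  direct <- c(vnorm(p1 - g1), vnorm(p2 - g2))
  flipped <- c(vnorm(p1 - g2), vnorm(p2 - g1))
  best <- if (sum(direct) <= sum(flipped)) direct else flipped
  all(best <= alpha * len)
}

#' Posture confusion matrix
#'
#' 4x4 counts with predicted classes in rows and ground truth in columns
#' (stand, locomotion, sit, lie), plus per-cell percentages of the column
#' total.
#'
#' @param pred_labels,gt_labels Equal-length character vectors.
#' @return Object of class `ks_confusion`: `counts`, `percent` (columns sum
#'   to 100 where the column is non-empty), `n`.
#' @export
confusion <- function(pred_labels, gt_labels) {
  if (length(pred_labels) != length(gt_labels))
    stop_invalid("invalid input: label vectors differ in length")
  counts <- table(factor(pred_labels, levels = POSTURE_LEVELS),
                  factor(gt_labels, levels = POSTURE_LEVELS))
  counts <- matrix(as.integer(counts), 4, 4,
                   dimnames = list(predicted = POSTURE_LEVELS,
                                   gt = POSTURE_LEVELS))
  cs <- colSums(counts)
  percent <- sweep(counts, 2, pmax(cs, 1), `/`) * 100
  structure(list(counts = counts, percent = percent,
                 n = length(gt_labels)),
            class = "ks_confusion")
}

# Spearman rank correlation with average ranks for ties.
spearman_rho <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# All permutations of seq_len(n) as an n! x n matrix (n <= 8).
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

spearman_p <- function(x, y, rho) {
  n <- length(x)
  if (is.na(rho)) return(NA_real_)
  if (n <= 8) {
    perms <- permutations_of(n)
    rhos <- apply(perms, 1, function(p) spearman_rho(x, y[p]))
    mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    t <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    2 * pt(-abs(t), n - 2)
  }
}

#' Agreement between automated and manual scoring
#'
#' Spearman's rho per behaviour label across clips, between the durations
#' scored automatically and the ground-truth annotations. Two-sided
#' p-values come from the exact permutation distribution for up to 8 clips
#' and the t approximation beyond. A constant duration vector leaves rho
#' undefined (`NA`).
#'
#' @param auto_durations,gt_durations Clips x labels matrices or data
#'   frames of per-clip durations (seconds); column names are the labels.
#' @return Object of class `ks_agreement`: `table` (label, rho, p_value),
#'   `n_clips`, plus `per_clip` carrying both duration sets for bar-plot
#'   style summaries.
#' @export
agreement <- function(auto_durations, gt_durations) {
  A <- as.matrix(auto_durations); G <- as.matrix(gt_durations)
  if (!all(dim(A) == dim(G)))
    stop_invalid("invalid input: duration tables differ in shape")
  if (nrow(A) < 3) stop_invalid("invalid input: need at least 3 clips")
  labels <- colnames(A) %||% paste0("label", seq_len(ncol(A)))
  tab <- do.call(rbind, lapply(seq_along(labels), function(j) {
    rho <- spearman_rho(A[, j], G[, j])
    data.frame(label = labels[j], rho = rho,
               p_value = spearman_p(A[, j], G[, j], rho))
  }))
  structure(list(table = tab, n_clips = nrow(A),
                 per_clip = list(auto = A, gt = G)),
            class = "ks_agreement")
}
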