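# PCP, confusion matrix and Spearman agreement, each against an
# independent brute-force computation.

test_that("pcp is exact on identical skeletons and at the threshold", {
  sk <- ks_demo_skeleton("stand")
  expect_equal(pcp(sk, sk)$overall, 1)
  # every endpoint displaced by 0.51 x part length -> 0% at alpha = 0.5
  segs <- lapply(sk$segments, function(s) {
    len <- sqrt(sum((s[2, ] - s[1, ])^2))
    s + 0.51 * len
  })
  off <- skeleton(segs, "stand")
  p <- pcp(off, sk, alpha = 0.5)
  expect_equal(p$overall, 0)
  # just inside the threshold counts
  segs2 <- lapply(sk$segments, function(s) {
    len <- sqrt(sum((s[2, ] - s[1, ])^2))
    s + 0.49 * len / sqrt(3)
  })
  expect_equal(pcp(skeleton(segs2, "stand"), sk)$overall, 1)
})

test_that("pcp agrees with a brute-force per-part loop on random skeletons", {
  set.seed(41)
  for (rep in 1:20) {
    gt <- ks_random_skeleton()
    pred <- ks_random_skeleton()
    alpha <- runif(1, 0.2, 0.8)
    res <- pcp(pred, gt, alpha)
    manual <- vapply(names(gt$segments), function(pn) {
      g <- gt$segments[[pn]]; pr <- pred$segments[[pn]]
      len <- sqrt(sum((g[2, ] - g[1, ])^2))
      d11 <- sqrt(sum((pr[1, ] - g[1, ])^2))
      d22 <- sqrt(sum((pr[2, ] - g[2, ])^2))
      d12 <- sqrt(sum((pr[1, ] - g[2, ])^2))
      d21 <- sqrt(sum((pr[2, ] - g[1, ])^2))
      if (d11 + d22 <= d12 + d21) d11 <= alpha * len && d22 <= alpha * len
      else d12 <= alpha * len && d21 <= alpha * len
    }, TRUE)
    expect_equal(unname(res$per_part[names(manual)]), unname(manual) * 1)
  }
})

test_that("pcp is monotone non-increasing under growing endpoint noise", {
  set.seed(43)
  gt <- lapply(1:15, function(i) ks_demo_skeleton("stand", heading = i / 3))
  vals <- vapply(c(0, 0.05, 0.12, 0.25, 0.5), function(sd_) {
    pred <- lapply(gt, function(sk) {
      segs <- lapply(sk$segments, function(s)
        s + matrix(rnorm(6, 0, sd_), 2, 3))
      skeleton(segs, sk$posture)
    })
    pcp(pred, gt)$overall
  }, 0)
  expect_true(all(diff(vals) <= 1e-9))
})

test_that("confusion matrix counts, normalises and validates", {
  gt <- c("stand", "stand", "sit", "lie", "locomotion", "sit")
  pred <- gt
  cm <- confusion(pred, gt)
  expect_equal(sum(diag(cm$counts)), 6)
  expect_equal(sum(cm$counts), 6)
  # constant prediction: one dense row
  cm2 <- confusion(rep("lie", 6), gt)
  expect_equal(sum(cm2$counts["lie", ]), 6)
  expect_equal(sum(cm2$counts[c("stand", "sit", "locomotion"), ]), 0)
  # column percentages sum to 100 for non-empty columns
  nonzero <- colSums(cm2$counts) > 0
  expect_true(all(abs(colSums(cm2$percent)[nonzero] - 100) < 1e-9))
  expect_error(confusion(c("sit"), gt), "length")
  # counts sum to n for random label pairs
  set.seed(47)
  for (rep in 1:10) {
    n <- sample(5:200, 1)
    a <- sample(c("stand", "locomotion", "sit", "lie"), n, TRUE)
    b <- sample(c("stand", "locomotion", "sit", "lie"), n, TRUE)
    expect_equal(sum(confusion(a, b)$counts), n)
  }
})

test_that("spearman agreement matches the brute-force rank formula", {
  set.seed(53)
  # 13 clips (the usual validation clip count), 4 labels
  for (rep in 1:10) {
    A <- matrix(runif(13 * 4, 0, 300), 13, 4,
                dimnames = list(NULL, c("stand", "locomotion", "sit", "lie")))
    G <- matrix(runif(13 * 4, 0, 300), 13, 4,
                dimnames = list(NULL, colnames(A)))
    ag <- agreement(A, G)
    for (j in 1:4) {
      rx <- rank(A[, j]); ry <- rank(G[, j])
      rho_manual <- sum((rx - mean(rx)) * (ry - mean(ry))) /
        sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
      expect_equal(ag$table$rho[j], rho_manual, tolerance = 1e-12)
      # t-approximation p-value recomputed independently (n = 13 > 8)
      tv <- rho_manual * sqrt(11 / (1 - rho_manual^2))
      expect_equal(ag$table$p_value[j], 2 * pt(-abs(tv), 11),
                   tolerance = 1e-12)
    }
  }
  # identical / reversed vectors
  x <- matrix(1:5, 5, 1); y <- matrix(5:1, 5, 1)
  expect_equal(agreement(x, x)$table$rho, 1)
  expect_equal(agreement(x, y)$table$rho, -1)
  # exact permutation p for small n: perfect agreement of 4 clips has
  # p = 2 / 4! (both extreme orderings)
  expect_equal(agreement(matrix(1:4, 4, 1), matrix(1:4, 4, 1))$table$p_value,
               2 / factorial(4))
  # constant vector: rho undefined
  expect_true(is.na(agreement(matrix(rep(1, 5), 5, 1),
                              matrix(1:5, 5, 1))$table$rho))
})
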