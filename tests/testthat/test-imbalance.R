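test_that("knnRadius and knnDensity match direct Eq.-5 evaluation", {
  x <- matrix(c(0, 0,
                3, 4,
                6, 8,
                1, 0,
                0, 2), ncol = 2L, byrow = TRUE)
  ## distances from row 1: 5, 10, 1, 2
  expect_equal(knnRadius(x, 1L, 1L), 1)
  expect_equal(knnRadius(x, 1L, 2L), 2)
  expect_equal(knnRadius(x, 1L, 3L), 5)
  expect_error(knnRadius(x, 1L, 5L), "smaller than the group size")

  ## direct density: f = g / (L * V_m(r)), V_2(r) = pi r^2
  k <- 2L
  r <- 2
  g <- 2                      # rows 4 and 5 inside radius 2
  direct <- g / (nrow(x) * pi * r^2)
  expect_equal(knnDensity(x, 1L, k), direct)
  expect_equal(knnDensity(x, 1L, k, log = TRUE), log(direct))
  ## L defaults to the group size but can be the global negative count
  expect_equal(knnDensity(x, 1L, k, L = 100), g / (100 * pi * r^2))
})

test_that("log-space density survives high dimension", {
  set.seed(2)
  m <- 700L
  x <- matrix(rnorm(20 * m), ncol = m)
  lf <- knnDensity(x, 1L, 5L, log = TRUE)
  expect_true(is.finite(lf))
  ## the naive volume is not representable at this dimension: the
  ## gamma term and r^m both overflow double precision
  expect_false(is.finite(pi^(m / 2) / gamma(m / 2 + 1) *
                           knnRadius(x, 1L, 5L)^m))
})

test_that("stage1Select reproduces the hand-simulated 1-D trace", {
  ## group of 6 points in two tight clusters, k = 2:
  ## densest point of each cluster (the middle one) is kept and its
  ## k-NN sphere deletes the rest of the cluster
  x <- matrix(c(0, 0.1, 0.2, 5, 5.1, 5.2), ncol = 1L)
  sel <- stage1Select(x, groups = rep("g", 6L), k = 2L)
  expect_identical(which(sel), c(2L, 5L))
  expect_identical(attr(sel, "degenerate_groups"), 0L)
})

test_that("stage1Select keeps small groups whole", {
  x <- matrix(rnorm(8), ncol = 2L)
  sel <- stage1Select(x, groups = rep("g", 4L), k = 11L)
  expect_true(all(sel))
  expect_identical(attr(sel, "degenerate_groups"), 1L)
})

test_that("stage1Select matches an independent reimplementation", {
  ## oracle: direct translation of the published procedure
  oracle <- function(x, groups, k) {
    keep <- logical(nrow(x))
    for (g in unique(groups)) {
      idx <- which(groups == g)
      if (length(idx) <= k) { keep[idx] <- TRUE; next }
      rem <- idx
      while (length(rem) > 0L) {
        if (length(rem) <= k) { keep[rem] <- TRUE; break }
        stats <- t(vapply(rem, function(i) {
          d <- sqrt(colSums((t(x[setdiff(rem, i), , drop = FALSE]) -
                             x[i, ])^2))
          r <- sort(d)[k]
          c(r = r, g = sum(d <= r))
        }, numeric(2L)))
        logf <- ifelse(stats[, 1L] == 0, Inf,
                       log(stats[, 2L]) -
                         ((ncol(x) / 2) * log(pi) -
                            lgamma(ncol(x) / 2 + 1) +
                            ncol(x) * log(stats[, 1L])))
        ord <- order(-logf, -stats[, 2L], rem)
        p <- ord[1L]
        keep[rem[p]] <- TRUE
        d <- sqrt(colSums((t(x[rem, , drop = FALSE]) - x[rem[p], ])^2))
        rem <- rem[!(d <= stats[p, 1L])]
      }
    }
    keep
  }
  set.seed(31)
  x <- matrix(rnorm(60 * 3), ncol = 3L)
  groups <- rep(c("a", "b"), each = 30L)
  got <- stage1Select(x, groups, k = 5L)
  expect_identical(as.logical(got), oracle(x, groups, 5L))
})

test_that("stage-1 coverage invariant: groups are represented", {
  set.seed(32)
  x <- matrix(rnorm(200 * 4), ncol = 4L)
  groups <- rep(letters[1:5], each = 40L)
  sel <- stage1Select(x, groups, k = 11L)
  for (g in letters[1:5]) expect_gt(sum(sel[groups == g]), 0L)
  ## condensation never selects everything in a dense oversized group
  dense <- matrix(rnorm(80 * 2, sd = 0.1), ncol = 2L)
  sdense <- stage1Select(dense, rep("d", 80L), k = 11L)
  expect_lt(sum(sdense), 80L)
})

test_that("predictionDeviation is the margin over the best positive", {
  expect_equal(predictionDeviation(0.5, c(-1, 0.2)), 0.3)
  expect_equal(predictionDeviation(-2, c(1)), -3)
  expect_error(predictionDeviation(1, numeric(0)), "positive score")
})

test_that("stage2Select adds misleading negatives until top-1 is real", {
  ## two groups in 2-D; positives at the top, a misleading negative
  ## close to them, easy negatives far away
  set.seed(33)
  x <- rbind(
    c(0, 1),    # g1 positive
    c(0, 0.9),  # g1 hard negative
    c(0, -1),   # g1 easy negative
    c(2, 1),    # g2 positive
    c(2, 0.8),  # g2 hard negative
    c(2, -1)    # g2 easy negative
  )
  labels <- c("real", "pseudo", "pseudo", "real", "pseudo", "pseudo")
  groups <- c("g1", "g1", "g1", "g2", "g2", "g2")
  trainer <- function(xx, ll) svmTrain(xx, ll, cost = 10, gamma = 1)
  s2 <- stage2Select(x, labels, groups, stage1Idx = c(3L, 6L), trainer,
                     maxIter = 10L)
  expect_true(all(s2$terminated))
  ## the final training set is a superset of positives + stage 1
  expect_true(all(c(1L, 3L, 4L, 6L) %in% s2$trainIdx))
  expect_lte(s2$iterations, 10L)
  ## audit rows track what was added when
  expect_true(all(s2$audit$row %in% s2$trainIdx))
  expect_true(all(s2$audit$sigma > 0))
})
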