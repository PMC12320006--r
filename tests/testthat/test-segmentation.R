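test_that("fitScore matches the literal volume-to-centroid computation", {
  set.seed(21)
  for (rep in 1:5) {
    X <- matrix(rnorm(15 * 20), 15, 20)
    vs <- VolumeSeries(X)
    nb <- sample(0:4, 1)
    b <- sort(sample(1:19, nb))
    expect_equal(fitScore(vs, b), naiveFitScore(X, b), tolerance = 1e-10)
  }
})

test_that("fitScore is 1 for perfect segmentations", {
  set.seed(22)
  P <- matrix(rnorm(20), 10, 2)
  vs <- VolumeSeries(P[, rep(1:2, c(3, 3))])
  expect_equal(fitScore(vs, 3), 1)
  const <- VolumeSeries(matrix(rnorm(10), 10, 6)[, rep(1, 6)])
  expect_equal(fitScore(const, integer(0)), 1)
})

test_that("the true single split beats every other split (exhaustive)", {
  set.seed(23)
  P <- matrix(rnorm(20), 10, 2)
  X <- P[, rep(1:2, c(5, 7))] + matrix(rnorm(10 * 12), 10, 12) / 5
  vs <- VolumeSeries(X)
  scores <- vapply(1:11, function(b) fitScore(vs, b), 0)
  expect_equal(which.max(scores), 5L)
})

test_that("zero-variance volumes contribute 0 with a warning", {
  set.seed(24)
  X <- matrix(rnorm(5 * 8), 5, 8)
  X[, 3] <- 2
  expect_warning(s <- fitScore(VolumeSeries(X), 4), "zero-variance")
  Xref <- X[, -3]
  expect_lt(s, 1)
})

test_that("greedy recovers noiseless boundaries and snapshots nest", {
  set.seed(25)
  P <- matrix(rnorm(10 * 3), 10, 3)
  vs <- VolumeSeries(P[, rep(1:3, c(4, 4, 4))])
  sg <- greedySegment(vs, kMax = 6)
  expect_equal(snapshotAt(sg, 3), c(4L, 8L))
  # single planted boundary at 3, T = 6: first iteration places exactly {3}
  P2 <- matrix(rnorm(16), 8, 2)
  vs2 <- VolumeSeries(P2[, rep(1:2, c(3, 3))])
  sg2 <- greedySegment(vs2, kMax = 3)
  expect_equal(snapshotAt(sg2, 2), 3L)
})

test_that("first greedy insertion matches exhaustive interval search", {
  set.seed(26)
  for (rep in 1:5) {
    T <- 12
    P <- matrix(rnorm(8 * 3), 8, 3)
    X <- P[, rep(1:3, c(4, 4, 4))] + matrix(rnorm(8 * T), 8, T) / 3
    vs <- VolumeSeries(X)
    sg <- greedySegment(vs, kMax = 4, finetune = 0)
    kFirst <- min(as.integer(names(sg@snapshots)))
    got <- snapshotAt(sg, kFirst)
    # brute force over all candidate intervals [i..j] of the single state
    best <- NULL; bestFit <- -Inf
    for (i in 1:T) for (j in i:T) {
      if (i == 1 && j == T) next
      b <- unique(c(if (i > 1) i - 1L, if (j < T) j))
      f <- fitScore(vs, sort(b))
      if (f > bestFit + 1e-8) { bestFit <- f; best <- sort(b) }
    }
    expect_equal(got, best)
  }
})

test_that("fit is non-decreasing over greedy iterations", {
  fix <- makePlantedSeries(T = 60, k = 5, V = 30, snr = 2, seed = 27,
                           nSubjects = 5)
  sg <- greedySegment(fix$series, kMax = 15)
  ks <- sort(as.integer(names(sg@snapshots)))
  fits <- vapply(ks, function(k) fitScore(fix$series, snapshotAt(sg, k)), 0)
  expect_true(all(diff(fits) >= -1e-8))
})

test_that("snapshots are nested up to one-volume finetuning shifts", {
  fix <- makePlantedSeries(T = 80, k = 6, V = 30, snr = 2, seed = 28,
                           nSubjects = 5)
  sg <- greedySegment(fix$series, kMax = 20)
  ks <- sort(as.integer(names(sg@snapshots)))
  for (idx in seq_along(ks)[-1]) {
    prev <- snapshotAt(sg, ks[idx - 1])
    cur <- snapshotAt(sg, ks[idx])
    # every earlier boundary survives within +/- 1 volume
    expect_true(all(vapply(prev, function(b) any(abs(cur - b) <= 1), TRUE)))
    expect_lte(length(cur) - length(prev), 2L)
  }
})

test_that("noisy parameter recovery finds most boundaries at the planted k", {
  rates <- vapply(1:5, function(sd) {
    fix <- makePlantedSeries(T = 120, k = 8, V = 50, snr = 2, seed = sd)
    matchRate(snapshotAt(greedySegment(fix$series, kMax = 8), 8),
              fix$boundaries)
  }, 0)
  expect_gte(mean(rates), 0.9)
})

test_that("selectK picks the planted count on noiseless data and the curve \
separates true from doubled k", {
  for (sd in c(29, 30, 31)) {
    fix <- makePlantedSeries(T = 80, k = 6, V = 40, snr = Inf, seed = sd,
                             nSubjects = 1)
    sg <- greedySegment(fix$series, kMax = 20)
    sel <- selectK(sg, fix$series)
    expect_equal(kSelected(sel), 6L)
    curve <- selectionCurve(sel)
    expect_gt(curve[["6"]], curve[["12"]])
    expect_equal(boundaries(sel), fix$boundaries)
  }
})

test_that("selectK completes on pure-noise series with a finite curve", {
  set.seed(30)
  for (rep in 1:5) {
    vs <- VolumeSeries(matrix(rnorm(20 * 40), 20, 40))
    sel <- selectK(greedySegment(vs, kMax = 10), vs)
    expect_true(kSelected(sel) %in% 2:10)
    expect_true(all(is.finite(selectionCurve(sel))))
  }
})

test_that("boundary strengths follow 1 minus the flanking-mean correlation", {
  # identical flanking state means -> 0
  p <- rnorm(6)
  vs <- VolumeSeries(cbind(p, p, p, p))
  expect_equal(boundaryStrengths(vs, 2), 0)
  # 2-voxel anticorrelated means -> 2
  vs2 <- VolumeSeries(cbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)))
  expect_equal(boundaryStrengths(vs2, 2), 2)
  # hand-checkable 3-voxel case, oracle = stats::cor
  vs3 <- VolumeSeries(cbind(c(3, 1, 2), c(3, 1, 2), c(1, 3, 2), c(1, 3, 2)))
  expect_equal(boundaryStrengths(vs3, 2),
               1 - stats::cor(c(3, 1, 2), c(1, 3, 2)))
  # zero-variance state mean -> error naming the boundary
  vs4 <- VolumeSeries(cbind(c(1, 1, 1), c(1, 1, 1), c(0, 1, 2), c(0, 1, 2)))
  expect_error(boundaryStrengths(vs4, 2), "boundary index 1")
})

test_that("strengths stay in [0, 2] over many random segmentations", {
  set.seed(31)
  for (rep in 1:200) {
    T <- sample(8:30, 1)
    vs <- VolumeSeries(matrix(rnorm(6 * T), 6, T))
    b <- sort(sample(1:(T - 1), sample(1:4, 1)))
    s <- boundaryStrengths(vs, b)
    expect_true(all(s >= 0 & s <= 2))
  }
})

test_that("timelines encode boundary positions and strengths invertibly", {
  fix <- makePlantedSeries(T = 40, k = 4, V = 20, snr = 5, seed = 32,
                           nSubjects = 3)
  sg <- segmentationAtK(greedySegment(fix$series, kMax = 4), fix$series, 4)
  tl <- toTimeline(sg)
  v <- timelineValues(tl)
  expect_length(v, 40)
  expect_equal(boundaries(tl), boundaries(sg))
  expect_equal(strengths(tl), strengths(sg))
  expect_equal(sum(v > 0), length(boundaries(sg)))
  expect_equal(v[boundaries(sg) + 1L], strengths(sg))
  # explicit placement: boundary 3 with strength s, T = 6 -> position 4
  sg2 <- new("StateSegmentation", nTimepoints = 6L, boundaries = 3L,
             strengths = 1.2, snapshots = list(), kSelected = NA_integer_,
             selectionCurve = numeric(0), trSeconds = 2, runId = "r")
  expect_equal(timelineValues(toTimeline(sg2)), c(0, 0, 0, 1.2, 0, 0))
})

test_that("degenerate segmentation inputs are rejected", {
  vs <- VolumeSeries(matrix(rnorm(9), 3, 3))
  expect_error(greedySegment(vs), "at least 4 volumes")
  vs2 <- VolumeSeries(matrix(rnorm(40), 4, 10))
  expect_error(greedySegment(vs2, kMax = 6), "kMax")
  expect_error(fitScore(vs2, c(5, 3)), "strictly increasing")
  expect_error(boundaryStrengths(vs2, integer(0)), "at least one boundary")
})
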