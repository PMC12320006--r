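test_that("partial correlation matches the first-order closed form", {
  expect_equal(partialCorrelation(1:10, 1:10), 1)
  set.seed(51)
  errs <- vapply(1:100, function(i) {
    x <- rnorm(30); y <- rnorm(30); z <- rnorm(30)
    rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
    closed <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    abs(partialCorrelation(x, y, cbind(z)) - closed)
  }, 0)
  expect_lt(max(errs), 1e-10)
  # y as its own covariate leaves a constant residual
  y <- rnorm(20)
  expect_error(partialCorrelation(rnorm(20), y, cbind(y)), "constant")
  # with no covariates: plain Pearson
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(partialCorrelation(x, y), cor(x, y))
})

test_that("rank-deficient covariates warn but still residualize", {
  set.seed(52)
  z <- rnorm(30)
  x <- z + rnorm(30); y <- z + rnorm(30)
  expect_warning(r1 <- partialCorrelation(x, y, cbind(z, 2 * z)), "rank")
  r2 <- partialCorrelation(x, y, cbind(z))
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("state shuffles preserve counts, durations and strengths", {
  sg <- new("StateSegmentation", nTimepoints = 10L, boundaries = c(3L, 6L),
            strengths = c(0.8, 1.1), snapshots = list(),
            kSelected = NA_integer_, selectionCurve = numeric(0),
            trSeconds = 2, runId = "r1")
  seen <- character(0)
  for (s in 1:60) {
    tl <- permuteStates(sg, seed = s)
    v <- timelineValues(tl)
    expect_equal(sum(v > 0), 2)
    b <- boundaries(tl)
    durs <- diff(c(0, b, 10))
    expect_equal(sort(durs), c(3, 3, 4))
    expect_equal(sort(v[v > 0]), c(0.8, 1.1))
    seen <- c(seen, paste(b, collapse = ","))
  }
  # the (3rd, 1st, 2nd) ordering yields boundaries {4, 7}
  expect_true("4,7" %in% seen)
  # identity ordering reproduces the original timeline
  expect_true("3,6" %in% seen)
  idSeed <- which(vapply(1:60, function(s) {
    identical(boundaries(permuteStates(sg, seed = s)), c(3L, 6L))
  }, TRUE))[1]
  expect_equal(timelineValues(permuteStates(sg, seed = idSeed)),
               c(0, 0, 0, 0.8, 0, 0, 1.1, 0, 0, 0))
  sg1 <- new("StateSegmentation", nTimepoints = 10L, boundaries = integer(0),
             strengths = numeric(0), snapshots = list(),
             kSelected = NA_integer_, selectionCurve = numeric(0),
             trSeconds = 2, runId = "r1")
  expect_error(permuteStates(sg1), "at least 2 states")
})

test_that("fully coupled annotations at high snr give p = 0", {
  fix <- makePlantedSeries(T = 100, k = 8, V = 40, snr = 5, seed = 53,
                           nSubjects = 5)
  sg <- segmentationAtK(greedySegment(fix$series, kMax = 8), fix$series, 8)
  src <- simulateAnnotationSources(fix$truth, distractorRate = 0,
                                   sourceKinds = c(events = "times"))
  ann <- shiftAndBin(src$events[[1]]$times, 2, 100, category = "events")
  res <- permutationTest(sg, ann, nPerm = 500, seed = 1)
  expect_equal(pOneTailed(res), 0)
  expect_gt(rObserved(res), max(nullSample(res)))
})

test_that("permutation tests are deterministic under a fixed seed", {
  fix <- makePlantedSeries(T = 60, k = 4, V = 20, snr = 2, seed = 54,
                           nSubjects = 3)
  sg <- segmentationAtK(greedySegment(fix$series, kMax = 4), fix$series, 4)
  ann <- shiftAndBin(fix$boundaries * 2 - 4.5, 2, 60, category = "events")
  r1 <- permutationTest(sg, ann, nPerm = 200, seed = 99)
  r2 <- permutationTest(sg, ann, nPerm = 200, seed = 99)
  expect_identical(nullSample(r1), nullSample(r2))
  expect_identical(pOneTailed(r1), pOneTailed(r2))
  expect_error(permutationTest(sg, ann, nPerm = 0), "nPerm")
})

test_that("the add-one p-value variant never returns 0", {
  fix <- makePlantedSeries(T = 60, k = 5, V = 20, snr = 5, seed = 55,
                           nSubjects = 3)
  sg <- segmentationAtK(greedySegment(fix$series, kMax = 5), fix$series, 5)
  ann <- shiftAndBin(fix$boundaries * 2 - 4.5, 2, 60, category = "events")
  res <- permutationTest(sg, ann, nPerm = 100, seed = 7,
                         addOneCorrection = TRUE)
  cnt <- sum(nullSample(res) >= rObserved(res))
  expect_equal(pOneTailed(res), (cnt + 1) / 101)
  expect_gt(pOneTailed(res), 0)
})

test_that("multi-run tests permute within runs and concatenate", {
  fixes <- lapply(1:2, function(r) makePlantedSeries(T = 50, k = 4, V = 20,
                                                     snr = 5, seed = 60 + r,
                                                     nSubjects = 3))
  segs <- lapply(fixes, function(f) {
    segmentationAtK(greedySegment(f$series, kMax = 4), f$series, 4)
  })
  anns <- lapply(fixes, function(f) {
    shiftAndBin(f$boundaries * 2 - 4.5, 2, 50, category = "events")
  })
  res <- permutationTest(segs, concatenateRuns(anns), nPerm = 300, seed = 3)
  expect_lt(pOneTailed(res), 0.05)
  # mismatched grid is rejected
  expect_error(permutationTest(segs, anns[[1]], nPerm = 10), "covers")
})

test_that("bonferroni multiplies and caps", {
  r <- new("AlignmentResult", category = "events", rObserved = 0.2,
           nullSample = rep(0, 100), pOneTailed = 0.010,
           nPermutations = 100L, pCorrected = NA_real_,
           correctionFactor = NA_integer_, seed = NA_integer_)
  expect_equal(pCorrected(bonferroni(r, 6)), 0.06)
  r@pOneTailed <- 0.3
  expect_equal(pCorrected(bonferroni(r, 6)), 1)
  expect_equal(pCorrected(bonferroni(r, 1)), 0.3)
  expect_error(bonferroni(r, 0), "nTests")
})

test_that("the default ledger matches the covariate table", {
  led <- defaultCovariateLedger()
  alex <- paste0("alexnet_l", 1:8)
  locCov <- c("low_level_visual", alex, "shots", "mfcc", "speech", "events")
  expect_setequal(covariatesFor(led, "small_locations"), locCov)
  expect_setequal(covariatesFor(led, "large_locations"), locCov)
  expect_setequal(covariatesFor(led, "low_level_visual"),
                  c("small_locations", "large_locations", "mfcc", "speech",
                    "events"))
  expect_setequal(covariatesFor(led, "speech"),
                  c("low_level_visual", alex, "shots", "small_locations",
                    "large_locations", "mfcc", "events"))
  expect_setequal(covariatesFor(led, "events"),
                  c("low_level_visual", alex, "shots", "small_locations",
                    "large_locations", "mfcc", "speech"))
  # shots are covariates only
  expect_false("shots" %in% names(led@map))
  expect_error(covariatesFor(led, "shots"), "not an annotation of interest")
})

test_that("ledger validity rejects self- and same-group covariates", {
  grp <- c(a = "g1", b = "g1", c = "g2")
  expect_error(covariateLedger(list(a = c("a", "c")), grp), "itself")
  expect_error(covariateLedger(list(a = c("b", "c")), grp), "same-group")
  led <- covariateLedger(list(a = "c", c = c("a", "b")), grp)
  expect_s4_class(led, "CovariateLedger")
})

test_that("ledger covariates are applied in the permutation test", {
  # annotation = covariate + noise: correcting for the covariate must lower
  # the observed partial correlation relative to the uncorrected one
  fix <- makePlantedSeries(T = 100, k = 8, V = 40, snr = 5, seed = 56,
                           nSubjects = 3)
  sg <- segmentationAtK(greedySegment(fix$series, kMax = 8), fix$series, 8)
  ann <- shiftAndBin(fix$boundaries * 2 - 4.5, 2, 100, category = "events")
  covTl <- shiftAndBin(fix$boundaries[1:4] * 2 - 4.5, 2, 100,
                       category = "mfcc", group = "low_level_audio")
  led <- defaultCovariateLedger(c("events", "mfcc"))
  rCorr <- permutationTest(sg, ann, ledger = led,
                           covariateTimelines = list(mfcc = covTl),
                           nPerm = 50, seed = 2)
  rPlain <- permutationTest(sg, ann, nPerm = 50, seed = 2)
  expect_lt(rObserved(rCorr), rObserved(rPlain))
})
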