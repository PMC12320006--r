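test_that("hash changes are normalized Hamming distances", {
  expect_equal(hashChangeTimeline(rbind(c(1, 0, 1), c(1, 0, 1))), c(0, 0))
  h <- rbind(rep(1, 64), rep(0, 64))
  expect_equal(hashChangeTimeline(h), c(0, 1))
  expect_equal(hashChangeTimeline(rbind(c(1, 1, 0, 0), c(1, 0, 1, 0))),
               c(0, 0.5))
  expect_error(hashChangeTimeline(list(c(1, 0), c(1, 0, 1))), "length")
})

test_that("cosine changes match hand computation and scale to unit max", {
  expect_equal(cosineChangeTimeline(cbind(c(1, 2), c(1, 2)), scale = FALSE),
               c(0, 0))
  expect_equal(cosineChangeTimeline(cbind(c(1, 0), c(0, 1)), scale = FALSE),
               c(0, 1))
  expect_equal(cosineChangeTimeline(cbind(c(1, 0), c(1, 1)), scale = FALSE),
               c(0, 1 - 1 / sqrt(2)))
  set.seed(41)
  F <- matrix(abs(rnorm(5 * 30)) + 0.1, 5, 30)
  expect_equal(max(cosineChangeTimeline(F)), 1)
  expect_error(cosineChangeTimeline(cbind(c(1, 1), c(0, 0))), "zero vector")
})

test_that("MFCC changes average within volumes then take cosine distances", {
  # constant coefficients -> all-zero change series
  co <- matrix(1:3, 3, 8)
  expect_equal(mfccChangeTimeline(co, seq(0, 3.5, 0.5), 2, 2,
                                  delaySeconds = 0),
               c(0, 0))
  # two volumes with orthogonal means -> [0, 1] after scaling
  co2 <- cbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  expect_equal(mfccChangeTimeline(co2, c(0, 1, 2, 3), 2, 2, delaySeconds = 0),
               c(0, 1))
  # 3-volume toy against a direct hand computation
  m1 <- c(1, 0); m2 <- c(1, 1); m3 <- c(0, 1)
  co3 <- cbind(m1, m1, m2, m2, m3, m3)
  raw <- c(0,
           1 - sum(m1 * m2) / sqrt(sum(m1^2) * sum(m2^2)),
           1 - sum(m2 * m3) / sqrt(sum(m2^2) * sum(m3^2)))
  expect_equal(mfccChangeTimeline(co3, c(0, .5, 1, 1.5, 2, 2.5), 1, 3,
                                  delaySeconds = 0),
               raw / max(raw))
  expect_error(mfccChangeTimeline(co2, c(0, 0.1, 0.2, 0.3), 2, 2,
                                  delaySeconds = 0),
               "volume 2")
})

test_that("speech changes mark period starts per the silence rule", {
  w <- data.frame(onset_s = c(1, 1.5, 8), duration_s = c(0.3, 0.4, 0.5))
  ct <- speechChangeTimeline(w, 2, 20)
  expect_equal(as.numeric(ct), c(1.0, 1.9, 8.0, 8.5))
  expect_equal(attr(ct, "type"),
               c("speech_on", "silence_on", "speech_on", "silence_on"))
  expect_length(speechChangeTimeline(data.frame(onset_s = numeric(0),
                                                duration_s = numeric(0)),
                                     2, 20), 0)
  # a word starting at time 0: its onset is not a change
  w0 <- data.frame(onset_s = 0, duration_s = 1)
  ct0 <- speechChangeTimeline(w0, 2, 20)
  expect_equal(as.numeric(ct0), 1)
  expect_equal(attr(ct0, "type"), "silence_on")
})

test_that("speech change types always alternate", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(1:15, 1)
    on <- sort(runif(n, 0, 90))
    w <- data.frame(onset_s = on, duration_s = runif(n, 0.1, 3))
    w$duration_s <- pmin(w$duration_s, 100 - w$onset_s)
    ct <- speechChangeTimeline(w, 2, 100)
    types <- attr(ct, "type")
    if (length(types) > 1) {
      expect_true(all(types[-1] != types[-length(types)]))
    }
  }
})

test_that("event boundaries require enough distinct subjects per cluster", {
  pr <- data.frame(subject = c(1:6, 7:9),
                   press_time_s = c(30 + c(-.2, -.1, 0, .1, .2, .15),
                                    60 + c(-.1, 0, .1)))
  eb <- eventBoundaries(pr)
  expect_length(eb, 1)
  expect_equal(eb, mean(30 + c(-.2, -.1, 0, .1, .2, .15)) - 0.9)
  # one subject pressing 6 times counts once
  pr2 <- data.frame(subject = rep(1, 6), press_time_s = 30 + (0:5) / 10)
  expect_length(eventBoundaries(pr2), 0)
  expect_error(eventBoundaries(pr, clusterWindowSeconds = 0), "positive")
})

test_that("event-boundary count is non-increasing in minSubjects", {
  set.seed(43)
  for (rep in 1:10) {
    pr <- data.frame(subject = sample(1:16, 60, replace = TRUE),
                     press_time_s = sort(runif(60, 0, 300)))
    counts <- vapply(1:8, function(ms) {
      length(eventBoundaries(pr, minSubjects = ms))
    }, 0L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("shiftAndBin places changes in the right volume windows", {
  tl <- shiftAndBin(1.0, trSeconds = 2, nVolumes = 6, category = "events")
  expect_equal(timelineValues(tl), c(0, 0, 1, 0, 0, 0))
  expect_equal(timelineValues(shiftAndBin(numeric(0), 2, 4,
                                          category = "events")),
               rep(0, 4))
  # two changes in one volume stay a binary 1
  tl2 <- shiftAndBin(c(1.0, 1.2), 2, 6, category = "events")
  expect_equal(sum(timelineValues(tl2)), 1)
  # delay 0, TR 1: identity on integer change times
  times <- c(2, 5, 9)
  tl3 <- shiftAndBin(times, 1, 12, delaySeconds = 0, category = "events")
  expect_equal(which(timelineValues(tl3) == 1) - 1L, times)
  # shifted times beyond the run are dropped
  tl4 <- shiftAndBin(c(1, 50), 2, 6, category = "events")
  expect_equal(sum(timelineValues(tl4)), 1)
})

test_that("continuous binning averages frame values within windows", {
  vals <- c(0.2, 0.4, 0.6, 0.8)
  tl <- shiftAndBin(vals, 2, 3, delaySeconds = 0, kind = "continuous",
                    times = c(0, 1, 2, 3), category = "mfcc",
                    group = "low_level_audio")
  expect_equal(timelineValues(tl), c(0.3, 0.7, 0))
  tlMax <- shiftAndBin(vals, 2, 3, delaySeconds = 0, kind = "continuous",
                       times = c(0, 1, 2, 3), aggregator = "max",
                       category = "mfcc", group = "low_level_audio")
  expect_equal(timelineValues(tlMax), c(0.4, 0.8, 0))
})

test_that("run concatenation preserves values and records run lengths", {
  t1 <- AnnotationTimeline(c(0, 1, 0), "events", "conceptual", "binary", "r1")
  t2 <- AnnotationTimeline(c(1, 0, 0, 1), "events", "conceptual", "binary", "r2")
  cc <- concatenateRuns(list(t1, t2))
  expect_equal(nVolumes(cc), 7)
  expect_equal(timelineValues(cc), c(0, 1, 0, 1, 0, 0, 1))
  expect_equal(cc@runLengths, c(3L, 4L))
  t3 <- AnnotationTimeline(c(1, 0), "speech", "mid_level_audio", "binary")
  expect_error(concatenateRuns(list(t1, t3)), "categories")
})

test_that("scaled continuous categories peak at exactly 1 after concatenation", {
  set.seed(44)
  tls <- lapply(1:3, function(r) {
    AnnotationTimeline(runif(20) * 0.6, "mfcc", "low_level_audio",
                       "continuous", sprintf("r%d", r))
  })
  cc <- scaleToUnitMax(concatenateRuns(tls))
  expect_equal(max(timelineValues(cc)), 1)
})
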