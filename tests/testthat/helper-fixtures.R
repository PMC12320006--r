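# Shared fixtures and independent oracles.

# Group-averaged, z-scored series with planted states; returns the series
# and the planted boundaries.
makePlantedSeries <- function(T = 120, k = 8, V = 50, snr = 2, seed = 1,
                              nSubjects = 15) {
  gt <- simulateGroundTruth(T, k, V, coupling = c(events = 1), snr = snr,
                            nSubjects = nSubjects, seed = seed)
  g <- zscoreVolumeSeries(groupAverage(simulateRun(gt, 1)))
  list(series = g, boundaries = gt@boundaries[[1]], truth = gt)
}

# Independent fit oracle: literal mean of volume-to-state-centroid Pearson
# correlations, computed column by column with stats::cor.
naiveFitScore <- function(X, b) {
  T <- ncol(X)
  starts <- c(1L, b + 1L)
  ends <- c(b, T)
  vals <- numeric(T)
  for (s in seq_along(starts)) {
    idx <- starts[s]:ends[s]
    m <- rowMeans(X[, idx, drop = FALSE])
    for (t in idx) {
      vals[t] <- suppressWarnings(stats::cor(X[, t], m))
      if (is.na(vals[t])) vals[t] <- 0
    }
  }
  mean(vals)
}

# Quadratic-time Benjamini-Hochberg step-up reference.
referenceStepUp <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  imax <- 0L
  for (i in seq_len(m)) if (ps[i] <= i * alpha / m) imax <- i
  reject <- rep(FALSE, m)
  thr <- NA_real_
  if (imax > 0L) {
    thr <- ps[imax]
    reject <- p <= thr
  }
  list(reject = reject, highestSurvivingP = thr)
}

# fraction of planted boundaries with a recovered boundary within +/- tol
matchRate <- function(found, planted, tol = 1L) {
  mean(vapply(planted, function(b) any(abs(found - b) <= tol), TRUE))
}
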