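# Greedy state boundary search (states variant), fit scoring, data-driven
# selection of the state count, and boundary strengths.
#
# The fit criterion is the mean, over volumes, of the Pearson correlation
# between each volume's voxel pattern and the mean pattern of the state
# containing it.  All candidate evaluations reduce to O(1) lookups in 2D
# prefix sums of weighted Gram matrices: writing c_t for the voxel-centred
# pattern of volume t, u_t = c_t / ||c_t|| and w_t = ||c_t||, the summed
# correlation of the volumes of a contiguous segment I with the segment mean
# is Q(I) / sqrt(S(I)) with
#   Q(I) = sum_{t,s in I} w_s u_t'u_s,   S(I) = sum_{t,s in I} w_t w_s u_t'u_s,
# because centring commutes with averaging.  Single-volume segments come out
# as correlation 1 automatically (Q = w, S = w^2).

# Precompute the Gram machinery for a series.  Zero-variance volumes get
# weight 0 (their correlation with any mean pattern is undefined; they
# contribute 0 to the fit, with a warning).
.segPrep <- function(series) {
  X <- seriesData(series)
  T <- ncol(X)
  C <- X - matrix(colMeans(X), nrow(X), T, byrow = TRUE)
  w <- sqrt(colSums(C^2))
  zero <- w < .Machine$double.eps^0.5 * sqrt(nrow(X))
  if (any(zero)) {
    warnf("%d volume(s) have zero-variance patterns; they contribute 0 to the fit",
          sum(zero))
    w[zero] <- 0
  }
  U <- C
  nz <- which(!zero)
  U[, nz] <- sweep(C[, nz, drop = FALSE], 2, w[nz], "/")
  U[, zero] <- 0
  G <- crossprod(U)                       # T x T volume-pattern correlations
  M1 <- sweep(G, 2, w, "*")               # G[t,s] * w[s]
  M2 <- sweep(M1, 1, w, "*")              # w[t] * G[t,s] * w[s]
  pad <- function(M) {
    P <- apply(apply(M, 2, cumsum), 1, cumsum)  # transposed 2D prefix sum
    rbind(0, cbind(0, t(P)))
  }
  list(T = T, w = w, G = G, P1 = pad(M1), P2 = pad(M2))
}

# Summed volume-to-segment-mean correlation of segments [i..j] (1-based,
# inclusive), vectorised over i, j.  Empty segments (i > j) contribute 0.
.segContrib <- function(prep, i, j) {
  n <- max(length(i), length(j))
  i <- rep_len(as.integer(i), n)
  j <- rep_len(as.integer(j), n)
  out <- numeric(n)
  ok <- i <= j
  if (!any(ok)) return(out)
  i <- i[ok]; j <- j[ok]
  bs <- function(P) {
    P[cbind(j + 1L, j + 1L)] - P[cbind(i, j + 1L)] -
      P[cbind(j + 1L, i)] + P[cbind(i, i)]
  }
  Q <- bs(prep$P1)
  S <- pmax(bs(prep$P2), 0)
  v <- ifelse(S > 1e-12, Q / sqrt(S), 0)
  out[ok] <- v
  out
}

# Total fit (sum over states of segment contributions) for a boundary set.
.segFitSum <- function(prep, b) {
  starts <- c(1L, b + 1L)
  ends <- c(b, prep$T)
  sum(.segContrib(prep, starts, ends))
}

.checkBoundaries <- function(b, T) {
  b <- as.integer(b)
  if (length(b) && (any(b <= 0L) || any(b >= T) || any(diff(b) <= 0L))) {
    stopf("boundaries must be strictly increasing integers in (0, %d)", T)
  }
  b
}

#' Fit of a candidate segmentation
#'
#' The mean over volumes of the Pearson correlation between each volume's
#' voxel pattern and the mean pattern of the state containing it.  Higher is
#' better; single-volume states contribute correlation 1; zero-variance
#' volumes contribute 0 with a warning.
#'
#' @param series a [VolumeSeries-class].
#' @param boundaries strictly increasing integer boundary positions in
#'   `(0, T)` (boundary `b`: a new state starts at volume `b + 1`); empty for
#'   a single state spanning the run.
#' @return A single number in `[-1, 1]`.
#' @examples
#' x <- VolumeSeries(cbind(matrix(1:4, 4, 3), matrix(c(4, 1, 3, 2), 4, 3)))
#' fitScore(x, 3)   # perfect two-state split
#' @export
fitScore <- function(series, boundaries = integer(0)) {
  stopifnot(is(series, "VolumeSeries"))
  prep <- .segPrep(series)
  b <- .checkBoundaries(boundaries, prep$T)
  .segFitSum(prep, b) / prep$T
}

# One finetuning pass: visit boundaries left to right, shift each by -1/0/+1,
# keeping a shift only when it strictly improves the total fit.
.finetunePass <- function(prep, b) {
  T <- prep$T
  for (bi in seq_along(b)) {
    prev <- if (bi > 1L) b[bi - 1L] else 0L
    nxt <- if (bi < length(b)) b[bi + 1L] else T
    cur <- b[bi]
    cand <- c(cur - 1L, cur + 1L)
    cand <- cand[cand > prev & cand < nxt]
    if (!length(cand)) next
    base <- sum(.segContrib(prep, c(prev + 1L, cur + 1L), c(cur, nxt)))
    alt <- vapply(cand, function(nb) {
      sum(.segContrib(prep, c(prev + 1L, nb + 1L), c(nb, nxt)))
    }, 0)
    if (max(alt) > base + 1e-8) b[bi] <- cand[which.max(alt)]
  }
  b
}

#' Greedy state boundary search
#'
#' Segments a multivariate time series into temporally contiguous states by
#' greedy search.  Each iteration tries every contiguous interval strictly
#' inside an existing state as a candidate new state — contributing two new
#' boundaries when both interval edges are interior, or one when an edge
#' coincides with an existing state edge — and keeps the candidate that
#' maximizes [fitScore()].  After each iteration (when `finetune = 1`) every
#' boundary may shift by one volume if that strictly improves the fit.  The
#' boundary set reached at each state count is recorded as a snapshot, up to
#' `kMax` states.
#'
#' Exact ties between candidates are broken toward the earliest interval
#' (smallest start, then smallest end), making the search deterministic.
#'
#' @param series a [VolumeSeries-class] (at least 4 volumes).
#' @param kMax maximum number of states; default half the number of
#'   timepoints, the recommended setting.
#' @param finetune 1 to allow one-volume boundary shifts after each
#'   iteration (default), 0 to disable.
#' @return A [StateSegmentation-class] with `snapshots` populated and
#'   `boundaries` set to the snapshot at the largest reached state count;
#'   `kSelected` is unset until [selectK()].
#' @seealso [selectK()], [boundaryStrengths()], [toTimeline()]
#' @export
greedySegment <- function(series, kMax = NULL, finetune = 1) {
  stopifnot(is(series, "VolumeSeries"))
  T <- nVolumes(series)
  if (T < 4L) stopf("need at least 4 volumes to place a boundary (T = %d)", T)
  if (is.null(kMax)) kMax <- floor(T / 2)
  kMax <- as.integer(kMax)
  if (kMax < 2L || kMax > floor(T / 2)) {
    stopf("kMax must lie in [2, floor(T/2)] = [2, %d]", floor(T / 2))
  }
  if (!finetune %in% c(0, 1)) stopf("finetune must be 0 or 1")

  prep <- .segPrep(series)
  b <- integer(0)
  snapshots <- list()
  while (length(b) + 1L < kMax) {
    nStatesNow <- length(b) + 1L
    roomFor2 <- (kMax - nStatesNow) >= 2L
    starts <- c(1L, b + 1L)
    ends <- c(b, T)
    # evaluate every candidate interval in every splittable state, then pick
    # the earliest candidate whose gain is within tolerance of the maximum
    # (ties in exact arithmetic must not be decided by rounding dust)
    cand <- vector("list", length(starts))
    for (st in seq_along(starts)) {
      s <- starts[st]; e <- ends[st]
      if (e - s + 1L < 2L) next
      # candidate intervals [i..j] within [s..e], excluding the full state
      i <- unlist(lapply(s:e, function(ii) rep(ii, e - ii + 1L)))
      j <- unlist(lapply(s:e, function(ii) ii:e))
      keep <- !(i == s & j == e)
      i <- i[keep]; j <- j[keep]
      if (!roomFor2) {
        sel <- ((i > s) + (j < e)) == 1L
        i <- i[sel]; j <- j[sel]
        if (!length(i)) next
      }
      base <- .segContrib(prep, s, e)
      gain <- .segContrib(prep, s, i - 1L) + .segContrib(prep, i, j) +
        .segContrib(prep, j + 1L, e) - base
      cand[[st]] <- list(s = s, e = e, i = i, j = j, gain = gain)
    }
    cand <- cand[!vapply(cand, is.null, TRUE)]
    if (!length(cand)) break   # no splittable state remains
    gmax <- max(vapply(cand, function(cc) max(cc$gain), 0))
    tol <- 1e-8
    bestNew <- NULL
    for (cc in cand) {
      hit <- which(cc$gain >= gmax - tol)
      if (length(hit)) {
        wm <- hit[1]   # candidates are ordered by (i, j)
        nb <- integer(0)
        if (cc$i[wm] > cc$s) nb <- c(nb, cc$i[wm] - 1L)
        if (cc$j[wm] < cc$e) nb <- c(nb, cc$j[wm])
        bestNew <- nb
        break
      }
    }
    b <- sort(c(b, bestNew))
    if (finetune == 1) b <- .finetunePass(prep, b)
    snapshots[[as.character(length(b) + 1L)]] <- b
  }
  new("StateSegmentation", nTimepoints = T, boundaries = b,
      strengths = numeric(0), snapshots = snapshots,
      kSelected = NA_integer_, selectionCurve = numeric(0),
      trSeconds = trSeconds(series), runId = runId(series))
}

# Pooled two-sample t statistic (within minus between); +/-Inf when the
# pooled variance vanishes but the means differ, NaN when both are constant
# and equal.
.tStat <- function(xw, xb) {
  n1 <- length(xw); n2 <- length(xb)
  if (n1 < 1L || n2 < 1L || n1 + n2 < 3L) return(NaN)
  m1 <- mean(xw); m2 <- mean(xb)
  ss <- sum((xw - m1)^2) + sum((xb - m2)^2)
  sp <- sqrt(ss / (n1 + n2 - 2L))
  d <- m1 - m2
  if (sp == 0) return(if (d == 0) NaN else sign(d) * Inf)
  d / (sp * sqrt(1 / n1 + 1 / n2))
}

#' Select the number of states
#'
#' For every recorded snapshot, compares the Pearson correlations of volume-
#' pattern pairs lying within the same state against pairs lying in
#' temporally adjacent states with a pooled two-sample t-statistic, and picks
#' the state count that maximizes the statistic (maximal within-state
#' similarity, minimal between-state similarity).  Snapshots with no
#' within-state pair are skipped.
#'
#' @param segmentation a [StateSegmentation-class] from [greedySegment()].
#' @param series the [VolumeSeries-class] the segmentation was fitted on.
#' @return The segmentation with `kSelected` and `selectionCurve` filled in,
#'   `boundaries` set to the selected snapshot, and `strengths` computed.
#' @export
selectK <- function(segmentation, series) {
  stopifnot(is(segmentation, "StateSegmentation"), is(series, "VolumeSeries"))
  if (!length(segmentation@snapshots)) stopf("segmentation has no snapshots")
  T <- nVolumes(series)
  if (T != segmentation@nTimepoints) {
    stopf("series has %d volumes but segmentation expects %d", T,
          segmentation@nTimepoints)
  }
  prep <- .segPrep(series)
  G <- prep$G
  ut <- upper.tri(G)
  curve <- numeric(0)
  for (kc in names(segmentation@snapshots)) {
    b <- segmentation@snapshots[[kc]]
    z <- rep(seq_len(length(b) + 1L), diff(c(0L, b, T)))
    sameState <- outer(z, z, "==") & ut
    adjState <- abs(outer(z, z, "-")) == 1L & ut
    if (!any(sameState)) next
    curve[kc] <- .tStat(G[sameState], G[adjState])
  }
  if (!length(curve) || all(!is.finite(curve) & is.nan(curve))) {
    stopf("no snapshot admits the separation statistic")
  }
  curve[is.nan(curve)] <- -Inf
  kSel <- as.integer(names(curve)[which.max(curve)])
  segmentationAtK(segmentation, series, kSel, selectionCurve = curve)
}

#' Fix a segmentation at a given state count
#'
#' Returns the segmentation with `boundaries` set to the snapshot recorded at
#' `k` and strengths computed there.  Useful for analyses at a known state
#' count (e.g. a planted ground truth).
#'
#' @param segmentation a [StateSegmentation-class] with snapshots.
#' @param series the fitted [VolumeSeries-class].
#' @param k state count; a snapshot must exist at `k`.
#' @param selectionCurve optional curve to store alongside.
#' @return The updated [StateSegmentation-class].
#' @export
segmentationAtK <- function(segmentation, series, k,
                            selectionCurve = segmentation@selectionCurve) {
  b <- snapshotAt(segmentation, k)
  if (is.null(b)) stopf("no snapshot at k = %d (double-boundary iterations can skip counts)", k)
  segmentation@boundaries <- b
  segmentation@strengths <- boundaryStrengths(series, b)
  segmentation@kSelected <- as.integer(k)
  segmentation@selectionCurve <- selectionCurve
  validObject(segmentation)
  segmentation
}

#' Boundary strengths
#'
#' The strength of a boundary is 1 minus the Pearson correlation between the
#' mean voxel patterns of the two states that surround it, giving values in
#' `[0, 2]`: 0 for identical flanking patterns, 2 for perfectly
#' anticorrelated ones.
#'
#' @param series a [VolumeSeries-class].
#' @param boundaries strictly increasing boundary positions (at least one).
#' @return Numeric vector of strengths, one per boundary.
#' @export
boundaryStrengths <- function(series, boundaries) {
  stopifnot(is(series, "VolumeSeries"))
  X <- seriesData(series)
  T <- ncol(X)
  b <- .checkBoundaries(boundaries, T)
  if (!length(b)) stopf("at least one boundary is required")
  starts <- c(1L, b + 1L)
  ends <- c(b, T)
  means <- vapply(seq_along(starts), function(s) {
    rowMeans(X[, starts[s]:ends[s], drop = FALSE])
  }, numeric(nrow(X)))
  sds <- apply(means, 2, stats::sd)
  if (any(sds == 0)) {
    stopf("state mean pattern has zero variance at boundary index %d",
          which(sds == 0)[1])
  }
  out <- vapply(seq_along(b), function(s) {
    1 - stats::cor(means[, s], means[, s + 1L])
  }, 0)
  pmin(pmax(out, 0), 2)
}

#' Boundary timeline of a segmentation
#'
#' Expands a segmentation into a per-volume vector: 0 at volumes without a
#' boundary, and the boundary strength at each volume that opens a new state
#' (boundary `b` lands at vector position `b + 1`).
#'
#' @param segmentation a [StateSegmentation-class] with strengths computed
#'   (see [segmentationAtK()] or [selectK()]).
#' @return A [BoundaryTimeline-class].
#' @export
toTimeline <- function(segmentation) {
  stopifnot(is(segmentation, "StateSegmentation"))
  b <- segmentation@boundaries
  if (length(b) && !length(segmentation@strengths)) {
    stopf("strengths not computed; call selectK() or segmentationAtK() first")
  }
  v <- numeric(segmentation@nTimepoints)
  v[b + 1L] <- segmentation@strengths
  new("BoundaryTimeline", values = v, runId = segmentation@runId,
      runLengths = segmentation@nTimepoints)
}
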