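# Stimulus-change timelines: per-frame change series from perceptual hashes,
# feature vectors and MFCCs; speech on/offsets from word tables; consensus
# event boundaries from pooled button presses; hemodynamic shift and volume
# binning; run concatenation.

#' Low-level visual change from perceptual hashes
#'
#' Frame-to-frame change as the Hamming distance between the perceptual-hash
#' bit-vectors of consecutive frames, normalized by the bit-vector length so
#' values lie in `[0, 1]`.  The first frame carries change 0.
#'
#' @param hashes list of equal-length 0/1 (or logical) vectors, or a frames x
#'   bits 0/1 matrix, one row/element per frame.
#' @return Numeric per-frame change series.
#' @examples
#' hashChangeTimeline(rbind(c(1, 1, 0, 0), c(1, 0, 1, 0)))  # 0, 0.5
#' @export
hashChangeTimeline <- function(hashes) {
  if (is.matrix(hashes)) hashes <- asplit(hashes, 1)
  L <- unique(lengths(hashes))
  if (length(L) != 1L || L < 1L) {
    stopf("all hash bit-vectors must share one positive length")
  }
  H <- do.call(rbind, lapply(hashes, as.numeric))
  if (nrow(H) < 2L) return(numeric(nrow(H)))
  d <- rowSums(abs(H[-1L, , drop = FALSE] - H[-nrow(H), , drop = FALSE])) / L
  c(0, d)
}

# cosine distance between consecutive columns of a dim x frames matrix
.cosineChanges <- function(M, what = "frame") {
  nrm <- sqrt(colSums(M^2))
  if (any(nrm == 0)) {
    stopf("zero vector at %s %d: cosine distance undefined", what,
          which(nrm == 0)[1])
  }
  U <- sweep(M, 2, nrm, "/")
  n <- ncol(M)
  if (n < 2L) return(numeric(n))
  c(0, 1 - colSums(U[, -1L, drop = FALSE] * U[, -n, drop = FALSE]))
}

#' Feature-vector change as cosine distance
#'
#' Frame-to-frame change of a feature representation (e.g. a network layer's
#' spatially pooled activations) as the cosine distance between consecutive
#' frame vectors, optionally scaled so the series maximum is exactly 1 (the
#' per-layer scaling; apply it over the concatenated movie by passing all
#' frames at once).
#'
#' @param features frames in columns (dim x frames matrix) or a list of
#'   per-frame vectors.
#' @param scale divide by the series maximum (default TRUE).
#' @return Numeric per-frame change series; first frame 0.
#' @export
cosineChangeTimeline <- function(features, scale = TRUE) {
  if (is.list(features)) features <- do.call(cbind, features)
  features <- as.matrix(features)
  ch <- .cosineChanges(features, "frame")
  if (scale && max(ch) > 0) ch <- ch / max(ch)
  ch
}

#' Per-volume MFCC change
#'
#' Audio-descriptor change on the fMRI volume grid: sample times are first
#' shifted by the hemodynamic delay, coefficient vectors are averaged within
#' each volume window, and the change series is the cosine distance between
#' consecutive volume-mean vectors, scaled to a maximum of 1.  The first
#' volume carries change 0.
#'
#' @param coeffs coefficients x samples matrix (columns are audio samples).
#' @param sampleTimes sample times in seconds (stimulus clock).
#' @param trSeconds volume duration.
#' @param nVolumes number of volumes in the run.
#' @param delaySeconds hemodynamic delay added to the sample times
#'   (default 4.5).
#' @param scale divide by the maximum (default TRUE).
#' @return Numeric per-volume change series of length `nVolumes`.
#' @export
mfccChangeTimeline <- function(coeffs, sampleTimes, trSeconds, nVolumes,
                               delaySeconds = 4.5, scale = TRUE) {
  coeffs <- as.matrix(coeffs)
  if (ncol(coeffs) != length(sampleTimes)) {
    stopf("need one sample time per coefficient column")
  }
  if (trSeconds <= 0) stopf("trSeconds must be positive")
  t2 <- sampleTimes + delaySeconds
  vol <- floor(t2 / trSeconds) + 1L
  keep <- vol >= 1L & vol <= nVolumes
  vol <- vol[keep]
  M <- vapply(seq_len(nVolumes), function(v) {
    idx <- which(vol == v)
    if (!length(idx)) stopf("no audio samples fall in volume %d", v)
    rowMeans(coeffs[, which(keep)[idx], drop = FALSE])
  }, numeric(nrow(coeffs)))
  ch <- .cosineChanges(as.matrix(M), "volume")
  if (scale && max(ch) > 0) ch <- ch / max(ch)
  ch
}

#' Speech on/offset changes from a word table
#'
#' Merges words into speech periods (a gap shorter than one TR between a
#' word's offset and the next word's onset keeps the period open), then
#' marks the start of each speech period and the start of each silence
#' period — a period of at least one TR without words, including trailing
#' silence to the run end — as a change in speech.  A change at time 0 (a
#' run starting mid-speech or mid-silence) is not a change and is dropped.
#'
#' @param words data frame with columns `onset_s` and `duration_s`.
#' @param trSeconds the TR defining "silence" (default 2 s).
#' @param runLengthSeconds run duration in seconds.
#' @return Sorted numeric change times in seconds, with a `"type"` attribute
#'   (`"speech_on"` / `"silence_on"`, alternating).
#' @examples
#' w <- data.frame(onset_s = c(1, 1.5, 8), duration_s = c(0.3, 0.4, 0.5))
#' speechChangeTimeline(w, 2, 20)  # 1.0 1.9 8.0 8.5
#' @export
speechChangeTimeline <- function(words, trSeconds = 2, runLengthSeconds) {
  stopifnot(all(c("onset_s", "duration_s") %in% names(words)))
  if (!nrow(words)) return(structure(numeric(0), type = character(0)))
  if (any(words$duration_s <= 0)) stopf("word durations must be positive")
  words <- words[order(words$onset_s), , drop = FALSE]
  if (any(words$onset_s < 0) ||
      any(words$onset_s + words$duration_s > runLengthSeconds)) {
    stopf("words must lie within the run")
  }
  on <- words$onset_s
  off <- words$onset_s + words$duration_s
  # merge into speech periods: gap < TR keeps the period open
  pStart <- on[1]; pEnd <- off[1]
  starts <- ends <- numeric(0)
  for (i in seq_len(nrow(words))[-1]) {
    if (on[i] - pEnd < trSeconds) {
      pEnd <- max(pEnd, off[i])
    } else {
      starts <- c(starts, pStart); ends <- c(ends, pEnd)
      pStart <- on[i]; pEnd <- off[i]
    }
  }
  starts <- c(starts, pStart); ends <- c(ends, pEnd)
  # silence starts at a period end whose following gap is >= TR
  gaps <- c(starts[-1], runLengthSeconds) - ends
  silence <- ends[gaps >= trSeconds]
  times <- c(starts, silence)
  types <- c(rep("speech_on", length(starts)),
             rep("silence_on", length(silence)))
  o <- order(times)
  times <- times[o]; types <- types[o]
  keep <- times > 0
  structure(times[keep], type = types[keep])
}

#' Consensus event boundaries from pooled button presses
#'
#' Subtracts the response time from every press, clusters the shifted
#' presses across observers by single linkage (a gap of at most
#' `clusterWindowSeconds` joins presses into one cluster), and emits one
#' boundary — at the cluster's mean time — for each cluster in which at
#' least `minSubjects` distinct observers pressed.
#'
#' @param presses data frame with columns `subject` and `press_time_s`.
#' @param responseShiftSeconds response-time shift (default 0.9 s).
#' @param minSubjects minimum distinct observers per boundary (default 5).
#' @param clusterWindowSeconds single-linkage gap threshold (default 1 s).
#' @return Sorted numeric boundary times in seconds.
#' @export
eventBoundaries <- function(presses, responseShiftSeconds = 0.9,
                            minSubjects = 5, clusterWindowSeconds = 1) {
  stopifnot(all(c("subject", "press_time_s") %in% names(presses)))
  if (clusterWindowSeconds <= 0) stopf("clusterWindowSeconds must be positive")
  if (!nrow(presses)) return(numeric(0))
  t <- sort(presses$press_time_s - responseShiftSeconds)
  o <- order(presses$press_time_s)
  subj <- presses$subject[o]
  cl <- cumsum(c(1, diff(t) > clusterWindowSeconds))
  out <- vapply(split(seq_along(t), cl), function(idx) {
    if (length(unique(subj[idx])) >= minSubjects) mean(t[idx]) else NA_real_
  }, 0)
  sort(unname(out[!is.na(out)]))
}

#' Delay and bin a change series onto the volume grid
#'
#' Adds the hemodynamic delay to every change time (or to the time base of a
#' continuous series) and downsamples from seconds to fMRI volumes: a binary
#' timeline marks a volume 1 when at least one shifted change time falls in
#' its window `[v * TR, (v + 1) * TR)`; a continuous timeline takes the mean
#' (or maximum) of the values whose shifted times fall in the window.
#' Shifted times beyond the run are dropped.
#'
#' @param x numeric change times in seconds (`kind = "binary"`), or values of
#'   a continuous series (`kind = "continuous"`, with `times`).
#' @param trSeconds volume duration.
#' @param nVolumes number of volumes in the run.
#' @param delaySeconds hemodynamic delay (default 4.5 s).
#' @param kind `"binary"` or `"continuous"`.
#' @param times time base of a continuous series, in seconds.
#' @param aggregator within-volume aggregation for continuous series.
#' @param category,group labels stored on the result.
#' @param runId run label.
#' @return An [AnnotationTimeline-class] of length `nVolumes`.
#' @examples
#' # change at 1.0 s, delay 4.5, TR 2 -> lands in the third volume
#' timelineValues(shiftAndBin(1.0, trSeconds = 2, nVolumes = 5,
#'                            category = "events"))
#' @export
shiftAndBin <- function(x, trSeconds, nVolumes, delaySeconds = 4.5,
                        kind = c("binary", "continuous"), times = NULL,
                        aggregator = c("mean", "max"),
                        category = "annotation", group = "conceptual",
                        runId = "run1") {
  kind <- match.arg(kind)
  aggregator <- match.arg(aggregator)
  nVolumes <- as.integer(nVolumes)
  v <- numeric(nVolumes)
  if (kind == "binary") {
    tt <- x + delaySeconds
    idx <- floor(tt / trSeconds) + 1L
    idx <- idx[idx >= 1L & idx <= nVolumes]
    v[unique(idx)] <- 1
  } else {
    if (is.null(times)) stopf("continuous series need a 'times' vector")
    if (length(times) != length(x)) stopf("times and values lengths differ")
    tt <- times + delaySeconds
    idx <- floor(tt / trSeconds) + 1L
    keep <- idx >= 1L & idx <= nVolumes
    agg <- if (aggregator == "mean") mean else max
    vals <- vapply(split(x[keep], idx[keep]), agg, 0)
    v[as.integer(names(vals))] <- vals
  }
  AnnotationTimeline(v, category = category, group = group, kind = kind,
                     runId = runId, runLengths = nVolumes)
}

#' Scale a continuous timeline to unit maximum
#'
#' Divides by the maximum so the scaled series peaks at exactly 1.  Apply to
#' the run-concatenated timeline for whole-movie (per-category) scaling.
#'
#' @param timeline an [AnnotationTimeline-class] (continuous) or numeric
#'   vector.
#' @return Same type as the input, scaled.
#' @export
scaleToUnitMax <- function(timeline) {
  if (is(timeline, "AnnotationTimeline")) {
    m <- max(timeline@values)
    if (m > 0) timeline@values <- timeline@values / m
    return(timeline)
  }
  m <- max(timeline)
  if (m > 0) timeline / m else timeline
}

#' Concatenate per-run timelines
#'
#' Joins per-run timelines of the same annotation category, in run order,
#' recording the run lengths so that downstream permutations stay within
#' runs.
#'
#' @param timelines list of [AnnotationTimeline-class] (same category) or of
#'   [BoundaryTimeline-class].
#' @return A concatenated timeline with `runId = "concat"`.
#' @export
concatenateRuns <- function(timelines) {
  stopifnot(length(timelines) >= 1L)
  if (is(timelines[[1]], "BoundaryTimeline")) {
    stopifnot(all(vapply(timelines, is, TRUE, "BoundaryTimeline")))
    return(new("BoundaryTimeline",
               values = unlist(lapply(timelines, timelineValues)),
               runId = "concat",
               runLengths = vapply(timelines, nVolumes, 1L)))
  }
  stopifnot(all(vapply(timelines, is, TRUE, "AnnotationTimeline")))
  cats <- unique(vapply(timelines, category, ""))
  if (length(cats) != 1L) {
    stopf("cannot concatenate different categories: %s",
          paste(cats, collapse = ", "))
  }
  new("AnnotationTimeline",
      values = unlist(lapply(timelines, timelineValues)),
      category = cats, group = timelines[[1]]@group,
      kind = timelines[[1]]@kind, runId = "concat",
      runLengths = vapply(timelines, nVolumes, 1L))
}
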