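# Spherical searchlights over a voxel mask, per-searchlight alignment
# analysis, BH-FDR across searchlights and voxel-level aggregation.

#' Tile a mask with spherical searchlights
#'
#' Candidate centers lie on a regular grid (spacing `spacingVoxels`)
#' anchored at the minimum corner of the mask's bounding box; a searchlight
#' keeps every in-mask voxel within Euclidean distance `radiusVoxels` of its
#' center (boundary inclusive, voxel units) and is retained only when it has
#' at least `minVoxels` members.
#'
#' @param mask 3D logical (or 0/1) array.
#' @param radiusVoxels sphere radius in voxels (default 3.5).
#' @param spacingVoxels center spacing in voxels (default 2).
#' @param minVoxels minimum member count (default 20).
#' @return A [SearchlightSet-class].
#' @export
buildSearchlights <- function(mask, radiusVoxels = 3.5, spacingVoxels = 2,
                              minVoxels = 20) {
  mask <- array(as.logical(mask), dim = dim(mask))
  if (length(dim(mask)) != 3L) stopf("mask must be a 3D array")
  if (!any(mask)) stopf("mask is empty")
  vox <- which(mask)
  coords <- arrayInd(vox, dim(mask))
  lo <- apply(coords, 2, min)
  hi <- apply(coords, 2, max)
  grid <- as.matrix(expand.grid(
    seq.int(lo[1], hi[1], by = spacingVoxels),
    seq.int(lo[2], hi[2], by = spacingVoxels),
    seq.int(lo[3], hi[3], by = spacingVoxels)))
  r2 <- radiusVoxels^2
  centers <- list(); members <- list()
  for (g in seq_len(nrow(grid))) {
    d2 <- (coords[, 1] - grid[g, 1])^2 + (coords[, 2] - grid[g, 2])^2 +
      (coords[, 3] - grid[g, 3])^2
    m <- vox[d2 <= r2]
    if (length(m) >= minVoxels) {
      centers[[length(centers) + 1L]] <- grid[g, ]
      members[[length(members) + 1L]] <- m
    }
  }
  if (!length(members)) stopf("no searchlight reaches %d voxels", minVoxels)
  new("SearchlightSet", mask = mask,
      centers = do.call(rbind, centers), members = members,
      radiusVoxels = radiusVoxels, spacingVoxels = as.integer(spacingVoxels),
      minVoxels = as.integer(minVoxels))
}

# Extract a members x T matrix from a 4D array (x, y, z, t).
.extractMembers <- function(arr4d, memberIdx) {
  d <- dim(arr4d)
  nvox <- prod(d[1:3])
  T <- d[4]
  idx <- rep(memberIdx, times = T) + nvox * rep(seq_len(T) - 1L, each = length(memberIdx))
  matrix(arr4d[idx], length(memberIdx), T)
}

#' Run the alignment analysis in every searchlight
#'
#' For each searchlight: extract the member-voxel time series of every
#' subject and run, z-score per voxel per run, average across subjects,
#' segment each run by [greedySegment()] (state count either selected
#' data-drivenly or fixed via `k`), and test the boundary/annotation
#' alignment with [permutationTest()].  Per-searchlight permutation seeds
#' are derived deterministically from the master seed.
#'
#' @param set a [SearchlightSet-class].
#' @param runs list over runs; each element is a single 4D array
#'   `(x, y, z, t)` (group data) or a list of per-subject 4D arrays.
#' @param annotation run-concatenated [AnnotationTimeline-class].
#' @param ledger,covariateTimelines as in [permutationTest()].
#' @param nPerm permutations per searchlight (default 1000).
#' @param seed master seed.
#' @param kMax maximum state count per run (default: half the volumes).
#' @param k fixed state count; `NULL` (default) selects it per run with
#'   [selectK()].
#' @param finetune passed to [greedySegment()].
#' @param trSeconds repetition time of the data.
#' @return A data frame with one row per searchlight: center coordinates,
#'   member count, observed partial correlation `r` and one-tailed `p`
#'   (`NA` for degenerate searchlights, e.g. constant data).
#' @export
runSearchlightAnalysis <- function(set, runs, annotation, ledger = NULL,
                                   covariateTimelines = NULL, nPerm = 1000,
                                   seed = 1, kMax = NULL, k = NULL,
                                   finetune = 1, trSeconds = 2) {
  stopifnot(is(set, "SearchlightSet"))
  nSl <- length(set@members)
  res <- data.frame(x = set@centers[, 1], y = set@centers[, 2],
                    z = set@centers[, 3],
                    nMembers = vapply(set@members, length, 1L),
                    r = rep(NA_real_, nSl), p = rep(NA_real_, nSl))
  for (i in seq_len(nSl)) {
    mIdx <- set@members[[i]]
    segs <- tryCatch({
      lapply(seq_along(runs), function(rn) {
        ru <- runs[[rn]]
        subjects <- if (is.list(ru)) ru else list(ru)
        serList <- lapply(subjects, function(a) {
          zscoreVolumeSeries(VolumeSeries(.extractMembers(a, mIdx),
                                          trSeconds = trSeconds,
                                          runId = sprintf("run%d", rn)))
        })
        g <- groupAverage(serList)
        sg <- greedySegment(g, kMax = kMax, finetune = finetune)
        if (is.null(k)) selectK(sg, g) else segmentationAtK(sg, g, k)
      })
    }, error = function(e) NULL)
    if (is.null(segs)) next
    out <- tryCatch(
      permutationTest(segs, annotation, ledger = ledger,
                      covariateTimelines = covariateTimelines,
                      nPerm = nPerm, seed = deriveSeed(seed, i)),
      error = function(e) NULL)
    if (is.null(out)) next
    res$r[i] <- rObserved(out)
    res$p[i] <- pOneTailed(out)
  }
  res
}

#' Benjamini-Hochberg FDR correction across searchlights
#'
#' Step-up procedure: with the valid p-values sorted ascending, find the
#' largest `i` with `p_(i) <= i * alpha / m` and reject every test with
#' `p <= p_(i)`.  Missing (`NA`) entries are excluded and never rejected.
#'
#' @param pValues numeric vector of p-values (may contain `NA`).
#' @param alpha target false discovery rate (default 0.05).
#' @return List with `reject` (logical, same length as input) and
#'   `highestSurvivingP` (the largest rejected p, `NA` when none survive).
#' @examples
#' fdrCorrect(c(0.001, 0.01, 0.02, 0.5))  # 3 rejections, threshold 0.02
#' @export
fdrCorrect <- function(pValues, alpha = 0.05) {
  ok <- !is.na(pValues)
  if (any(pValues[ok] < 0 | pValues[ok] > 1)) stopf("p-values must lie in [0, 1]")
  reject <- rep(FALSE, length(pValues))
  if (any(ok)) {
    adj <- stats::p.adjust(pValues[ok], method = "BH")
    reject[ok] <- adj <= alpha
  }
  highest <- if (any(reject)) max(pValues[reject]) else NA_real_
  list(reject = reject, highestSurvivingP = highest)
}

#' Aggregate searchlight p-values to voxels
#'
#' Each voxel receives the mean p-value of all searchlights whose member
#' lists contain it (searchlights with missing p excluded), and is flagged
#' significant only when that mean is strictly smaller than the highest
#' p-value that survived the FDR correction.  Voxels covered by no
#' searchlight get a missing mean and are never significant; when no
#' searchlight survived the FDR correction, no voxel is significant.
#'
#' @param set a [SearchlightSet-class].
#' @param pValues per-searchlight p-values (order of `set`).
#' @param highestSurvivingP FDR threshold from [fdrCorrect()].
#' @return A [VoxelSignificanceMap-class].
#' @export
voxelAggregate <- function(set, pValues, highestSurvivingP) {
  stopifnot(is(set, "SearchlightSet"),
            length(pValues) == length(set@members))
  d <- dim(set@mask)
  sumP <- array(0, d)
  cnt <- array(0L, d)
  for (i in seq_along(set@members)) {
    if (is.na(pValues[i])) next
    m <- set@members[[i]]
    sumP[m] <- sumP[m] + pValues[i]
    cnt[m] <- cnt[m] + 1L
  }
  meanP <- array(NA_real_, d)
  covered <- cnt > 0L
  meanP[covered] <- sumP[covered] / cnt[covered]
  sig <- array(FALSE, d)
  if (!is.na(highestSurvivingP)) {
    sig[covered] <- meanP[covered] < highestSurvivingP
  }
  new("VoxelSignificanceMap", meanP = meanP, significant = sig,
      fdrThresholdP = if (is.na(highestSurvivingP)) NA_real_ else highestSurvivingP)
}
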