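# Covariate-corrected partial correlation between boundary and annotation
# timelines, with a duration-preserving state-permutation null.

#' Partial Pearson correlation
#'
#' Residualizes `x` and `y` on the covariate matrix (plus an intercept) by
#' least squares and returns the Pearson correlation of the residuals.  With
#' no covariates this is the plain Pearson correlation.  A rank-deficient
#' covariate matrix is handled by projection onto its column space (the
#' least-squares residual is still unique), with a warning.
#'
#' @param x,y numeric vectors of equal length.
#' @param covariates numeric matrix (one covariate per column), or `NULL`.
#' @return The partial correlation coefficient.
#' @examples
#' set.seed(1)
#' z <- rnorm(50); x <- z + rnorm(50); y <- -z + rnorm(50)
#' partialCorrelation(x, y, cbind(z))
#' @export
partialCorrelation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stopf("x and y lengths differ")
  p <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n < 3L + p) stopf("need at least %d observations for %d covariate(s)",
                        3L + p, p)
  Z <- cbind(rep(1, n), covariates)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    warnf("covariate matrix is rank deficient (rank %d of %d)", qz$rank - 1L,
          ncol(Z) - 1L)
  }
  rx <- qr.resid(qz, x)
  ry <- qr.resid(qz, y)
  if (.nearConstant(rx, x) || .nearConstant(ry, y)) {
    stopf("residual is constant; partial correlation undefined")
  }
  stats::cor(rx, ry)
}

# residual indistinguishable from 0 at the scale of the original variable
.nearConstant <- function(res, orig) {
  stats::sd(res) < 1e-10 * max(stats::sd(orig), 1e-300)
}

#' Duration-preserving state shuffle
#'
#' Randomly permutes the order of a run's neural states while keeping the
#' number of states and the multiset of state durations intact.  Each
#' boundary strength travels with the state it opens; the first state opens
#' no boundary, and its empty slot is dropped from the permuted strength
#' sequence, so the remaining strengths are assigned, in permuted order, to
#' the rebuilt boundaries in temporal order.  The strength multiset is
#' preserved on every draw.
#'
#' @param segmentation a [StateSegmentation-class] with at least 2 states
#'   and strengths computed.
#' @param seed optional seed for this draw.
#' @return A [BoundaryTimeline-class] for the shuffled run.
#' @export
permuteStates <- function(segmentation, seed = NULL) {
  stopifnot(is(segmentation, "StateSegmentation"))
  b <- segmentation@boundaries
  if (length(b) < 1L) stopf("need at least 2 states to permute")
  if (!length(segmentation@strengths)) {
    stopf("strengths not computed; call selectK() or segmentationAtK() first")
  }
  T <- segmentation@nTimepoints
  dur <- diff(c(0L, b, T))
  s <- c(NA_real_, segmentation@strengths)   # strength opening each state
  withSeed(seed, {
    perm <- sample.int(length(dur))
    newB <- cumsum(dur[perm])[-length(dur)]
    newS <- s[perm]
    newS <- newS[!is.na(newS)]
    v <- numeric(T)
    v[newB + 1L] <- newS
    new("BoundaryTimeline", values = v, runId = segmentation@runId,
        runLengths = T)
  })
}

# residualizer closure: projects out Z's column space (incl. intercept)
.makeResidualizer <- function(n, covariates) {
  Z <- cbind(rep(1, n), covariates)
  qz <- qr(Z)
  rank <- qz$rank
  if (rank < ncol(Z)) {
    warnf("covariate matrix is rank deficient (rank %d of %d)", rank - 1L,
          ncol(Z) - 1L)
  }
  Q <- qr.Q(qz)[, seq_len(rank), drop = FALSE]
  function(v) as.vector(v - Q %*% crossprod(Q, v))
}

#' Permutation test of boundary/annotation alignment
#'
#' Computes the observed partial correlation between the run-concatenated
#' boundary timeline and an annotation timeline, correcting for the
#' annotation's ledger covariates, and compares it against a null
#' distribution built by shuffling state order independently within every
#' run ([permuteStates()]), re-concatenating and re-computing the partial
#' correlation.  The one-tailed p-value is the fraction of null values
#' greater than or equal to the observed value (`p = count / nPerm`, so an
#' observed value above the whole null yields p = 0; set
#' `addOneCorrection = TRUE` for the (count + 1) / (nPerm + 1) variant).
#'
#' @param segmentations a [StateSegmentation-class] or list of them (one per
#'   run), each with strengths computed.
#' @param annotation an [AnnotationTimeline-class] covering the concatenated
#'   volume grid.
#' @param ledger a [CovariateLedger-class], or `NULL` to use the covariates
#'   given directly.
#' @param covariateTimelines named list of [AnnotationTimeline-class] (or
#'   numeric vectors) supplying covariate timelines by category.  When a
#'   ledger is given, the ledger's entries for the annotation's category are
#'   looked up here.
#' @param nPerm number of permutations (default 10000).
#' @param seed seed for the permutation stream.
#' @param addOneCorrection use (count + 1) / (nPerm + 1) (default FALSE).
#' @return An [AlignmentResult-class].
#' @export
permutationTest <- function(segmentations, annotation, ledger = NULL,
                            covariateTimelines = NULL, nPerm = 10000,
                            seed = NULL, addOneCorrection = FALSE) {
  if (is(segmentations, "StateSegmentation")) {
    segmentations <- list(segmentations)
  }
  stopifnot(all(vapply(segmentations, is, TRUE, "StateSegmentation")),
            is(annotation, "AnnotationTimeline"))
  nPerm <- as.integer(nPerm)
  if (nPerm < 1L) stopf("nPerm must be at least 1")
  runT <- vapply(segmentations, nVolumes, 1L)
  n <- sum(runT)
  y <- timelineValues(annotation)
  if (length(y) != n) {
    stopf("annotation covers %d volumes but segmentations cover %d",
          length(y), n)
  }
  covNames <- character(0)
  if (!is.null(ledger)) {
    covNames <- covariatesFor(ledger, category(annotation),
                              available = names(covariateTimelines))
  } else if (!is.null(covariateTimelines)) {
    covNames <- names(covariateTimelines)
  }
  covMat <- NULL
  if (length(covNames)) {
    covMat <- vapply(covNames, function(nm) {
      v <- covariateTimelines[[nm]]
      if (is(v, "AnnotationTimeline")) v <- timelineValues(v)
      if (length(v) != n) stopf("covariate '%s' has wrong length", nm)
      v
    }, numeric(n))
  }
  resid <- .makeResidualizer(n, covMat)
  ry <- resid(y)
  if (.nearConstant(ry, y)) stopf("annotation residual is constant")

  observed <- unlist(lapply(segmentations, function(sg) {
    timelineValues(toTimeline(sg))
  }))
  rx <- resid(observed)
  if (.nearConstant(rx, observed)) {
    stopf("boundary-timeline residual is constant")
  }
  rObs <- stats::cor(rx, ry)

  nullSample <- withSeed(seed, {
    vapply(seq_len(nPerm), function(i) {
      perm <- unlist(lapply(segmentations, function(sg) {
        timelineValues(permuteStates(sg))
      }))
      rp <- resid(perm)
      if (.nearConstant(rp, perm)) return(NA_real_)
      stats::cor(rp, ry)
    }, 0)
  })
  if (anyNA(nullSample)) {
    stopf("%d permutation(s) produced a constant residual", sum(is.na(nullSample)))
  }
  cnt <- sum(nullSample >= rObs)
  p <- if (addOneCorrection) (cnt + 1) / (nPerm + 1) else cnt / nPerm
  new("AlignmentResult", category = category(annotation), rObserved = rObs,
      nullSample = nullSample, pOneTailed = p, nPermutations = nPerm,
      pCorrected = NA_real_, correctionFactor = NA_integer_,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Bonferroni correction
#'
#' Multiplies each one-tailed p-value by the number of tests (e.g. the
#' number of ROIs) and caps at 1.
#'
#' @param results an [AlignmentResult-class] or list of them.
#' @param nTests number of tests corrected for.
#' @return The input with `pCorrected` and `correctionFactor` filled in
#'   (single object in, single object out).
#' @export
bonferroni <- function(results, nTests) {
  nTests <- as.integer(nTests)
  if (nTests < 1L) stopf("nTests must be at least 1")
  single <- is(results, "AlignmentResult")
  if (single) results <- list(results)
  results <- lapply(results, function(r) {
    stopifnot(is(r, "AlignmentResult"))
    r@pCorrected <- min(1, r@pOneTailed * nTests)
    r@correctionFactor <- nTests
    r
  })
  if (single) results[[1]] else results
}
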