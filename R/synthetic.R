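# Synthetic runs with planted neural states and annotation sources whose
# coupling to the planted boundaries is controlled.  Every downstream stage
# (segmentation, annotation building, alignment, searchlight) can be
# validated against this ground truth.

#' Generate a planted ground truth
#'
#' Draws, for each run, a set of strictly increasing state boundaries with a
#' minimum state duration, and one i.i.d. standard-normal voxel pattern per
#' state (giving near-zero expected correlation between state means, so that
#' boundary detectability is controlled by `snr` alone).
#'
#' Boundaries are kept at or above `ceiling(delaySeconds / trSeconds)`
#' volumes so that every boundary maps to a non-negative stimulus time when
#' the hemodynamic delay is inverted.
#'
#' @param runLengths integer vector: volumes per run.
#' @param nStates states per run (recycled across runs).
#' @param nVoxels voxels per pattern.
#' @param coupling named numeric in `[0, 1]`: per annotation category, the
#'   fraction of planted boundaries that carry a change in that category.
#' @param snr ratio of pattern SD to additive noise SD.
#' @param nSubjects number of subjects (default 15).
#' @param trSeconds repetition time (default 2 s).
#' @param delaySeconds hemodynamic delay (default 4.5 s).
#' @param ar1 AR(1) coefficient of the temporal noise (default 0 = white).
#' @param minDuration minimum state duration in volumes (default 3).
#' @param seed integer seed; the object is fully determined by it.
#' @return A [GroundTruth-class].
#' @examples
#' gt <- simulateGroundTruth(120, nStates = 8, nVoxels = 50,
#'                           coupling = c(events = 1), snr = 2, seed = 1)
#' gt
#' @export
simulateGroundTruth <- function(runLengths, nStates, nVoxels,
                                coupling = numeric(0), snr = 1,
                                nSubjects = 15, trSeconds = 2,
                                delaySeconds = 4.5, ar1 = 0,
                                minDuration = 3, seed = 1) {
  runLengths <- as.integer(runLengths)
  nStates <- rep_len(as.integer(nStates), length(runLengths))
  if (snr <= 0) stopf("snr must be positive")
  if (any(nStates < 2L)) stopf("each run needs at least 2 states")
  if (any(nStates * minDuration > runLengths)) {
    stopf("runs too short for %d states of >= %d volumes", max(nStates),
          minDuration)
  }
  minB <- max(minDuration, ceiling(delaySeconds / trSeconds))
  withSeed(seed, {
    boundaries <- vector("list", length(runLengths))
    patterns <- vector("list", length(runLengths))
    for (r in seq_along(runLengths)) {
      T <- runLengths[r]; k <- nStates[r]
      repeat {
        b <- sort(sample(seq.int(minB, T - minDuration), k - 1L))
        if (all(diff(c(0L, b, T)) >= minDuration) && b[1] >= minB) break
      }
      boundaries[[r]] <- as.integer(b)
      patterns[[r]] <- matrix(stats::rnorm(nVoxels * k), nVoxels, k)
    }
    new("GroundTruth", runLengths = runLengths, boundaries = boundaries,
        statePatterns = patterns, coupling = coupling, snr = snr,
        nSubjects = as.integer(nSubjects), trSeconds = trSeconds,
        delaySeconds = delaySeconds, ar1 = ar1, seed = as.integer(seed))
  })
}

# State id per volume for one run of a ground truth.
.stateIds <- function(truth, runIndex) {
  T <- truth@runLengths[runIndex]
  b <- truth@boundaries[[runIndex]]
  rep(seq_len(length(b) + 1L), diff(c(0L, b, T)))
}

#' Simulate one run for all subjects
#'
#' Each subject's matrix is the state-pattern block structure (the pattern of
#' state `s` repeated over its volumes) plus independent Gaussian noise with
#' SD `1 / snr` (AR(1)-correlated in time when `ar1 > 0`), z-scored per voxel
#' within the run.  Planted boundaries are identical across subjects.
#'
#' @param truth a [GroundTruth-class].
#' @param runIndex which run to simulate.
#' @return List of [VolumeSeries-class], one per subject.
#' @export
simulateRun <- function(truth, runIndex) {
  stopifnot(is(truth, "GroundTruth"))
  runIndex <- as.integer(runIndex)
  if (runIndex < 1L || runIndex > length(truth@runLengths)) {
    stopf("runIndex %d out of range", runIndex)
  }
  T <- truth@runLengths[runIndex]
  P <- truth@statePatterns[[runIndex]]
  V <- nrow(P)
  z <- .stateIds(truth, runIndex)
  signal <- P[, z, drop = FALSE]
  lapply(seq_len(truth@nSubjects), function(s) {
    noise <- if (is.finite(truth@snr)) {
      withSeed(deriveSeed(truth@seed, runIndex, s), {
        e <- matrix(stats::rnorm(V * T), V, T)
        if (truth@ar1 != 0) {
          a <- truth@ar1
          for (t in 2:T) e[, t] <- a * e[, t - 1L] + sqrt(1 - a^2) * e[, t]
        }
        e / truth@snr
      })
    } else 0
    vs <- VolumeSeries(signal + noise, trSeconds = truth@trSeconds,
                       runId = sprintf("run%d", runIndex),
                       subjectId = sprintf("sub%02d", s))
    zscoreVolumeSeries(vs)
  })
}

#' Average a set of runs across subjects
#'
#' Element-wise mean of identically shaped [VolumeSeries-class] objects; the
#' result is labelled subject `"group"`.
#'
#' @param series list of [VolumeSeries-class] with identical dimensions and
#'   TR.
#' @return A [VolumeSeries-class].
#' @export
groupAverage <- function(series) {
  if (is(series, "VolumeSeries")) series <- list(series)
  stopifnot(length(series) >= 1L, all(vapply(series, is, TRUE, "VolumeSeries")))
  d <- dim(seriesData(series[[1]]))
  tr <- trSeconds(series[[1]])
  for (s in series) {
    if (!identical(dim(seriesData(s)), d)) stopf("shape mismatch across subjects")
    if (trSeconds(s) != tr) stopf("TR mismatch across subjects")
  }
  m <- Reduce(`+`, lapply(series, seriesData)) / length(series)
  VolumeSeries(m, trSeconds = tr, runId = runId(series[[1]]),
               subjectId = "group")
}

# Stimulus time (s) of a boundary at volume position b: the new state starts
# at the onset of volume b + 1, i.e. at b * TR seconds of scanner time, and
# the driving stimulus change precedes it by the hemodynamic delay.
.boundaryStimTime <- function(b, trSeconds, delaySeconds) {
  b * trSeconds - delaySeconds
}

#' Simulate raw annotation sources coupled to planted boundaries
#'
#' For a category with coupling `c`, a fraction `c` of each run's planted
#' boundaries (selected by count) receives a stimulus change at the
#' boundary's stimulus time — the boundary's volume onset minus the
#' hemodynamic delay — plus uniformly placed off-boundary distractor changes
#' that keep at least a one-volume gap from true boundaries.  A category
#' listed in `coOccur` instead co-occurs with a target category's changes at
#' the given rate (plus its own distractors), emulating the strong
#' between-annotation correlations typical of movie annotations.
#'
#' Sources are delivered in the shape the annotation builders consume:
#' \describe{
#'   \item{`times`}{numeric change times in seconds (default).}
#'   \item{`words`}{a word table (`onset_s`, `duration_s`) whose speech
#'     on/offsets realize the change times (consecutive changes are paired
#'     into speech periods; an odd trailing change opens a 1 s word).}
#'   \item{`presses`}{a button-press table (`subject`, `press_time_s`):
#'     `nPressSubjects` of 16 observers press 0.9 s after each change, with
#'     small uniform jitter.}
#'   \item{`frames`}{a per-frame change-magnitude series (`times`, `values`)
#'     at `frameRateHz`, with unit-magnitude changes at the change times over
#'     a small noise floor.}
#' }
#'
#' @param truth a [GroundTruth-class] with a non-empty coupling map.
#' @param distractorRate expected distractor changes per eligible
#'   off-boundary volume (default 0.05).
#' @param coOccur optional named list: `category -> list(with = <target
#'   category>, rate = <fraction>)`.
#' @param sourceKinds named character overriding the per-category source
#'   kind; defaults: `speech -> "words"`, `events -> "presses"`, categories
#'   named `mfcc` or starting with `low_level_visual`/`alexnet` -> `"frames"`,
#'   everything else `"times"`.
#' @param nPressSubjects observers pressing per event (default 8 of 16).
#' @param frameRateHz frame rate of `frames` sources (default 1).
#' @param seed seed for the source randomness (defaults to the truth's seed).
#' @return Named list: per category, a list of per-run sources, each a list
#'   with elements `kind` and the source payload.  The attribute
#'   `trueChangeTimes` records the exact per-run change times per category.
#' @export
simulateAnnotationSources <- function(truth, distractorRate = 0.05,
                                      coOccur = NULL, sourceKinds = NULL,
                                      nPressSubjects = 8, frameRateHz = 1,
                                      seed = NULL) {
  stopifnot(is(truth, "GroundTruth"))
  cats <- names(truth@coupling)
  if (!length(cats)) stopf("truth has no coupling map")
  for (cv in names(coOccur)) {
    tgt <- coOccur[[cv]]$with
    if (!tgt %in% cats) stopf("co-occurrence target '%s' not in coupling map", tgt)
  }
  if (is.null(seed)) seed <- truth@seed
  tr <- truth@trSeconds; delay <- truth@delaySeconds
  R <- length(truth@runLengths)

  kindOf <- function(cat) {
    if (!is.null(sourceKinds) && cat %in% names(sourceKinds)) {
      return(sourceKinds[[cat]])
    }
    if (cat == "speech") return("words")
    if (cat == "events") return("presses")
    if (cat == "mfcc" || grepl("^(low_level_visual|alexnet)", cat)) {
      return("frames")
    }
    "times"
  }

  # change times per category per run
  timesByCat <- withSeed(deriveSeed(seed, 1L), {
    out <- list()
    for (cat in cats) {
      cc <- truth@coupling[[cat]]
      out[[cat]] <- lapply(seq_len(R), function(r) {
        b <- truth@boundaries[[r]]
        T <- truth@runLengths[r]
        nSel <- round(cc * length(b))
        onB <- if (nSel > 0) sort(sample(b, nSel)) else integer(0)
        # the one-volume disambiguation gap around true boundaries applies
        # only to partially coupled categories; a fully uncoupled category
        # (coupling 0) must be statistically independent of the boundaries
        eligible <- if (cc > 0) {
          setdiff(seq.int(ceiling(delay / tr), T - 1L), c(b - 1L, b, b + 1L))
        } else {
          seq.int(ceiling(delay / tr), T - 1L)
        }
        nDis <- round(distractorRate * length(eligible))
        dis <- if (nDis > 0) sort(sample(eligible, nDis)) else integer(0)
        .boundaryStimTime(sort(c(onB, dis)), tr, delay)
      })
    }
    # co-occurring covariate categories: overwrite with a sampled subset of
    # the target's changes (their own distractors are kept)
    for (cv in names(coOccur)) {
      tgt <- coOccur[[cv]]$with; rate <- coOccur[[cv]]$rate
      out[[cv]] <- lapply(seq_len(R), function(r) {
        tt <- out[[tgt]][[r]]
        nCo <- round(rate * length(tt))
        co <- if (nCo > 0) sort(sample(tt, nCo)) else numeric(0)
        T <- truth@runLengths[r]
        b <- truth@boundaries[[r]]
        eligible <- setdiff(seq.int(ceiling(delay / tr), T - 1L),
                            c(b - 1L, b, b + 1L))
        nDis <- round(distractorRate * length(eligible))
        dis <- if (nDis > 0) {
          .boundaryStimTime(sort(sample(eligible, nDis)), tr, delay)
        } else numeric(0)
        sort(unique(c(co, dis)))
      })
    }
    out
  })

  sources <- withSeed(deriveSeed(seed, 2L), {
    out <- list()
    for (cat in names(timesByCat)) {
      kind <- kindOf(cat)
      out[[cat]] <- lapply(seq_len(R), function(r) {
        ct <- timesByCat[[cat]][[r]]
        Tsec <- truth@runLengths[r] * tr
        switch(kind,
          times = list(kind = "times", times = ct),
          words = {
            # pair consecutive changes into speech periods
            n2 <- 2L * (length(ct) %/% 2L)
            on <- ct[seq_len(n2) %% 2L == 1L]
            off <- ct[seq_len(n2) %% 2L == 0L]
            if (length(ct) > n2) {
              on <- c(on, ct[length(ct)])
              off <- c(off, min(ct[length(ct)] + 1, Tsec - 0.1))
            }
            list(kind = "words",
                 table = data.frame(onset_s = on, duration_s = off - on))
          },
          presses = {
            subj <- unlist(lapply(seq_along(ct), function(i) {
              sample(16L, nPressSubjects)
            }))
            pt <- rep(ct, each = nPressSubjects) + 0.9 +
              stats::runif(length(ct) * nPressSubjects, -0.15, 0.15)
            list(kind = "presses",
                 table = data.frame(subject = subj, press_time_s = pt))
          },
          frames = {
            ft <- seq(0, Tsec - 1 / frameRateHz, by = 1 / frameRateHz)
            v <- abs(stats::rnorm(length(ft), 0, 0.03))
            idx <- pmin(length(ft), floor(ct * frameRateHz) + 1L)
            v[idx] <- 1
            list(kind = "frames", times = ft, values = v)
          },
          stopf("unknown source kind '%s'", kind))
      })
    }
    out
  })
  attr(sources, "trueChangeTimes") <- timesByCat
  attr(sources, "runLengthsSeconds") <- truth@runLengths * tr
  sources
}
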