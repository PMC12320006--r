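#' @import methods
NULL

#' VolumeSeries: one run of multivoxel fMRI data
#'
#' A voxels x timepoints matrix for a single run of a single subject (or a
#' group average), together with the repetition time (TR) and identifying
#' labels.  All downstream segmentation operates on this container.
#'
#' @slot data numeric matrix, voxels in rows, volumes (timepoints) in columns.
#' @slot trSeconds duration of one volume in seconds.
#' @slot runId run label.
#' @slot subjectId subject label, or `"group"` for an across-subject average.
#'
#' @seealso [VolumeSeries()] for the constructor,
#'   [zscoreVolumeSeries()], [greedySegment()].
#' @export
setClass("VolumeSeries",
  representation(
    data = "matrix",
    trSeconds = "numeric",
    runId = "character",
    subjectId = "character"
  ),
  prototype(trSeconds = 2, runId = "run1", subjectId = "group")
)

setValidity("VolumeSeries", function(object) {
  d <- object@data
  if (!is.numeric(d)) return("data must be a numeric matrix")
  if (nrow(d) < 2L || ncol(d) < 2L) {
    return("data needs at least 2 voxels and 2 timepoints")
  }
  if (!all(is.finite(d))) return("data contains non-finite values")
  if (length(object@trSeconds) != 1L || object@trSeconds <= 0) {
    return("trSeconds must be a single positive number")
  }
  TRUE
})

#' Construct a VolumeSeries
#'
#' @param data voxels x timepoints numeric matrix.
#' @param trSeconds repetition time in seconds (default 2, the usual movie
#'   fMRI TR in this pipeline).
#' @param runId,subjectId labels.
#' @return A [VolumeSeries-class] object.
#' @examples
#' vs <- VolumeSeries(matrix(rnorm(40), 4, 10))
#' nVolumes(vs)
#' @export
VolumeSeries <- function(data, trSeconds = 2, runId = "run1",
                         subjectId = "group") {
  new("VolumeSeries", data = as.matrix(data), trSeconds = trSeconds,
      runId = as.character(runId), subjectId = as.character(subjectId))
}

#' GroundTruth: planted structure for synthetic runs
#'
#' Describes a simulated experiment: per-run planted state boundaries and
#' state patterns, the coupling of each annotation category to those
#' boundaries, the signal-to-noise ratio and the subject count.  Created by
#' [simulateGroundTruth()]; consumed by [simulateRun()] and
#' [simulateAnnotationSources()].
#'
#' Boundaries are counted in volumes from the start of the run: boundary
#' value `b` means the first `b` volumes precede it and a new state begins at
#' volume `b + 1` (1-based).
#'
#' @slot runLengths integer vector of run lengths in volumes.
#' @slot boundaries list (per run) of strictly increasing boundary positions
#'   in `(0, T)`.
#' @slot statePatterns list (per run) of voxels x states pattern matrices.
#' @slot coupling named numeric in `[0, 1]`: fraction of planted boundaries
#'   that carry a change in each annotation category.
#' @slot snr ratio of state-pattern SD to additive noise SD.
#' @slot nSubjects number of simulated subjects.
#' @slot trSeconds repetition time in seconds.
#' @slot delaySeconds hemodynamic delay used to map boundaries back to
#'   stimulus time.
#' @slot ar1 temporal AR(1) coefficient of the noise (0 = white).
#' @slot seed integer seed the object was generated from.
#' @export
setClass("GroundTruth",
  representation(
    runLengths = "integer",
    boundaries = "list",
    statePatterns = "list",
    coupling = "numeric",
    snr = "numeric",
    nSubjects = "integer",
    trSeconds = "numeric",
    delaySeconds = "numeric",
    ar1 = "numeric",
    seed = "integer"
  )
)

setValidity("GroundTruth", function(object) {
  R <- length(object@runLengths)
  if (length(object@boundaries) != R || length(object@statePatterns) != R) {
    return("boundaries and statePatterns must have one element per run")
  }
  for (r in seq_len(R)) {
    b <- object@boundaries[[r]]
    T <- object@runLengths[r]
    if (length(b) && (any(diff(b) <= 0) || any(b <= 0) || any(b >= T))) {
      return(sprintf("run %d: boundaries must be strictly increasing in (0, T)", r))
    }
    if (ncol(object@statePatterns[[r]]) != length(b) + 1L) {
      return(sprintf("run %d: need one pattern per state", r))
    }
  }
  nv <- vapply(object@statePatterns, nrow, 1L)
  if (length(unique(nv)) > 1L) return("all state patterns must share a voxel count")
  if (any(object@coupling < 0 | object@coupling > 1)) {
    return("coupling fractions must lie in [0, 1]")
  }
  if (object@snr <= 0) return("snr must be positive")
  if (object@nSubjects < 1L) return("nSubjects must be >= 1")
  TRUE
})

#' StateSegmentation: result of greedy boundary search
#'
#' Ordered state-boundary positions for one run, the strength of each
#' boundary, the nested boundary sets recorded at every reached state count,
#' and (after [selectK()]) the data-driven choice of the number of states.
#'
#' Boundary value `b` means a new state starts at volume `b + 1` (1-based);
#' valid values lie strictly between 0 and the number of timepoints.
#'
#' @slot nTimepoints number of volumes in the run.
#' @slot boundaries strictly increasing integer boundary positions.
#' @slot strengths per-boundary strength in `[0, 2]` (1 minus the Pearson
#'   correlation of the flanking state-mean patterns); length 0 until
#'   computed.
#' @slot snapshots named list: for each reached state count `k`, the boundary
#'   set at that `k`.
#' @slot kSelected selected number of states (`NA` until [selectK()]).
#' @slot selectionCurve named numeric: per candidate `k`, the within-versus-
#'   between separation t-statistic.
#' @slot trSeconds repetition time in seconds.
#' @slot runId run label.
#' @export
setClass("StateSegmentation",
  representation(
    nTimepoints = "integer",
    boundaries = "integer",
    strengths = "numeric",
    snapshots = "list",
    kSelected = "integer",
    selectionCurve = "numeric",
    trSeconds = "numeric",
    runId = "character"
  ),
  prototype(kSelected = NA_integer_, strengths = numeric(0),
            selectionCurve = numeric(0), trSeconds = 2, runId = "run1")
)

setValidity("StateSegmentation", function(object) {
  b <- object@boundaries
  T <- object@nTimepoints
  if (length(b) && (any(b <= 0L) || any(b >= T) || any(diff(b) <= 0L))) {
    return("boundaries must be strictly increasing integers in (0, T)")
  }
  s <- object@strengths
  if (length(s) && length(s) != length(b)) {
    return("strengths must match boundaries in length (or be empty)")
  }
  if (length(s) && (any(s < 0) || any(s > 2 + 1e-12))) {
    return("strengths must lie in [0, 2]")
  }
  TRUE
})

#' BoundaryTimeline: per-volume boundary-strength vector
#'
#' A vector with one entry per fMRI volume: 0 where no neural state boundary
#' occurs, and the boundary strength (in `(0, 2]`) at volumes that open a new
#' state.
#'
#' @slot values numeric vector of length T.
#' @slot runId run label ("concat" for run-concatenated timelines).
#' @slot runLengths lengths of the constituent runs (a single value for one
#'   run).
#' @export
setClass("BoundaryTimeline",
  representation(values = "numeric", runId = "character",
                 runLengths = "integer"),
  prototype(runId = "run1")
)

setValidity("BoundaryTimeline", function(object) {
  v <- object@values
  if (any(!is.finite(v))) return("values must be finite")
  if (any(v < 0) || any(v > 2 + 1e-12)) return("values must be 0 or in (0, 2]")
  if (sum(object@runLengths) != length(v)) {
    return("runLengths must sum to length(values)")
  }
  TRUE
})

#' AnnotationTimeline: per-volume stimulus-change vector
#'
#' One annotation category sampled on the fMRI volume grid, after the
#' hemodynamic delay and volume binning.  Binary timelines mark volumes
#' containing at least one change; continuous timelines carry scaled change
#' magnitudes in `[0, 1]`.
#'
#' @slot values numeric vector of length T.
#' @slot category annotation category label (e.g. `"small_locations"`).
#' @slot group one of `"visual"`, `"locations"`, `"low_level_audio"`,
#'   `"mid_level_audio"`, `"conceptual"`.
#' @slot kind `"binary"` or `"continuous"`.
#' @slot runId run label ("concat" for concatenated timelines).
#' @slot runLengths lengths of the constituent runs.
#' @export
setClass("AnnotationTimeline",
  representation(values = "numeric", category = "character",
                 group = "character", kind = "character",
                 runId = "character", runLengths = "integer"),
  prototype(kind = "binary", group = "conceptual", runId = "run1")
)

.annotationGroups <- c("visual", "locations", "low_level_audio",
                       "mid_level_audio", "conceptual")

setValidity("AnnotationTimeline", function(object) {
  v <- object@values
  if (any(!is.finite(v))) return("values must be finite")
  if (!object@kind %in% c("binary", "continuous")) {
    return("kind must be 'binary' or 'continuous'")
  }
  if (object@kind == "binary" && !all(v %in% c(0, 1))) {
    return("binary timelines may contain only 0/1")
  }
  if (object@kind == "continuous" && (any(v < 0) || any(v > 1 + 1e-12))) {
    return("continuous timelines must lie in [0, 1]")
  }
  if (!object@group %in% .annotationGroups) {
    return(sprintf("group must be one of: %s",
                   paste(.annotationGroups, collapse = ", ")))
  }
  if (sum(object@runLengths) != length(v)) {
    return("runLengths must sum to length(values)")
  }
  TRUE
})

#' AnnotationTimeline constructor
#'
#' @param values per-volume numeric vector.
#' @param category category label.
#' @param group category group (see [AnnotationTimeline-class]).
#' @param kind `"binary"` or `"continuous"`.
#' @param runId run label.
#' @param runLengths run lengths; defaults to a single run.
#' @return An [AnnotationTimeline-class].
#' @export
AnnotationTimeline <- function(values, category, group = "conceptual",
                               kind = c("binary", "continuous"),
                               runId = "run1",
                               runLengths = length(values)) {
  kind <- match.arg(kind)
  new("AnnotationTimeline", values = as.numeric(values),
      category = as.character(category), group = group, kind = kind,
      runId = as.character(runId), runLengths = as.integer(runLengths))
}

#' CovariateLedger: which covariates correct each annotation
#'
#' Maps each annotation category of interest to the covariate categories that
#' are partialled out when testing its alignment with neural state
#' boundaries.  Categories belonging to the same group (which share the same
#' relevant information) never covary for each other, and no category covaries
#' for itself.
#'
#' @slot map named list: category -> character vector of covariate categories.
#' @slot groups named character: category -> group label.
#' @seealso [defaultCovariateLedger()] for the standard ledger.
#' @export
setClass("CovariateLedger",
  representation(map = "list", groups = "character")
)

setValidity("CovariateLedger", function(object) {
  for (cat in names(object@map)) {
    covs <- object@map[[cat]]
    if (cat %in% covs) {
      return(sprintf("category '%s' cannot covary for itself", cat))
    }
    g <- object@groups[[cat]]
    same <- names(object@groups)[object@groups == g]
    bad <- intersect(covs, setdiff(same, cat))
    if (length(bad)) {
      return(sprintf("category '%s' must not be corrected for same-group '%s'",
                     cat, bad[1]))
    }
    unknown <- setdiff(covs, names(object@groups))
    if (length(unknown)) {
      return(sprintf("covariate '%s' has no group assignment", unknown[1]))
    }
  }
  TRUE
})

#' AlignmentResult: partial correlation against the permutation null
#'
#' @slot category annotation category tested.
#' @slot rObserved observed partial correlation between the boundary timeline
#'   and the annotation timeline.
#' @slot nullSample permuted partial correlations.
#' @slot pOneTailed one-tailed p-value: the fraction of null values greater
#'   than or equal to the observed value.
#' @slot nPermutations number of permutations.
#' @slot pCorrected Bonferroni-corrected p (`NA` until [bonferroni()]).
#' @slot correctionFactor number of tests corrected for.
#' @slot seed seed used for the permutation stream.
#' @export
setClass("AlignmentResult",
  representation(
    category = "character",
    rObserved = "numeric",
    nullSample = "numeric",
    pOneTailed = "numeric",
    nPermutations = "integer",
    pCorrected = "numeric",
    correctionFactor = "integer",
    seed = "integer"
  ),
  prototype(pCorrected = NA_real_, correctionFactor = NA_integer_,
            seed = NA_integer_)
)

setValidity("AlignmentResult", function(object) {
  if (length(object@nullSample) != object@nPermutations) {
    return("nullSample length must equal nPermutations")
  }
  if (object@pOneTailed < 0 || object@pOneTailed > 1) {
    return("pOneTailed must lie in [0, 1]")
  }
  TRUE
})

#' SearchlightSet: spherical searchlights tiling a voxel mask
#'
#' @slot mask 3D logical array.
#' @slot centers integer matrix (n x 3) of center voxel coordinates (may lie
#'   on grid points outside the mask).
#' @slot members list: per searchlight, integer vector of linear array
#'   indices of its in-mask member voxels.
#' @slot radiusVoxels sphere radius in voxel units (boundary inclusive).
#' @slot spacingVoxels center grid spacing in voxels.
#' @slot minVoxels minimum member count for a searchlight to be kept.
#' @export
setClass("SearchlightSet",
  representation(
    mask = "array",
    centers = "matrix",
    members = "list",
    radiusVoxels = "numeric",
    spacingVoxels = "integer",
    minVoxels = "integer"
  )
)

setValidity("SearchlightSet", function(object) {
  if (nrow(object@centers) != length(object@members)) {
    return("one member list per center required")
  }
  if (length(object@members) &&
      any(vapply(object@members, length, 1L) < object@minVoxels)) {
    return("every searchlight must have at least minVoxels members")
  }
  TRUE
})

#' VoxelSignificanceMap: voxel-level aggregation of searchlight p-values
#'
#' @slot meanP 3D numeric array: per voxel, the mean p over covering
#'   searchlights; `NA` for voxels covered by no searchlight.
#' @slot significant 3D logical array; a voxel is significant only when its
#'   mean p is strictly below the FDR threshold.
#' @slot fdrThresholdP the highest p-value that survived the FDR correction
#'   (`NA` when none survived).
#' @export
setClass("VoxelSignificanceMap",
  representation(meanP = "array", significant = "array",
                 fdrThresholdP = "numeric")
)

#' RunConfig: parameters of one full pipeline run
#'
#' Bundles the simulation geometry and all analysis settings (delay, state
#' search, permutation counts, corrections) with a master seed so a pipeline
#' run is fully reproducible.  Create with [runConfig()].
#'
#' @slot params named list of settings (see [runConfig()]).
#' @export
setClass("RunConfig", representation(params = "list"))
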