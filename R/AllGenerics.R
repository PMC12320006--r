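# Accessor generics and show methods.

#' @describeIn VolumeSeries-class the voxels x timepoints matrix.
#' @param object a package object.
#' @export
setGeneric("seriesData", function(object) standardGeneric("seriesData"))
#' @export
setMethod("seriesData", "VolumeSeries", function(object) object@data)

#' @describeIn VolumeSeries-class repetition time in seconds.
#' @export
setGeneric("trSeconds", function(object) standardGeneric("trSeconds"))
#' @export
setMethod("trSeconds", "VolumeSeries", function(object) object@trSeconds)
#' @export
setMethod("trSeconds", "StateSegmentation", function(object) object@trSeconds)

#' @describeIn VolumeSeries-class run label.
#' @export
setGeneric("runId", function(object) standardGeneric("runId"))
#' @export
setMethod("runId", "VolumeSeries", function(object) object@runId)
#' @export
setMethod("runId", "StateSegmentation", function(object) object@runId)
#' @export
setMethod("runId", "BoundaryTimeline", function(object) object@runId)
#' @export
setMethod("runId", "AnnotationTimeline", function(object) object@runId)

#' @describeIn VolumeSeries-class subject label.
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @export
setMethod("subjectId", "VolumeSeries", function(object) object@subjectId)

#' @describeIn VolumeSeries-class number of volumes (timepoints).
#' @export
setGeneric("nVolumes", function(object) standardGeneric("nVolumes"))
#' @export
setMethod("nVolumes", "VolumeSeries", function(object) ncol(object@data))
#' @export
setMethod("nVolumes", "StateSegmentation", function(object) object@nTimepoints)
#' @export
setMethod("nVolumes", "BoundaryTimeline", function(object) length(object@values))
#' @export
setMethod("nVolumes", "AnnotationTimeline", function(object) length(object@values))

#' @describeIn VolumeSeries-class number of voxels.
#' @export
setGeneric("nVoxels", function(object) standardGeneric("nVoxels"))
#' @export
setMethod("nVoxels", "VolumeSeries", function(object) nrow(object@data))

#' @describeIn StateSegmentation-class boundary positions (volumes).
#' @param object a package object.
#' @export
setGeneric("boundaries", function(object) standardGeneric("boundaries"))
#' @export
setMethod("boundaries", "StateSegmentation", function(object) object@boundaries)
#' @export
setMethod("boundaries", "BoundaryTimeline",
          function(object) which(object@values > 0) - 1L)

#' @describeIn StateSegmentation-class per-boundary strengths.
#' @export
setGeneric("strengths", function(object) standardGeneric("strengths"))
#' @export
setMethod("strengths", "StateSegmentation", function(object) object@strengths)
#' @export
setMethod("strengths", "BoundaryTimeline",
          function(object) object@values[object@values > 0])

#' @describeIn StateSegmentation-class number of states implied by the
#'   current boundary set.
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))
#' @export
setMethod("nStates", "StateSegmentation",
          function(object) length(object@boundaries) + 1L)

#' @describeIn StateSegmentation-class selected number of states.
#' @export
setGeneric("kSelected", function(object) standardGeneric("kSelected"))
#' @export
setMethod("kSelected", "StateSegmentation", function(object) object@kSelected)

#' @describeIn StateSegmentation-class the per-k separation statistic curve.
#' @export
setGeneric("selectionCurve", function(object) standardGeneric("selectionCurve"))
#' @export
setMethod("selectionCurve", "StateSegmentation",
          function(object) object@selectionCurve)

#' Boundary set recorded at a given state count
#'
#' @param object a [StateSegmentation-class].
#' @param k state count whose snapshot to return.
#' @return Integer vector of boundary positions, or `NULL` when the greedy
#'   search skipped that count (a double-boundary iteration).
#' @export
setGeneric("snapshotAt", function(object, k) standardGeneric("snapshotAt"))
#' @export
setMethod("snapshotAt", "StateSegmentation", function(object, k) {
  object@snapshots[[as.character(k)]]
})

#' @describeIn AnnotationTimeline-class the per-volume values.
#' @export
setGeneric("timelineValues", function(object) standardGeneric("timelineValues"))
#' @export
setMethod("timelineValues", "BoundaryTimeline", function(object) object@values)
#' @export
setMethod("timelineValues", "AnnotationTimeline", function(object) object@values)

#' @describeIn AnnotationTimeline-class category label.
#' @export
setGeneric("category", function(object) standardGeneric("category"))
#' @export
setMethod("category", "AnnotationTimeline", function(object) object@category)
#' @export
setMethod("category", "AlignmentResult", function(object) object@category)

#' @describeIn AlignmentResult-class observed partial correlation.
#' @param object a package object.
#' @export
setGeneric("rObserved", function(object) standardGeneric("rObserved"))
#' @export
setMethod("rObserved", "AlignmentResult", function(object) object@rObserved)

#' @describeIn AlignmentResult-class one-tailed permutation p-value.
#' @export
setGeneric("pOneTailed", function(object) standardGeneric("pOneTailed"))
#' @export
setMethod("pOneTailed", "AlignmentResult", function(object) object@pOneTailed)

#' @describeIn AlignmentResult-class Bonferroni-corrected p-value.
#' @export
setGeneric("pCorrected", function(object) standardGeneric("pCorrected"))
#' @export
setMethod("pCorrected", "AlignmentResult", function(object) object@pCorrected)

#' @describeIn AlignmentResult-class the permutation null sample.
#' @export
setGeneric("nullSample", function(object) standardGeneric("nullSample"))
#' @export
setMethod("nullSample", "AlignmentResult", function(object) object@nullSample)

setMethod("show", "VolumeSeries", function(object) {
  cat(sprintf("VolumeSeries: %d voxels x %d volumes (TR %gs), run '%s', subject '%s'\n",
              nrow(object@data), ncol(object@data), object@trSeconds,
              object@runId, object@subjectId))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d run(s), %d voxels, snr %g, %d subjects, seed %d\n",
              length(object@runLengths), nrow(object@statePatterns[[1]]),
              object@snr, object@nSubjects, object@seed))
  for (r in seq_along(object@runLengths)) {
    cat(sprintf("  run %d: T = %d, %d states, boundaries: %s\n", r,
                object@runLengths[r], length(object@boundaries[[r]]) + 1L,
                paste(object@boundaries[[r]], collapse = " ")))
  }
  if (length(object@coupling)) {
    cat("  coupling:", paste(sprintf("%s=%g", names(object@coupling),
                                     object@coupling), collapse = ", "), "\n")
  }
})

setMethod("show", "StateSegmentation", function(object) {
  cat(sprintf("StateSegmentation: T = %d, %d boundaries (%d states)%s\n",
              object@nTimepoints, length(object@boundaries),
              length(object@boundaries) + 1L,
              if (is.na(object@kSelected)) ""
              else sprintf(", k selected = %d", object@kSelected)))
  cat("  boundaries:", paste(object@boundaries, collapse = " "), "\n")
  if (length(object@strengths)) {
    cat("  strengths:", paste(sprintf("%.3f", object@strengths),
                              collapse = " "), "\n")
  }
})

setMethod("show", "BoundaryTimeline", function(object) {
  cat(sprintf("BoundaryTimeline: %d volumes, %d boundaries, run '%s'\n",
              length(object@values), sum(object@values > 0), object@runId))
})

setMethod("show", "AnnotationTimeline", function(object) {
  cat(sprintf("AnnotationTimeline '%s' (%s, %s): %d volumes, %d nonzero\n",
              object@category, object@group, object@kind,
              length(object@values), sum(object@values > 0)))
})

setMethod("show", "CovariateLedger", function(object) {
  cat("CovariateLedger:\n")
  for (cat_ in names(object@map)) {
    cat(sprintf("  %s [%s] <- %s\n", cat_, object@groups[[cat_]],
                paste(object@map[[cat_]], collapse = ", ")))
  }
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("AlignmentResult '%s': r = %.4f, one-tailed p = %.4g (%d perms)%s\n",
              object@category, object@rObserved, object@pOneTailed,
              object@nPermutations,
              if (is.na(object@pCorrected)) ""
              else sprintf(", corrected p = %.4g", object@pCorrected)))
})

setMethod("show", "SearchlightSet", function(object) {
  ms <- vapply(object@members, length, 1L)
  cat(sprintf("SearchlightSet: %d searchlights (radius %g vox, spacing %d, min %d); members %d-%d (mean %.1f)\n",
              length(object@members), object@radiusVoxels,
              object@spacingVoxels, object@minVoxels,
              if (length(ms)) min(ms) else 0L,
              if (length(ms)) max(ms) else 0L,
              if (length(ms)) mean(ms) else 0))
})

setMethod("show", "VoxelSignificanceMap", function(object) {
  cat(sprintf("VoxelSignificanceMap: %d significant voxels (FDR threshold p %s)\n",
              sum(object@significant, na.rm = TRUE),
              if (is.na(object@fdrThresholdP)) "NA"
              else format(object@fdrThresholdP, digits = 4)))
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig:\n")
  p <- object@params
  for (nm in names(p)) {
    v <- p[[nm]]
    if (is.list(v)) v <- paste(sprintf("%s=%g", names(v), unlist(v)), collapse = ",")
    cat(sprintf("  %s: %s\n", nm, paste(format(v), collapse = " ")))
  }
})
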