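# Readers and writers for the plain-text and NIfTI interchange formats.

#' Read a voxels x time matrix from TSV
#'
#' @param path TSV file, voxels in rows, volumes in columns, no header.
#' @param trSeconds,runId,subjectId metadata for the result.
#' @return A [VolumeSeries-class].
#' @export
readVolumeSeriesTsv <- function(path, trSeconds = 2, runId = "run1",
                                subjectId = "group") {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  VolumeSeries(m, trSeconds = trSeconds, runId = runId, subjectId = subjectId)
}

#' Write a VolumeSeries as TSV
#'
#' @param series a [VolumeSeries-class].
#' @param path output file.
#' @export
writeVolumeSeriesTsv <- function(series, path) {
  utils::write.table(seriesData(series), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 4D NIfTI volume into a VolumeSeries
#'
#' Applies a 3D mask and flattens to voxels x time; the TR is taken from
#' the NIfTI header unless overridden.
#'
#' @param path 4D NIfTI file.
#' @param maskPath 3D mask NIfTI (nonzero = in mask).
#' @param trSeconds override the header TR.
#' @param runId,subjectId metadata.
#' @return A [VolumeSeries-class].
#' @export
readVolumeSeriesNifti <- function(path, maskPath, trSeconds = NULL,
                                  runId = "run1", subjectId = "group") {
  img <- RNifti::readNifti(path)
  msk <- RNifti::readNifti(maskPath)
  d <- dim(img)
  if (length(d) != 4L) stopf("expected a 4D NIfTI image")
  maskIdx <- which(as.array(msk) != 0)
  m <- matrix(as.array(img), prod(d[1:3]), d[4])[maskIdx, , drop = FALSE]
  if (is.null(trSeconds)) {
    pd <- RNifti::pixdim(img)
    trSeconds <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 2
  }
  VolumeSeries(m, trSeconds = trSeconds, runId = runId, subjectId = subjectId)
}

#' Write a VolumeSeries back into a masked 4D NIfTI
#'
#' @param series a [VolumeSeries-class] whose voxel order matches
#'   `which(mask != 0)`.
#' @param mask 3D array defining voxel placement.
#' @param path output file.
#' @export
writeVolumeSeriesNifti <- function(series, mask, path) {
  maskIdx <- which(mask != 0)
  X <- seriesData(series)
  if (length(maskIdx) != nrow(X)) stopf("mask voxel count does not match series")
  d <- c(dim(mask), ncol(X))
  arr <- array(0, d)
  for (t in seq_len(ncol(X))) {
    arr[maskIdx + prod(dim(mask)) * (t - 1)] <- X[, t]
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1, 1, 1, trSeconds(series))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a timeline as TSV with a JSON sidecar
#'
#' Writes columns `volume` (1-based) and `value`, plus `<path>.json` holding
#' category, group, kind and run lengths.
#'
#' @param timeline an [AnnotationTimeline-class] or [BoundaryTimeline-class].
#' @param path output TSV file.
#' @export
writeTimelineTsv <- function(timeline, path) {
  v <- timelineValues(timeline)
  utils::write.table(data.frame(volume = seq_along(v), value = v), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(runId = timeline@runId,
               runLengths = timeline@runLengths)
  if (is(timeline, "AnnotationTimeline")) {
    meta$category <- timeline@category
    meta$group <- timeline@group
    meta$kind <- timeline@kind
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a timeline TSV written by [writeTimelineTsv()]
#'
#' @param path the TSV file; the `<path>.json` sidecar restores metadata.
#' @return An [AnnotationTimeline-class] (when the sidecar carries a
#'   category) or [BoundaryTimeline-class].
#' @export
readTimelineTsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list(runId = "run1", runLengths = nrow(d))
  if (!is.null(meta$category)) {
    AnnotationTimeline(d$value, category = meta$category, group = meta$group,
                       kind = meta$kind, runId = meta$runId,
                       runLengths = meta$runLengths)
  } else {
    new("BoundaryTimeline", values = d$value, runId = meta$runId,
        runLengths = as.integer(meta$runLengths))
  }
}

#' Read a word table
#'
#' @param path TSV with columns `onset_s` and `duration_s`.
#' @return A data frame with non-decreasing onsets.
#' @export
readWordTable <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE)
  stopifnot(all(c("onset_s", "duration_s") %in% names(d)))
  if (any(d$duration_s <= 0)) stopf("word durations must be positive")
  d[order(d$onset_s), , drop = FALSE]
}

#' Read a button-press table
#'
#' @param path TSV with columns `subject` and `press_time_s`.
#' @return A data frame.
#' @export
readPressTable <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE)
  stopifnot(all(c("subject", "press_time_s") %in% names(d)))
  d
}

#' Write voxel significance maps as NIfTI
#'
#' Writes `<prefix>_meanp.nii.gz` (mean p per voxel; uncovered voxels
#' encoded as -1) and `<prefix>_sig.nii.gz` (0/1 significance).
#'
#' @param map a [VoxelSignificanceMap-class].
#' @param prefix output path prefix.
#' @export
writeVoxelMapNifti <- function(map, prefix) {
  mp <- map@meanP
  mp[is.na(mp)] <- -1
  RNifti::writeNifti(RNifti::asNifti(mp), paste0(prefix, "_meanp.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(map@significant),
                                           dim(map@significant))),
                     paste0(prefix, "_sig.nii.gz"))
  invisible(prefix)
}
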