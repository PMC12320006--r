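# Orchestration: z-scoring utility, run configuration, and the end-to-end
# pipeline from simulation (or loaded data) through segmentation,
# annotation building and alignment testing.

#' Z-score a run per voxel
#'
#' Scales every voxel's time course to mean 0 and SD 1 within the run.  The
#' population SD convention (divisor N) is the default and is recorded in
#' the pipeline manifest.
#'
#' @param series a [VolumeSeries-class].
#' @param sdType `"population"` (divisor N, default) or `"sample"`
#'   (divisor N - 1).
#' @return The z-scored [VolumeSeries-class].
#' @export
zscoreVolumeSeries <- function(series, sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  X <- seriesData(series)
  mu <- rowMeans(X)
  Xc <- X - mu
  s2 <- rowMeans(Xc^2)
  if (sdType == "sample") s2 <- s2 * ncol(X) / (ncol(X) - 1)
  if (any(s2 == 0)) {
    stopf("voxel %d has zero variance; cannot z-score", which(s2 == 0)[1])
  }
  series@data <- Xc / sqrt(s2)
  series
}

#' Pipeline run configuration
#'
#' Collects every parameter of a full synthetic pipeline run.  Defaults
#' follow the standard analysis settings: TR 2 s, hemodynamic delay 4.5 s,
#' maximum state count of half the run length, finetuning on, 10000
#' permutations, Bonferroni over `nTests` tests.
#'
#' @param runLengths volumes per run.
#' @param nStates planted states per run.
#' @param nVoxels voxels per region.
#' @param coupling named numeric: per-category coupling in `[0, 1]`.
#' @param snr signal-to-noise ratio of the simulation.
#' @param nSubjects simulated subjects (default 15).
#' @param trSeconds repetition time (default 2).
#' @param delaySeconds hemodynamic delay (default 4.5).
#' @param kMax maximum state count (`NULL`: half the volumes).
#' @param kPolicy `"select"` (data-driven state count, default) or
#'   `"planted"` (fix at the planted count).
#' @param finetune 0/1 boundary finetuning (default 1).
#' @param nPerm permutations per test (default 10000).
#' @param alpha significance level (default 0.05).
#' @param nTests Bonferroni correction factor (default 1).
#' @param excludedRuns integer run indices to drop from the analysis.
#' @param distractorRate off-boundary change rate (default 0.05).
#' @param coOccur covariate co-occurrence settings
#'   (see [simulateAnnotationSources()]).
#' @param analysisCategories categories to test (default: every ledger
#'   annotation of interest present in `coupling`).
#' @param seed master seed.
#' @param outputDir optional directory for result files.
#' @return A [RunConfig-class].
#' @export
runConfig <- function(runLengths, nStates, nVoxels, coupling, snr = 2,
                      nSubjects = 15, trSeconds = 2, delaySeconds = 4.5,
                      kMax = NULL, kPolicy = c("select", "planted"),
                      finetune = 1, nPerm = 10000, alpha = 0.05, nTests = 1,
                      excludedRuns = integer(0), distractorRate = 0.05,
                      coOccur = NULL, analysisCategories = NULL, seed = 1,
                      outputDir = NULL) {
  kPolicy <- match.arg(kPolicy)
  params <- list(
    runLengths = as.integer(runLengths), nStates = as.integer(nStates),
    nVoxels = as.integer(nVoxels), coupling = as.list(coupling), snr = snr,
    nSubjects = as.integer(nSubjects), trSeconds = trSeconds,
    delaySeconds = delaySeconds, kMax = kMax, kPolicy = kPolicy,
    finetune = finetune, nPerm = as.integer(nPerm), alpha = alpha,
    nTests = as.integer(nTests), excludedRuns = as.integer(excludedRuns),
    distractorRate = distractorRate, coOccur = coOccur,
    analysisCategories = analysisCategories, seed = as.integer(seed),
    outputDir = outputDir, sdConvention = "population")
  if (any(params$trSeconds <= 0)) stopf("trSeconds must be positive")
  if (params$delaySeconds < 0) stopf("delaySeconds must be non-negative")
  if (length(params$excludedRuns) &&
      any(!params$excludedRuns %in% seq_along(params$runLengths))) {
    stopf("excludedRuns must name valid run indices")
  }
  new("RunConfig", params = params)
}

#' Write a run configuration as YAML
#'
#' Serializes every parameter of a [RunConfig-class] to a plain-text YAML
#' file, so that a pipeline run is fully described by one file.
#'
#' @param config a [RunConfig-class].
#' @param path output YAML file.
#' @export
writeRunConfigYaml <- function(config, path) {
  stopifnot(is(config, "RunConfig"))
  yaml::write_yaml(config@params, path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Fields absent from the file take the [runConfig()] defaults.
#'
#' @param path YAML file written by [writeRunConfigYaml()] or by hand.
#' @return A validated [RunConfig-class].
#' @export
readRunConfigYaml <- function(path) {
  p <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  extra <- setdiff(names(p), c(known, "sdConvention"))
  if (length(extra)) stopf("unknown config field '%s'", extra[1])
  p$coupling <- unlist(p$coupling)
  do.call(runConfig, p[intersect(names(p), known)])
}

# group lookup with a conservative fallback
.groupOf <- function(cat) {
  if (cat %in% names(.defaultGroups)) .defaultGroups[[cat]] else "conceptual"
}

# Build per-run AnnotationTimelines from one category's raw sources.
.sourceToTimelines <- function(cat, perRun, runLengths, trSeconds,
                               delaySeconds) {
  lapply(seq_along(perRun), function(r) {
    src <- perRun[[r]]
    T <- runLengths[r]
    rid <- sprintf("run%d", r)
    grp <- .groupOf(cat)
    switch(src$kind,
      times = shiftAndBin(src$times, trSeconds, T, delaySeconds,
                          kind = "binary", category = cat, group = grp,
                          runId = rid),
      words = {
        ct <- speechChangeTimeline(src$table, trSeconds, T * trSeconds)
        shiftAndBin(as.numeric(ct), trSeconds, T, delaySeconds,
                    kind = "binary", category = cat, group = grp, runId = rid)
      },
      presses = {
        eb <- eventBoundaries(src$table)
        shiftAndBin(eb, trSeconds, T, delaySeconds, kind = "binary",
                    category = cat, group = grp, runId = rid)
      },
      frames = shiftAndBin(src$values, trSeconds, T, delaySeconds,
                           kind = "continuous", times = src$times,
                           category = cat, group = grp, runId = rid),
      stopf("unknown source kind '%s'", src$kind))
  })
}

#' Run the full pipeline on a synthetic dataset
#'
#' Simulates the configured ground truth, builds group-averaged z-scored
#' runs, segments each run into neural states, constructs the annotation
#' timelines (delayed, binned, concatenated, continuous categories scaled
#' to unit maximum over the concatenated runs), and tests the alignment of
#' every analysis category against the state-permutation null with its
#' ledger covariates, Bonferroni-corrected.
#'
#' All randomness derives from the config seed; rerunning the same config
#' reproduces the result bundle (and any written files) exactly.
#'
#' @param config a [RunConfig-class].
#' @return Invisibly, a list with elements `truth`, `segmentations`,
#'   `boundaryTimeline`, `annotations` (concatenated per category),
#'   `results` (per analysis category), and `manifest`.  When the config
#'   names an `outputDir`, results, timelines and the manifest are written
#'   there as JSON/TSV.
#' @export
runPipeline <- function(config) {
  stopifnot(is(config, "RunConfig"))
  p <- config@params
  truth <- simulateGroundTruth(
    p$runLengths, p$nStates, p$nVoxels, coupling = unlist(p$coupling),
    snr = p$snr, nSubjects = p$nSubjects, trSeconds = p$trSeconds,
    delaySeconds = p$delaySeconds, seed = p$seed)
  keptRuns <- setdiff(seq_along(p$runLengths), p$excludedRuns)

  segs <- lapply(keptRuns, function(r) {
    subjects <- simulateRun(truth, r)
    g <- zscoreVolumeSeries(groupAverage(subjects))
    if (p$kPolicy == "planted") {
      # capping the search at the planted count guarantees a snapshot there
      # (double-boundary iterations can otherwise skip a state count)
      kTrue <- length(truth@boundaries[[r]]) + 1L
      sg <- greedySegment(g, kMax = kTrue, finetune = p$finetune)
      segmentationAtK(sg, g, kTrue)
    } else {
      sg <- greedySegment(g, kMax = p$kMax, finetune = p$finetune)
      selectK(sg, g)
    }
  })
  boundaryTimeline <- concatenateRuns(lapply(segs, toTimeline))

  sources <- simulateAnnotationSources(
    truth, distractorRate = p$distractorRate, coOccur = p$coOccur,
    seed = p$seed)
  annotations <- lapply(names(sources), function(cat) {
    tls <- .sourceToTimelines(cat, sources[[cat]][keptRuns],
                              p$runLengths[keptRuns], p$trSeconds,
                              p$delaySeconds)
    tl <- concatenateRuns(tls)
    if (tl@kind == "continuous") tl <- scaleToUnitMax(tl)
    tl
  })
  names(annotations) <- names(sources)

  cats <- names(sources)
  ledger <- if (all(cats %in% names(.defaultGroups))) {
    defaultCovariateLedger(cats)
  } else NULL
  analysis <- p$analysisCategories
  if (is.null(analysis)) {
    analysis <- if (is.null(ledger)) cats else intersect(cats, names(ledger@map))
  }
  results <- lapply(seq_along(analysis), function(i) {
    cat <- analysis[[i]]
    permutationTest(segs, annotations[[cat]], ledger = ledger,
                    covariateTimelines = annotations[setdiff(cats, cat)],
                    nPerm = p$nPerm, seed = deriveSeed(p$seed, 900L, i))
  })
  names(results) <- analysis
  results <- bonferroni(results, p$nTests)

  manifest <- list(
    configHash = unname(.hashObject(p[setdiff(names(p), "outputDir")])),
    seed = p$seed,
    sdConvention = p$sdConvention,
    runsAnalyzed = keptRuns,
    parameters = p[setdiff(names(p), "outputDir")])

  bundle <- list(truth = truth, segmentations = segs,
                 boundaryTimeline = boundaryTimeline,
                 annotations = annotations, results = results,
                 manifest = manifest)
  if (!is.null(p$outputDir)) {
    manifest$outputs <- writePipelineOutputs(bundle, p$outputDir)
    bundle$manifest <- manifest
  }
  invisible(bundle)
}

# md5 of a canonical JSON serialization (no external digest dependency)
.hashObject <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tf)
  unname(tools::md5sum(tf))
}

.resultToList <- function(r) {
  list(category = r@category, r = r@rObserved, p = r@pOneTailed,
       pCorrected = r@pCorrected, correctionFactor = r@correctionFactor,
       nPermutations = r@nPermutations, seed = r@seed,
       nullMean = mean(r@nullSample), nullSd = stats::sd(r@nullSample),
       nullQ95 = unname(stats::quantile(r@nullSample, 0.95)))
}

#' Write pipeline outputs
#'
#' Serializes a [runPipeline()] bundle: segmentations and alignment results
#' as JSON, boundary and annotation timelines as TSV, plus a manifest
#' listing every written file with its checksum and the config hash.
#'
#' @param bundle result of [runPipeline()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of written file paths with md5 checksums.
#' @export
writePipelineOutputs <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  segJson <- lapply(bundle$segmentations, function(s) {
    list(runId = s@runId, nTimepoints = s@nTimepoints,
         boundaries = s@boundaries, strengths = s@strengths,
         kSelected = s@kSelected, selectionCurve = as.list(s@selectionCurve))
  })
  f <- file.path(dir, "segmentations.json")
  jsonlite::write_json(segJson, f, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, f)
  f <- file.path(dir, "results.json")
  jsonlite::write_json(lapply(bundle$results, .resultToList), f,
                       auto_unbox = TRUE, digits = NA)
  paths <- c(paths, f)
  f <- file.path(dir, "boundary_timeline.tsv")
  writeTimelineTsv(bundle$boundaryTimeline, f)
  paths <- c(paths, f)
  for (cat in names(bundle$annotations)) {
    f <- file.path(dir, sprintf("annotation_%s.tsv", cat))
    writeTimelineTsv(bundle$annotations[[cat]], f)
    paths <- c(paths, f)
  }
  sums <- tools::md5sum(paths)
  manifest <- c(bundle$manifest,
                list(files = lapply(seq_along(paths), function(i) {
                  list(path = basename(paths[i]), md5 = unname(sums[i]))
                })))
  f <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(stats::setNames(as.list(sums), basename(paths)))
}
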