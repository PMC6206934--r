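#' @include selfpaced.R io.R netmetrics.R
NULL

#' Pipeline configuration
#'
#' Bundles every tunable of the decoding pipeline with its default:
#' 0.35 s window step for cued decoding, 0.02 s for streaming, the
#' 3-cycle window criterion, 10 static features, 100 permutations, 30
#' bootstrap resamples, a 0.5 s switch segment at confidence threshold
#' 0.5, and 100 Monte-Carlo splits.
#'
#' @param sim a [simulationConfig()] describing the (synthetic) subject.
#' @param band brain rhythm the decoding runs in.
#' @param stepDecoding,stepStreaming window steps in seconds.
#' @param cycles cycle-criterion multiplier.
#' @param kStatic static feature count.
#' @param nRand,nBoot screening parameters.
#' @param switchWidth,switchThreshold switch segment width (s) and
#'   detection threshold.
#' @param nSplits Monte-Carlo splits of the self-paced evaluation.
#' @param seed master seed for every stage.
#' @return object of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(sim = simulationConfig(), band = "alpha1",
                           stepDecoding = 0.35, stepStreaming = 0.02,
                           cycles = 3, kStatic = 10, nRand = 100,
                           nBoot = 30, switchWidth = 0.5,
                           switchThreshold = 0.5, nSplits = 100, seed = 1) {
  num <- c(stepDecoding = stepDecoding, stepStreaming = stepStreaming,
           cycles = cycles, kStatic = kStatic, nRand = nRand,
           nBoot = nBoot, switchWidth = switchWidth,
           switchThreshold = switchThreshold, nSplits = nSplits)
  if (any(num <= 0)) stop("all pipeline parameters must be positive")
  if (!band %in% sim$bands$band) stop("unknown band: ", band)
  structure(list(sim = sim, band = band, stepDecoding = stepDecoding,
                 stepStreaming = stepStreaming, cycles = cycles,
                 kStatic = kStatic, nRand = nRand, nBoot = nBoot,
                 switchWidth = switchWidth,
                 switchThreshold = switchThreshold, nSplits = nSplits,
                 seed = seed),
            class = "pipelineConfig")
}

configAsList <- function(config) {
  out <- unclass(config)
  out$sim <- unclass(out$sim)
  out$sim$schedule <- unclass(out$sim$schedule)
  out
}

#' Run the full decoding pipeline on a synthetic subject
#'
#' End-to-end realization of the data-learning flow: simulate the subject,
#' decode statically (LOOCV with fold-wise feature selection), screen
#' temporally consistent couplings on the streaming sequences, train the
#' latency-specific SVM bank, assemble the time-lagged ensemble, train the
#' switch, and evaluate the self-paced detector over Monte-Carlo splits.
#' Every artifact written to \code{outDir} embeds the seed and the full
#' configuration that produced it; a rerun with the same configuration
#' reproduces every artifact bit-identically.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if missing); \code{NULL} skips
#'   writing.
#' @param verbose log stage summaries via [message()].
#' @return the report list (also written as \code{report.json}):
#'   static accuracy, selected couplings, accuracy curve, ensemble lags,
#'   FP/FN percentages.
#' @export
runPipeline <- function(config, outDir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipelineConfig"))
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  cfgList <- configAsList(config)
  seed <- config$seed

  say("[simulate] %d channels @ %g Hz, %d trials/class, seed %d",
      config$sim$nChannels, config$sim$fs, config$sim$nTrialsPerClass, seed)
  study <- makeStudyDataset(config$sim)
  if (!is.null(outDir)) {
    writeRecordingNative(study$mi, file.path(outDir, "mi"))
    writeRecordingNative(study$rest, file.path(outDir, "rest"))
    jsonlite::write_json(list(seed = seed, config = cfgList,
                              schedule = unclass(study$schedule)),
                         file.path(outDir, "schedule.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  say("[static] band %s, k = %d", config$band, config$kStatic)
  sets <- studyTrialSets(study, band = config$band)
  static <- loocvStaticAccuracy(staticPatterns(sets$left),
                                staticPatterns(sets$right),
                                k = config$kStatic)
  say("[static] LOOCV accuracy %.3f over %d folds", static$accuracy,
      static$nFolds)

  say("[stream] step %g s, screening nRand = %d, nBoot = %d",
      config$stepStreaming, config$nRand, config$nBoot)
  data <- selfPacedData(study, band = config$band,
                        step = config$stepStreaming)
  slicedL <- lapply(data$left, sliceSequence, cols = data$trainCols)
  slicedR <- lapply(data$right, sliceSequence, cols = data$trainCols)
  scr <- bootstrapSelect(slicedL, slicedR, nBoot = config$nBoot,
                         nRand = config$nRand, step = data$step,
                         seed = seed)
  say("[screen] %d couplings selected (threshold %.3f)",
      length(selectedPairs(scr)), scr@threshold)
  trs <- timeResolvedSvms(slicedL, slicedR, selectedPairs(scr))
  ens <- buildEnsemble(trs$accuracy, trs$bank, step = data$step,
                       window = trs$window)
  say("[ensemble] M = %d members at lags %s", length(ens@members),
      paste(ens@lags, collapse = ", "))

  say("[selfpaced] %d Monte-Carlo splits", config$nSplits)
  nTrain <- floor(config$sim$nTrialsPerClass / 2)
  mc <- monteCarloSelfPaced(data, nSplits = config$nSplits, seed = seed,
                            nTrain = nTrain,
                            nBoot = config$nBoot, nRand = config$nRand)
  say("[selfpaced] FP %.1f%%, FN %.1f%%", mc$fp, mc$fn)

  report <- list(seed = seed, config = cfgList,
                 static_accuracy = static$accuracy,
                 n_folds = static$nFolds,
                 selected_pairs = selectedPairs(scr),
                 accuracy_curve = trs$accuracy,
                 curve_times = trs$times,
                 ensemble_lags = as.integer(ens@lags),
                 ensemble_accuracy = ens@accuracy,
                 fp_percent = mc$fp, fn_percent = mc$fn)
  if (!is.null(outDir)) {
    writeSelection(scr, channelNames(sets$left),
                   file.path(outDir, "selection.json"), seed = seed,
                   config = cfgList)
    curveTab <- data.frame(time = trs$times, accuracy = trs$accuracy)
    writeLines(c(sprintf("# seed: %d", seed),
                 paste(names(curveTab), collapse = "\t"),
                 apply(curveTab, 1, function(r)
                   paste(format(r, trim = TRUE), collapse = "\t"))),
               file.path(outDir, "accuracy_curve.tsv"))
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
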