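#' @include synthdata.R
NULL

#' Write a recording in the native binary+sidecar format
#'
#' The native format is a raw little-endian float32 array in channel-major
#' order (\code{<path>.bin}) plus a JSON sidecar (\code{<path>.json})
#' holding the sampling rate, channel labels, event markers and array
#' shape. Designed for zero-dependency, reproducible fixture loading.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param path file stem; \code{.bin} and \code{.json} are appended.
#' @return \code{path}, invisibly.
#' @export
writeRecordingNative <- function(recording, path) {
  stopifnot(is(recording, "EEGRecording"))
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(t(recording@signal)), con, size = 4,
           endian = "little")
  sidecar <- list(format = "plvbci-native-v1",
                  fs = recording@fs,
                  channels = recording@channels,
                  n_channels = nrow(recording@signal),
                  n_samples = ncol(recording@signal),
                  dtype = "float32", byte_order = "little",
                  order = "channel-major",
                  events = recording@events)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

readRecordingNative <- function(path) {
  sidecarPath <- paste0(path, ".json")
  if (!file.exists(sidecarPath))
    stop("missing events/metadata sidecar: ", sidecarPath)
  meta <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
  for (f in c("fs", "channels", "n_channels", "n_samples"))
    if (is.null(meta[[f]]))
      stop("malformed native sidecar: missing field '", f, "'")
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  n <- meta$n_channels * meta$n_samples
  x <- readBin(con, numeric(), n = n, size = 4, endian = "little")
  if (length(x) != n)
    stop("truncated native data file: expected ", n, " samples")
  sig <- t(matrix(x, nrow = meta$n_samples, ncol = meta$n_channels))
  ev <- meta$events
  if (is.null(ev) || length(ev) == 0)
    ev <- data.frame(onset = numeric(), label = character(),
                     stringsAsFactors = FALSE)
  ev <- as.data.frame(ev)
  new("EEGRecording", signal = sig, fs = meta$fs,
      channels = as.character(meta$channels), events = ev)
}

# --- minimal EDF (16-bit, 1-second records) -------------------------------

edfPad <- function(x, width) strtrim(formatC(as.character(x), width = width,
                                             flag = "-"), width)

#' Write a recording as EDF
#'
#' Minimal European Data Format writer: one data record per second, all
#' channels at the recording's sampling rate, 16-bit samples scaled to the
#' per-channel physical range. Classic EDF carries no event annotations, so
#' events are written to a \code{<path>.events.json} sidecar which
#' [readRecording()] picks up again. The signal is truncated to whole
#' 1-second records.
#'
#' @param recording an \linkS4class{EEGRecording} with an integer sampling
#'   rate.
#' @param path output file path (conventionally \code{.edf}).
#' @return \code{path}, invisibly.
#' @export
writeEDF <- function(recording, path) {
  stopifnot(is(recording, "EEGRecording"))
  fs <- recording@fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  ns <- nrow(recording@signal)
  nRec <- floor(ncol(recording@signal) / fs)
  if (nRec < 1) stop("recording shorter than one EDF record")
  sig <- recording@signal[, seq_len(nRec * fs), drop = FALSE]
  # symmetric integer physical range per channel: short header fields that
  # survive the 8-character EDF formatting losslessly
  physMax <- pmax(ceiling(apply(abs(sig), 1, max)), 1)
  physMin <- -physMax
  digMin <- -32768; digMax <- 32767
  scale <- (physMax - physMin) / (digMax - digMin)
  dig <- round(sweep(sweep(sig, 1, physMin), 1, scale, "/")) + digMin
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(edfPad("0", 8),
                edfPad("plvbci synthetic subject", 80),
                edfPad("plvbci recording", 80),
                edfPad("01.01.26", 8), edfPad("00.00.00", 8),
                edfPad(256 + ns * 256, 8), edfPad("", 44),
                edfPad(nRec, 8), edfPad(1, 8), edfPad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  writeChar(paste0(vapply(recording@channels, edfPad, "", width = 16),
                   collapse = ""), con, eos = NULL)
  writeChar(strrep(edfPad("", 80), ns), con, eos = NULL)            # transducer
  writeChar(strrep(edfPad("uV", 8), ns), con, eos = NULL)           # dimension
  writeChar(paste0(vapply(as.character(physMin), edfPad, "", width = 8),
                   collapse = ""), con, eos = NULL)
  writeChar(paste0(vapply(as.character(physMax), edfPad, "", width = 8),
                   collapse = ""), con, eos = NULL)
  writeChar(strrep(edfPad(digMin, 8), ns), con, eos = NULL)
  writeChar(strrep(edfPad(digMax, 8), ns), con, eos = NULL)
  writeChar(strrep(edfPad("", 80), ns), con, eos = NULL)            # prefilter
  writeChar(strrep(edfPad(fs, 8), ns), con, eos = NULL)
  writeChar(strrep(edfPad("", 32), ns), con, eos = NULL)            # reserved
  for (r in seq_len(nRec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    block <- t(dig[, cols, drop = FALSE])  # per signal, contiguous samples
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  if (nrow(recording@events))
    jsonlite::write_json(recording@events, paste0(path, ".events.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readStr <- function(n) {
    raw <- readBin(con, "raw", n = n)
    trimws(rawToChar(raw))
  }
  version <- readStr(8)
  if (version != "0") stop("malformed EDF: unexpected version field '",
                           version, "'")
  readStr(80); readStr(80); readStr(8); readStr(8)
  headerBytes <- as.integer(readStr(8))
  readStr(44)
  nRec <- as.integer(readStr(8))
  recDur <- as.numeric(readStr(8))
  ns <- as.integer(readStr(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF: bad signal count field")
  labels <- vapply(seq_len(ns), function(i) readStr(16), "")
  readBin(con, "raw", n = ns * 80)  # transducer
  readBin(con, "raw", n = ns * 8)   # dimension
  physMin <- as.numeric(vapply(seq_len(ns), function(i) readStr(8), ""))
  physMax <- as.numeric(vapply(seq_len(ns), function(i) readStr(8), ""))
  digMin <- as.numeric(vapply(seq_len(ns), function(i) readStr(8), ""))
  digMax <- as.numeric(vapply(seq_len(ns), function(i) readStr(8), ""))
  readBin(con, "raw", n = ns * 80)  # prefilter
  nsPerRec <- as.integer(vapply(seq_len(ns), function(i) readStr(8), ""))
  readBin(con, "raw", n = ns * 32)  # reserved
  if (length(unique(nsPerRec)) != 1L)
    stop("mixed per-signal sampling rates are not supported")
  spr <- nsPerRec[1]
  fs <- spr / recDur
  scale <- (physMax - physMin) / (digMax - digMin)
  sig <- matrix(0, ns, nRec * spr)
  for (r in seq_len(nRec)) {
    block <- readBin(con, integer(), n = ns * spr, size = 2,
                     endian = "little")
    if (length(block) != ns * spr)
      stop("truncated EDF data record ", r)
    m <- matrix(block, nrow = spr, ncol = ns)
    sig[, ((r - 1L) * spr + 1L):(r * spr)] <-
      t(sweep(sweep(m, 2, digMin, "-"), 2, scale, "*") +
          matrix(physMin, spr, ns, byrow = TRUE))
  }
  evPath <- paste0(path, ".events.json")
  ev <- if (file.exists(evPath))
    as.data.frame(jsonlite::read_json(evPath, simplifyVector = TRUE))
  else data.frame(onset = numeric(), label = character(),
                  stringsAsFactors = FALSE)
  new("EEGRecording", signal = sig, fs = fs, channels = labels, events = ev)
}

#' Read a recording (native or EDF)
#'
#' @param path file stem (native) or file path (EDF).
#' @param format \code{"native"} or \code{"edf"}.
#' @return an \linkS4class{EEGRecording}.
#' @seealso [writeRecordingNative()], [writeEDF()]
#' @export
readRecording <- function(path, format = c("native", "edf")) {
  format <- match.arg(format)
  switch(format, native = readRecordingNative(path), edf = readEDF(path))
}

#' Write a connectivity tensor (trials x pairs x tau) with metadata
#'
#' Serializes the time-indexed connectivity of a trial collection into the
#' raw-float32-plus-JSON-sidecar container, recording band, step and window
#' metadata so the tensor round-trips losslessly at float32 precision.
#'
#' @param seqs list of \linkS4class{ConnectivitySequence}, one per trial.
#' @param path file stem.
#' @return \code{path}, invisibly.
#' @export
writeConnectivityTensor <- function(seqs, path) {
  arr <- sequenceArray(seqs)
  s1 <- seqs[[1]]
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(arr), con, size = 4, endian = "little")
  meta <- list(format = "plvbci-tensor-v1", dim = dim(arr),
               dim_names = c("trial", "pair", "tau"),
               band = s1@band, step = s1@step, window = s1@window,
               t0 = s1@t0, times = s1@times, channels = s1@channels,
               dtype = "float32", byte_order = "little")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a connectivity tensor written by [writeConnectivityTensor()]
#'
#' @param path file stem.
#' @return list of \linkS4class{ConnectivitySequence}.
#' @export
readConnectivityTensor <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  n <- prod(meta$dim)
  x <- readBin(con, numeric(), n = n, size = 4, endian = "little")
  arr <- array(x, dim = meta$dim)
  lapply(seq_len(meta$dim[1]), function(i)
    new("ConnectivitySequence", vecs = arr[i, , , drop = TRUE],
        step = meta$step, window = meta$window, band = meta$band,
        times = meta$times, t0 = meta$t0,
        channels = as.character(meta$channels)))
}

#' Save a selected-coupling list as JSON
#'
#' @param screening a \linkS4class{ScreeningResult}.
#' @param channels channel labels of the underlying montage.
#' @param path output JSON path.
#' @param seed,config provenance embedded in the artifact.
#' @return \code{path}, invisibly.
#' @export
writeSelection <- function(screening, channels, path, seed = NA,
                           config = NULL) {
  map <- pairIndexMap(length(channels))
  sel <- selectedPairs(screening)
  out <- list(selected = sel,
              pairs = lapply(sel, function(p)
                c(channels[map$i[p]], channels[map$j[p]])),
              profile = pairProfile(screening)[sel],
              threshold = screening@threshold,
              n_rand = screening@nRand, n_boot = screening@nBoot,
              seed = seed, config = config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
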