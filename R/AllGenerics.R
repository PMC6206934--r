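#' @include AllClasses.R
NULL

#' Sampling rate accessor
#' @param x an object holding sampled data.
#' @return sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Channel label accessor
#' @param x an object with channel metadata.
#' @return character vector of channel labels.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Event table accessor
#' @param x an \linkS4class{EEGRecording}.
#' @return data.frame with \code{onset} (s) and \code{label} columns.
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' Trial count accessor
#' @param x a \linkS4class{TrialSet}.
#' @return integer number of trials.
#' @export
setGeneric("trialCount", function(x) standardGeneric("trialCount"))

#' Trial class-label accessor
#' @param x a \linkS4class{TrialSet}.
#' @return character vector of per-trial labels.
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))

#' Vectorized upper triangle of a connectivity pattern
#'
#' Returns vec(W): the row-major upper triangle of the symmetric PLV matrix,
#' pairs ordered (1,2), (1,3), ..., (1,N), (2,3), ... as in [pairIndexMap()].
#'
#' @param x a \linkS4class{ConnectivityPattern} or a
#'   \linkS4class{ConnectivitySequence} (one column per window).
#' @return numeric vector of length N(N-1)/2, or a matrix for a sequence.
#' @export
setGeneric("vecW", function(x) standardGeneric("vecW"))

#' Signed-confidence prediction
#'
#' Evaluates a decoder on new patterns and returns signed confidences in
#' [-1, 1] (+ right / - left).
#'
#' @param object a fitted classifier.
#' @param newdata numeric matrix of patterns (rows) over the model's
#'   features, or a vector for a single pattern.
#' @return numeric vector of signed confidences.
#' @export
setGeneric("predictConfidence",
           function(object, newdata) standardGeneric("predictConfidence"))
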