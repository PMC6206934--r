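#' The canonical seven-band EEG rhythm table
#'
#' Band edges in Hz for the seven classical EEG rhythms: delta (1-4),
#' theta (4-8), alpha1 (8-10), alpha2 (10-13), beta1 (13-20), beta2 (20-30)
#' and gamma (30-45). Every band-specific analysis in the package refers to
#' bands by these names; the table can be overridden wherever a \code{bands}
#' argument is accepted.
#'
#' @param file optional path to a JSON file mapping band names to
#'   \code{[low, high]} edge pairs, overriding the defaults.
#' @return data.frame with columns \code{band}, \code{low}, \code{high}.
#' @examples
#' bandTable()
#' @export
bandTable <- function(file = NULL) {
  if (!is.null(file)) {
    raw <- jsonlite::read_json(file, simplifyVector = TRUE)
    tab <- data.frame(band = names(raw),
                      low = vapply(raw, function(x) x[[1]], numeric(1)),
                      high = vapply(raw, function(x) x[[2]], numeric(1)),
                      stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(
      band = c("delta", "theta", "alpha1", "alpha2", "beta1", "beta2", "gamma"),
      low  = c(1, 4, 8, 10, 13, 20, 30),
      high = c(4, 8, 10, 13, 20, 30, 45),
      stringsAsFactors = FALSE)
  }
  if (any(tab$low >= tab$high)) stop("band edges must satisfy low < high")
  if (anyDuplicated(tab$band)) stop("band names must be unique")
  rownames(tab) <- tab$band
  tab
}

#' Look up one band's edges
#'
#' @param band band name or a numeric length-2 vector of edges in Hz.
#' @param bands band table from [bandTable()].
#' @return numeric c(low, high) in Hz.
#' @export
bandEdges <- function(band, bands = bandTable()) {
  if (is.numeric(band)) {
    stopifnot(length(band) == 2L, band[1] < band[2])
    return(as.numeric(band))
  }
  if (!band %in% bands$band)
    stop("unknown band: ", band)
  as.numeric(bands[band, c("low", "high")])
}

#' Standard 10-10 montage labels
#'
#' The 61 scalp positions of the extended international 10-10 system used as
#' default channel labels by the simulator (ground and reference electrodes
#' are not part of the data channels).
#'
#' @param n number of labels requested; the first \code{n} montage positions
#'   are returned, or generic \code{chNN} labels beyond 61.
#' @return character vector of length \code{n}.
#' @export
montageLabels <- function(n = 61) {
  labs <- c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
            "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
            "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
            "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
            "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
            "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
            "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2")
  if (n <= length(labs)) labs[seq_len(n)]
  else c(labs, sprintf("ch%02d", seq.int(length(labs) + 1L, n)))
}
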