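## shared helpers: time/sample conversions and channel-kind bookkeeping

.kinds <- c("magnetometer", "gradiometer", "eog")

.unitForKind <- function(kind) {
  c(magnetometer = "T", gradiometer = "T/m", eog = "V")[kind]
}

## ms -> 1-based sample index under the package-wide rounding convention
.timeIndex <- function(ms, fs, t0) {
  idx <- round((ms - t0) * fs / 1000) + 1L
  as.integer(idx)
}

## inclusive sample index range for an interval c(a, b) in ms
.intervalIndex <- function(interval, fs, t0, nSamples, what = "interval") {
  stopifnot(length(interval) == 2L)
  i <- .timeIndex(interval[1L], fs, t0)
  j <- .timeIndex(interval[2L], fs, t0)
  if (j < i) stop(what, " is empty", call. = FALSE)
  if (i < 1L || j > nSamples)
    stop(what, " [", interval[1L], ", ", interval[2L],
         "] ms lies outside the epoch", call. = FALSE)
  seq.int(i, j)
}

#' Sample times of a time-resolved object
#'
#' @param x an object with a sampling rate and start time (`EpochSet`,
#'   `ERRCSet`, `SourceEstimate`, `SummarySeries`).
#' @return numeric vector of sample times in ms relative to stimulus onset.
#' @export
epochTimes <- function(x) {
  n <- if (is(x, "EpochSet")) dim(x@data)[3L]
       else if (is(x, "ERRCSet")) dim(x@coefficients)[3L]
       else if (is(x, "SourceEstimate")) ncol(x@values)
       else if (is(x, "SummarySeries")) length(x@values)
       else stop("no time base on this object")
  x@t0 + (seq_len(n) - 1L) * 1000 / x@fs
}

#' @rdname accessors
#' @export
samplingRate <- function(x) x@fs

#' Accessors for the pipeline containers
#'
#' `samplingRate` returns the sampling rate in Hz; `trialItems` the item id
#' per trial; `channelData` the channel metadata data.frame; `nTrials`,
#' `nChannels` and `nSources` the obvious counts; `seriesValues` the raw
#' numeric vector of a [SummarySeries-class].
#'
#' @param x a pipeline object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
trialItems <- function(x) {
  if (is(x, "DesignMatrix") || is(x, "EpochSet")) x@trialItems
  else stop("no trial items on this object")
}

#' @rdname accessors
#' @export
channelData <- function(x) x@channels

#' @rdname accessors
#' @export
nTrials <- function(x) {
  if (is(x, "EpochSet")) dim(x@data)[1L]
  else if (is(x, "DesignMatrix")) nrow(x@X)
  else stop("no trials on this object")
}

#' @rdname accessors
#' @export
nChannels <- function(x) nrow(x@channels)

#' @rdname accessors
#' @export
nSources <- function(x) {
  if (is(x, "LeadField")) ncol(x@gain)
  else if (is(x, "SourceEstimate")) nrow(x@values)
  else if (is(x, "InverseOperator")) nrow(x@M)
  else stop("no sources on this object")
}

#' @rdname accessors
#' @export
seriesValues <- function(x) {
  stopifnot(is(x, "SummarySeries"))
  x@values
}

#' Build channel metadata
#'
#' Units are implied by the channel kind: magnetometers measure field in T,
#' planar gradiometers field gradient in T/m, EOG voltage in V.
#'
#' @param names channel names.
#' @param kinds one of `"magnetometer"`, `"gradiometer"`, `"eog"` per channel
#'   (recycled if scalar).
#' @return data.frame with columns `name`, `kind`, `unit`.
#' @export
channelInfo <- function(names, kinds) {
  kinds <- rep_len(kinds, length(names))
  if (!all(kinds %in% .kinds))
    stop("unknown channel kind; use one of ",
         paste(.kinds, collapse = ", "))
  data.frame(name = as.character(names), kind = kinds,
             unit = unname(.unitForKind(kinds)),
             stringsAsFactors = FALSE)
}

## logical index of channels entering regression / source analysis
.analysisChannels <- function(channels) channels$kind != "eog"
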