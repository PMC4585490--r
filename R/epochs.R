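#' Construct an EpochSet
#'
#' @param data numeric array `[trials, channels, samples]` in channel-native
#'   units.
#' @param channels channel metadata from [channelInfo].
#' @param fs sampling rate (Hz).
#' @param t0 time of the first sample (ms relative to stimulus onset).
#' @param trialItems item id per trial; defaults to `"trial<i>"` labels.
#' @return an [EpochSet-class].
#' @export
epochSet <- function(data, channels, fs, t0,
                     trialItems = paste0("trial", seq_len(dim(data)[1L]))) {
  new("EpochSet", data = data, channels = channels, fs = fs, t0 = t0,
      trialItems = as.character(trialItems))
}

#' @rdname accessors
#' @export
epochData <- function(x) {
  stopifnot(is(x, "EpochSet"))
  x@data
}

## forward-backward filtering of one vector with odd-reflect edge padding
.filtfilt1 <- function(flt, x) {
  n <- length(x)
  np <- min(n - 1L, 3L * (max(length(flt$a), length(flt$b)) - 1L))
  pre <- 2 * x[1L] - x[(np + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - np)]
  y <- c(pre, x, post)
  y <- as.numeric(signal::filter(flt, y))
  y <- rev(as.numeric(signal::filter(flt, rev(y))))
  y[(np + 1L):(np + n)]
}

.bandpassMatrix <- function(x, lo, hi, fs, order = 4L) {
  ny <- fs / 2
  if (hi >= ny) stop("upper edge must be below the Nyquist frequency ", ny)
  if (lo < 0 || lo >= hi) stop("need 0 <= lo < hi")
  filters <- list(signal::butter(order, hi / ny, type = "low"))
  if (lo > 0)
    filters <- c(filters, list(signal::butter(order, lo / ny, type = "high")))
  for (flt in filters)
    x <- t(apply(x, 1L, .filtfilt1, flt = flt))
  x
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth sections (high-pass at `lo`, low-pass at `hi`)
#' applied forward-backward, giving zero phase shift so response latencies
#' are not distorted. Edges are handled by odd-reflect padding. With
#' `lo = 0` only the low-pass is applied. The operation is linear.
#'
#' @param x a channels-by-samples numeric matrix or an [EpochSet-class]
#'   (every trial filtered).
#' @param lo,hi band edges in Hz, `0 <= lo < hi < fs/2`.
#' @param fs sampling rate (ignored for `EpochSet`, which carries its own).
#' @param order Butterworth section order (default 4).
#' @return same type as `x`.
#' @export
bandpass <- function(x, lo, hi, fs = NULL, order = 4L) {
  if (is(x, "EpochSet")) {
    d <- x@data
    for (tr in seq_len(dim(d)[1L]))
      d[tr, , ] <- .bandpassMatrix(d[tr, , , drop = TRUE], lo, hi, x@fs,
                                   order)
    x@data <- d
    return(x)
  }
  if (is.null(fs)) stop("fs required for matrix input")
  .bandpassMatrix(as.matrix(x), lo, hi, fs, order)
}

#' Segment continuous data into stimulus-locked epochs
#'
#' Per event at sample index `e`, samples `e + round(tmin*fs/1000)` through
#' `e + round(tmax*fs/1000)` are extracted, both endpoints included — so
#' -100..500 ms at 1000 Hz gives 601 samples. Events whose window exceeds
#' the recording are skipped with a warning.
#'
#' @param continuous channels-by-samples numeric matrix.
#' @param events 1-based sample indices of stimulus onsets.
#' @param tmin,tmax epoch window in ms relative to each event.
#' @param fs sampling rate (Hz).
#' @param channels channel metadata from [channelInfo].
#' @param trialItems item id per event (skipped events are dropped from it).
#' @return an [EpochSet-class] with `t0 = tmin`.
#' @export
segmentEpochs <- function(continuous, events, tmin, tmax, fs, channels,
                          trialItems = paste0("trial", seq_along(events))) {
  stopifnot(tmin < tmax)
  off1 <- as.integer(round(tmin * fs / 1000))
  off2 <- as.integer(round(tmax * fs / 1000))
  ns <- off2 - off1 + 1L
  total <- ncol(continuous)
  ok <- (events + off1 >= 1L) & (events + off2 <= total)
  if (any(!ok))
    warning("skipping ", sum(!ok), " event(s) whose window exceeds the ",
            "recording: ", paste(which(!ok), collapse = ", "))
  events <- events[ok]
  if (!length(events)) stop("no valid events")
  data <- array(0, dim = c(length(events), nrow(continuous), ns))
  for (i in seq_along(events))
    data[i, , ] <- continuous[, (events[i] + off1):(events[i] + off2)]
  epochSet(data, channels, fs, t0 = off1 * 1000 / fs,
           trialItems = trialItems[ok])
}

#' Default peak-to-peak rejection thresholds
#'
#' 2500 fT for magnetometers, 1000 fT/cm for gradiometers and 150 µV for
#' EOG, expressed in the channel-native SI units (T, T/m, V).
#'
#' @return named numeric vector of thresholds by channel kind.
#' @export
defaultRejection <- function() {
  c(magnetometer = 2500e-15, gradiometer = 1000e-13, eog = 150e-6)
}

#' Reject epochs on peak-to-peak amplitude
#'
#' An epoch is dropped iff any channel's max - min within the window exceeds
#' the threshold for that channel's kind. EOG channels take part in
#' rejection (they exist for exactly this purpose) even though they are
#' excluded from regression and source analysis.
#'
#' @param epochs an [EpochSet-class].
#' @param thresholds named positive limits per channel kind in native units;
#'   kinds without a threshold are not checked. Default [defaultRejection].
#' @param window ms interval checked; default the full epoch.
#' @return list with `epochs` (survivors) and `log`, a data.frame with one
#'   row per input epoch: `trial`, `item`, `kept`, `channel` (first offender
#'   or NA) and `p2p` (its peak-to-peak amplitude).
#' @export
rejectEpochs <- function(epochs, thresholds = defaultRejection(),
                         window = NULL) {
  stopifnot(all(thresholds > 0))
  d <- dim(epochs@data)
  if (is.null(window)) {
    sel <- seq_len(d[3L])
  } else {
    sel <- .intervalIndex(window, epochs@fs, epochs@t0, d[3L],
                          "rejection window")
  }
  lim <- unname(thresholds[epochs@channels$kind])  # NA where unchecked
  kept <- logical(d[1L])
  offCh <- rep(NA_character_, d[1L])
  offP2p <- rep(NA_real_, d[1L])
  for (tr in seq_len(d[1L])) {
    seg <- epochs@data[tr, , sel, drop = FALSE]
    dim(seg) <- c(d[2L], length(sel))
    p2p <- apply(seg, 1L, function(v) max(v) - min(v))
    bad <- which(!is.na(lim) & p2p > lim)
    kept[tr] <- length(bad) == 0L
    if (length(bad)) {
      offCh[tr] <- epochs@channels$name[bad[1L]]
      offP2p[tr] <- p2p[bad[1L]]
    }
  }
  log <- data.frame(trial = seq_len(d[1L]), item = epochs@trialItems,
                    kept = kept, channel = offCh, p2p = offP2p,
                    stringsAsFactors = FALSE)
  if (!any(kept)) warning("all epochs rejected")
  epochs@data <- epochs@data[kept, , , drop = FALSE]
  epochs@trialItems <- epochs@trialItems[kept]
  list(epochs = epochs, log = log)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline interval.
#' Idempotent and required before computing regression coefficients.
#'
#' @param epochs an [EpochSet-class].
#' @param interval baseline in ms, default the 100 ms before onset.
#' @return the corrected [EpochSet-class].
#' @export
baselineCorrect <- function(epochs, interval = c(-100, 0)) {
  d <- dim(epochs@data)
  sel <- .intervalIndex(interval, epochs@fs, epochs@t0, d[3L], "baseline")
  bl <- apply(epochs@data[, , sel, drop = FALSE], c(1L, 2L), mean)
  epochs@data <- epochs@data - array(bl, dim = d)  # bl recycles over samples
  epochs
}
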