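#' Build the linear estimator G from a design matrix
#'
#' Solving `y = X b` by least squares gives `b = G y` with
#' `G = (X'X)^{-1} X'`, computed here through a rank-revealing SVD
#' pseudoinverse. Each row of G holds per-trial weights, so every
#' coefficient is a weighted average of trials: for an intercept-only design
#' the weights are `1/n` (the plain evoked average), and for a binary
#' factorial design they reduce to the `1/n` vs `-1/m` contrast (see
#' [factorialWeights]).
#'
#' Singular values below `tol` times the largest are treated as zero and
#' reported as a rank-deficiency error naming the collinear columns, rather
#' than silently returning minimum-norm coefficients.
#'
#' @param design a [DesignMatrix-class] with at least as many trials as columns.
#' @param tol relative singular-value tolerance, default `1e-10`.
#' @return a [LinearEstimator-class].
#' @export
linearEstimator <- function(design, tol = 1e-10) {
  X <- design@X
  if (nrow(X) < ncol(X))
    stop("need at least as many trials as design columns")
  sv <- svd(X)
  keep <- sv$d > tol * sv$d[1L]
  if (!all(keep)) {
    qrX <- qr(X)
    dep <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("design matrix is rank-deficient; collinear column(s): ",
         paste(dep, collapse = ", "))
  }
  G <- sv$v %*% (t(sv$u) / sv$d)
  rownames(G) <- colnames(X)
  new("LinearEstimator", G = G, design = design)
}

#' Compute event-related regression coefficients (ERRCs)
#'
#' For every channel and latency, the across-trial measurement vector y is
#' regressed on the design: `b = G y`. The result is identical to fitting
#' ordinary least squares independently at each (channel, sample) point, but
#' is obtained with a single matrix product. Epochs should be
#' baseline-corrected first ([baselineCorrect]); EOG channels are excluded.
#'
#' @param epochs a baseline-corrected [EpochSet-class].
#' @param design a [DesignMatrix-class] or [LinearEstimator-class] whose
#'   trials match `epochs` in number, order and item identity.
#' @return an [ERRCSet-class] with one coefficient plane per design column.
#' @export
computeERRC <- function(epochs, design) {
  est <- if (is(design, "LinearEstimator")) design
         else linearEstimator(design)
  dm <- est@design
  d <- dim(epochs@data)
  if (d[1L] != nrow(dm@X))
    stop("trial count mismatch: ", d[1L], " epochs vs ", nrow(dm@X),
         " design rows")
  if (!identical(epochs@trialItems, dm@trialItems))
    stop("trial item sequence of epochs and design differ")
  keep <- .analysisChannels(epochs@channels)
  Y <- epochs@data[, keep, , drop = FALSE]
  dk <- dim(Y)
  dim(Y) <- c(dk[1L], dk[2L] * dk[3L])
  B <- est@G %*% Y
  dim(B) <- c(nrow(est@G), dk[2L], dk[3L])
  dimnames(B) <- list(rownames(est@G),
                      epochs@channels$name[keep], NULL)
  new("ERRCSet",
      coefficients = B,
      predictors = rownames(est@G),
      channels = epochs@channels[keep, , drop = FALSE],
      fs = epochs@fs, t0 = epochs@t0)
}

#' @rdname accessors
#' @export
errcCoefficients <- function(x) {
  stopifnot(is(x, "ERRCSet"))
  x@coefficients
}

#' Trial weights of the binary factorial special case
#'
#' A two-condition subtraction design is the special case of regression in
#' which the first category's trials are weighted `1/n` and the second's
#' `-1/m`; applying the weights to data yields the condition-mean
#' difference.
#'
#' @param n,m trial counts of the two categories, both at least 1.
#' @return numeric weight vector of length `n + m`.
#' @examples
#' factorialWeights(3, 2)
#' @export
factorialWeights <- function(n, m) {
  stopifnot(n >= 1L, m >= 1L)
  c(rep(1 / n, n), rep(-1 / m, m))
}

#' Per-channel SNR time courses
#'
#' Divides each channel's amplitude series by that channel's SD over the
#' baseline interval. This renders magnetometers (T) and gradiometers (T/m)
#' unitless and mutually comparable, and makes the result invariant to
#' rescaling any single channel. Over the baseline itself the SNR values
#' have SD 1 by construction.
#'
#' @param series channels-by-samples numeric matrix of amplitudes (e.g. one
#'   predictor's ERRC plane).
#' @param fs,t0 time base of `series`.
#' @param baseline ms interval over which the noise SD is estimated.
#' @param channelNames optional names used in error messages.
#' @return channels-by-samples matrix of SNR values.
#' @export
snrTimecourse <- function(series, fs, t0, baseline = c(-100, 0),
                          channelNames = rownames(series)) {
  series <- as.matrix(series)
  sel <- .intervalIndex(baseline, fs, t0, ncol(series), "baseline")
  sigma <- apply(series[, sel, drop = FALSE], 1L, stats::sd)
  zero <- which(sigma == 0)
  if (length(zero))
    stop("zero baseline SD on channel(s): ",
         paste(if (is.null(channelNames)) zero else channelNames[zero],
               collapse = ", "))
  series / sigma
}

#' RMS across channels of per-channel SNR
#'
#' `value(t) = sqrt(mean_c SNR_c(t)^2)` — the standard unitless summary of
#' multichannel response strength over time when sensor types with different
#' units are combined.
#'
#' @param snr channels-by-samples matrix (EOG channels must already be
#'   excluded).
#' @param fs,t0 time base.
#' @return a [SummarySeries-class].
#' @export
rmsAcrossChannels <- function(snr, fs, t0) {
  snr <- as.matrix(snr)
  if (nrow(snr) < 1L) stop("need at least one channel")
  new("SummarySeries", values = sqrt(colMeans(snr^2)), fs = fs, t0 = t0,
      kind = "snr_rms")
}

#' SNR-RMS summary curves of an ERRCSet
#'
#' Convenience wrapper: for each coefficient, compute per-channel SNR using
#' that coefficient's own baseline segment, then the RMS across channels.
#'
#' @param errc an [ERRCSet-class].
#' @param baseline ms interval for the noise SD.
#' @return named list of [SummarySeries-class], one per coefficient.
#' @export
errcSnrRms <- function(errc, baseline = c(-100, 0)) {
  out <- lapply(seq_along(errc@predictors), function(p) {
    plane <- errc@coefficients[p, , , drop = TRUE]
    dim(plane) <- dim(errc@coefficients)[2:3]
    snr <- snrTimecourse(plane, errc@fs, errc@t0, baseline,
                         channelNames = errc@channels$name)
    rmsAcrossChannels(snr, errc@fs, errc@t0)
  })
  stats::setNames(out, errc@predictors)
}

#' Find peaks of a summary series
#'
#' Local maxima within the window whose prominence is at least
#' `minProminence` times the series maximum, returned sorted by latency.
#' Prominence is the height of a peak above the higher of the two minima
#' separating it from the nearest taller point (or window edge) on each
#' side.
#'
#' @param series a [SummarySeries-class] or numeric vector.
#' @param window ms interval searched; default 0-300 ms, the pre-articulatory
#'   range a naming epoch can be analyzed in.
#' @param minProminence fraction of the series maximum, default 0.25.
#' @param fs,t0 time base, required when `series` is a bare vector.
#' @return numeric vector of peak latencies in ms (possibly empty).
#' @export
findPeaks <- function(series, window = c(0, 300), minProminence = 0.25,
                      fs = NULL, t0 = NULL) {
  if (is(series, "SummarySeries")) {
    v <- series@values; fs <- series@fs; t0 <- series@t0
  } else {
    v <- as.numeric(series)
    if (is.null(fs) || is.null(t0)) stop("fs and t0 required for vectors")
  }
  sel <- .intervalIndex(window, fs, t0, length(v), "peak window")
  w <- v[sel]
  n <- length(w)
  if (n < 3L) return(numeric(0L))
  peaks <- integer(0L)
  for (i in 2L:(n - 1L)) {
    if (w[i] > w[i - 1L] && w[i] > w[i + 1L]) peaks <- c(peaks, i)
  }
  if (!length(peaks)) return(numeric(0L))
  prom <- vapply(peaks, function(i) {
    left <- w[seq_len(i - 1L)]
    higher <- which(left > w[i])
    base1 <- min(left[seq.int(if (length(higher)) max(higher) else 1L,
                              i - 1L)])
    right <- w[seq.int(i + 1L, n)]
    higher <- which(right > w[i])
    base2 <- min(right[seq_len(if (length(higher)) min(higher) else
                               length(right))])
    w[i] - max(base1, base2)
  }, numeric(1L))
  keep <- prom >= minProminence * max(v)
  latencies <- t0 + (sel[peaks[keep]] - 1L) * 1000 / fs
  sort(latencies)
}
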