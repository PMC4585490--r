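#' Construct a LeadField
#'
#' @param gain channels-by-sources numeric matrix (channel-native units per
#'   unit source amplitude; fixed source orientations, one signed scalar per
#'   source).
#' @param channels channel metadata from [channelInfo].
#' @param sourcePos numeric matrix of source positions, one row per source.
#' @return a [LeadField-class].
#' @export
leadField <- function(gain, channels, sourcePos) {
  new("LeadField", gain = gain, channels = channels,
      sourcePos = as.matrix(sourcePos))
}

#' Estimate the baseline noise covariance
#'
#' Empirical channel covariance pooled over trials and baseline samples.
#' Within each trial the per-channel mean over the baseline is removed, the
#' outer products are accumulated, and the pooled sum is divided by the
#' total degrees of freedom `trials * (samples - 1)`. Diagonal loading of
#' `loading` times the mean diagonal is added for small-sample stability.
#'
#' @param x an [EpochSet-class] (baseline taken from `interval`) or a
#'   `[trials, channels, samples]` array of baseline segments.
#' @param interval baseline ms interval, default -100..0 (used for
#'   `EpochSet` input). The analysis channels (non-EOG) are used.
#' @param loading diagonal loading fraction, default 0.1.
#' @return a [NoiseCovariance-class].
#' @export
noiseCovariance <- function(x, interval = c(-100, 0), loading = 0.1) {
  stopifnot(loading >= 0)
  if (is(x, "EpochSet")) {
    keep <- .analysisChannels(x@channels)
    sel <- .intervalIndex(interval, x@fs, x@t0, dim(x@data)[3L], "baseline")
    seg <- x@data[, keep, sel, drop = FALSE]
    channels <- x@channels[keep, , drop = FALSE]
  } else {
    seg <- x
    stopifnot(length(dim(seg)) == 3L)
    channels <- channelInfo(paste0("ch", seq_len(dim(seg)[2L])),
                            "magnetometer")
  }
  d <- dim(seg)
  if (d[3L] < 2L) stop("need at least 2 baseline samples")
  C <- matrix(0, d[2L], d[2L])
  for (tr in seq_len(d[1L])) {
    M <- seg[tr, , , drop = FALSE]
    dim(M) <- d[2:3]
    M <- M - rowMeans(M)
    C <- C + tcrossprod(M)
  }
  C <- C / (d[1L] * (d[3L] - 1L))
  C <- C + diag(loading * mean(diag(C)), d[2L])
  dimnames(C) <- list(channels$name, channels$name)
  new("NoiseCovariance", Cmat = C, nSamples = as.integer(d[1L] * d[3L]),
      loading = loading, channels = channels)
}

#' Whitening transform of a noise covariance
#'
#' From the eigendecomposition `C = U L U'`, `W = L^{-1/2} U'` with
#' eigenvalues below `rankTol` times the largest truncated (their rows
#' dropped), so that `W C W'` is the identity on the retained subspace.
#'
#' @param cov a [NoiseCovariance-class] (or bare PSD matrix).
#' @param rankTol relative eigenvalue truncation threshold, default `1e-8`.
#' @return matrix with one row per retained component, `ncol = channels`.
#' @export
whitener <- function(cov, rankTol = 1e-8) {
  C <- if (is(cov, "NoiseCovariance")) cov@Cmat else as.matrix(cov)
  eg <- eigen(C, symmetric = TRUE)
  keep <- eg$values > rankTol * eg$values[1L]
  if (!any(keep)) stop("all eigenvalues truncated; covariance is degenerate")
  t(eg$vectors[, keep, drop = FALSE]) / sqrt(eg$values[keep])
}

#' Assemble a regularized L2 minimum-norm inverse operator
#'
#' The lead field is whitened (`Lw = W L`), the source prior is the identity
#' scaled so that `trace(Lw R Lw') = n` whitened channels, and the
#' regularization is `lambda2 = 1 / snr^2` (the conventional SNR-based
#' choice; `snr = 3` implies about 10% residual variance). The kernel is
#'
#'   `M = R Lw' (Lw R Lw' + lambda2 I)^{-1} W`
#'
#' The per-source dSPM norms are the noise SDs of the source estimates under
#' whitened unit noise, i.e. the row norms of the kernel before the final
#' whitener is folded in.
#'
#' @param lf a [LeadField-class].
#' @param cov a [NoiseCovariance-class] on the same channels.
#' @param snr assumed amplitude SNR, default 3.
#' @param rankTol eigenvalue truncation for the whitener.
#' @return an [InverseOperator-class].
#' @export
makeInverse <- function(lf, cov, snr = 3, rankTol = 1e-8) {
  stopifnot(snr > 0)
  if (nrow(lf@gain) != nrow(cov@Cmat))
    stop("lead field and covariance channel counts differ")
  zero <- which(colSums(abs(lf@gain)) == 0)
  if (length(zero))
    stop("degenerate lead field: zero gain column(s) ",
         paste(zero, collapse = ", "))
  W <- whitener(cov, rankTol)
  Lw <- W %*% lf@gain
  nw <- nrow(Lw)
  sigma2 <- nw / sum(Lw^2)          # trace(Lw R Lw') = nw with R = sigma2 I
  lambda2 <- 1 / snr^2
  A <- sigma2 * tcrossprod(Lw) + diag(lambda2, nw)
  Mw <- sigma2 * t(Lw) %*% solve(A) # sources x whitened channels
  dspm <- sqrt(rowSums(Mw^2))
  new("InverseOperator", M = Mw %*% W, lambda2 = lambda2, whitener = W,
      sigma2 = sigma2, dspmNorms = dspm, channels = lf@channels)
}

#' Apply an inverse operator to sensor data
#'
#' `values = M data`; the `dspm` flavor additionally divides each source row
#' by its noise SD ([makeInverse]), yielding unitless noise-normalized
#' values. The operation is linear in the data, so the inverse of an ERRC
#' equals the ERRC of source-projected trials.
#'
#' @param op an [InverseOperator-class].
#' @param data channels-by-samples matrix, or an [ERRCSet-class] (one
#'   estimate per coefficient).
#' @param flavor `"dspm"` (default) or `"mne_amplitude"`.
#' @param fs,t0 time base for matrix input.
#' @return a [SourceEstimate-class], or a named list of them for `ERRCSet`
#'   input.
#' @export
applyInverse <- function(op, data, flavor = c("dspm", "mne_amplitude"),
                         fs = NULL, t0 = NULL) {
  flavor <- match.arg(flavor)
  if (is(data, "ERRCSet")) {
    if (nrow(data@channels) != ncol(op@M))
      stop("channel mismatch: operator has ", ncol(op@M), ", data has ",
           nrow(data@channels))
    out <- lapply(seq_along(data@predictors), function(p) {
      plane <- data@coefficients[p, , , drop = TRUE]
      dim(plane) <- dim(data@coefficients)[2:3]
      applyInverse(op, plane, flavor, fs = data@fs, t0 = data@t0)
    })
    return(stats::setNames(out, data@predictors))
  }
  data <- as.matrix(data)
  if (nrow(data) != ncol(op@M))
    stop("channel mismatch: operator has ", ncol(op@M), ", data has ",
         nrow(data))
  if (is.null(fs)) { fs <- 1; t0 <- 0 }
  vals <- op@M %*% data
  if (flavor == "dspm") vals <- vals / op@dspmNorms
  new("SourceEstimate", values = vals, flavor = flavor, fs = fs, t0 = t0)
}

#' @rdname accessors
#' @export
sourceValues <- function(x) {
  stopifnot(is(x, "SourceEstimate"))
  x@values
}
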