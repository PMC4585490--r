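#' @import methods
NULL

## Central S4 containers for the regression-MEG pipeline. All time is in
## milliseconds relative to stimulus onset; sampling rates in Hz; sensor data
## in channel-native units (T for magnetometers, T/m for gradiometers, V for
## EOG).


#' CompositePredictor: a standardized PC1 composite of item measures
#'
#' One predictor variable per item, derived as the first principal component
#' of z-scored item measures (correlation PCA) and re-standardized to mean 0,
#' SD 1 across items.
#'
#' @slot name predictor label, e.g. `"VisualComplexity"`.
#' @slot values named numeric, one standardized score per item.
#' @slot loadings unit-norm PC1 weights, one per input measure.
#' @slot explainedVariance fraction of correlation-matrix variance carried by
#'   PC1, in `[0, 1]`.
#' @slot excludedItems items dropped because a contributing measure was
#'   missing; these carry no score.
#' @exportClass CompositePredictor
setClass("CompositePredictor",
  representation(
    name = "character",
    values = "numeric",
    loadings = "numeric",
    explainedVariance = "numeric",
    excludedItems = "character"
  ),
  validity = function(object) {
    msg <- NULL
    v <- object@values
    if (is.null(names(v))) msg <- c(msg, "values must be named by item id")
    if (length(v) >= 2) {
      if (abs(mean(v)) > 1e-10) msg <- c(msg, "values must have mean 0")
      if (abs(stats::sd(v) - 1) > 1e-10) msg <- c(msg, "values must have SD 1")
    }
    if (abs(sqrt(sum(object@loadings^2)) - 1) > 1e-8)
      msg <- c(msg, "loadings must be unit-norm")
    ev <- object@explainedVariance
    if (length(ev) != 1L || ev < 0 || ev > 1 + 1e-12)
      msg <- c(msg, "explainedVariance must be a fraction in [0, 1]")
    if (is.null(msg)) TRUE else msg
  }
)

#' PredictorSet: item-by-predictor matrix of standardized composites
#'
#' @slot values numeric matrix, items (rows, named by item id) by predictors
#'   (columns, named).
#' @slot loadings list of per-composite loading vectors (may be empty for
#'   synthetic predictors that were not derived from measures).
#' @slot explainedVariance named numeric, PC1 variance fraction per composite
#'   (NA where not applicable).
#' @exportClass PredictorSet
setClass("PredictorSet",
  representation(
    values = "matrix",
    loadings = "list",
    explainedVariance = "numeric"
  ),
  validity = function(object) {
    msg <- NULL
    if (is.null(rownames(object@values)))
      msg <- c(msg, "rows of values must be named by item id")
    if (anyDuplicated(rownames(object@values)))
      msg <- c(msg, "duplicate item ids")
    if (is.null(colnames(object@values)))
      msg <- c(msg, "columns of values must be named by predictor")
    if (is.null(msg)) TRUE else msg
  }
)

#' DesignMatrix: trial-level regressor matrix X
#'
#' Row i carries the composite predictor values of the item shown on trial i;
#' an optional leading intercept column of ones absorbs the mean evoked
#' response so that predictor coefficients are slopes per predictor SD.
#'
#' @slot X numeric matrix, trials by (intercept +) predictors.
#' @slot trialItems item id per trial (row).
#' @slot hasIntercept does column 1 hold the intercept?
#' @exportClass DesignMatrix
setClass("DesignMatrix",
  representation(
    X = "matrix",
    trialItems = "character",
    hasIntercept = "logical"
  ),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@X) != length(object@trialItems))
      msg <- c(msg, "one trial item per design row required")
    if (object@hasIntercept &&
        (ncol(object@X) < 1L || any(object@X[, 1L] != 1)))
      msg <- c(msg, "intercept flagged but column 1 is not all ones")
    if (is.null(msg)) TRUE else msg
  }
)

#' EpochSet: trials x channels x samples tensor with channel metadata
#'
#' @slot data numeric array `[trials, channels, samples]` in channel-native
#'   units.
#' @slot channels data.frame with columns `name`, `kind` (one of
#'   `"magnetometer"`, `"gradiometer"`, `"eog"`) and `unit` (`"T"`, `"T/m"`,
#'   `"V"`).
#' @slot fs sampling rate in Hz.
#' @slot t0 time of the first sample in ms relative to stimulus onset.
#' @slot trialItems item id per trial.
#' @exportClass EpochSet
setClass("EpochSet",
  representation(
    data = "array",
    channels = "data.frame",
    fs = "numeric",
    t0 = "numeric",
    trialItems = "character"
  ),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@data)
    if (length(d) != 3L) msg <- c(msg, "data must be trials x channels x samples")
    if (object@fs <= 0) msg <- c(msg, "fs must be positive")
    if (!is.null(d) && length(d) == 3L) {
      if (d[2L] != nrow(object@channels))
        msg <- c(msg, "channel metadata does not match data")
      if (d[1L] != length(object@trialItems))
        msg <- c(msg, "trialItems must have one entry per trial")
    }
    ok <- .unitForKind(object@channels$kind)
    bad <- which(object@channels$unit != ok)
    if (length(bad))
      msg <- c(msg, paste0("channel kind/unit mismatch: ",
                           paste(object@channels$name[bad], collapse = ", ")))
    if (is.null(msg)) TRUE else msg
  }
)

#' LinearEstimator: the weights G mapping trials to regression coefficients
#'
#' `G = (X'X)^{-1} X'` computed through a rank-revealing pseudoinverse; each
#' row of G holds the per-trial weights whose inner product with the data
#' yields one regression coefficient, so every coefficient is a weighted
#' average of trials.
#'
#' @slot G numeric matrix, (intercept +) predictors by trials.
#' @slot design the [DesignMatrix-class] the estimator was built from.
#' @exportClass LinearEstimator
setClass("LinearEstimator",
  representation(G = "matrix", design = "DesignMatrix"),
  validity = function(object) {
    P <- object@G %*% object@design@X
    if (max(abs(P - diag(ncol(object@design@X)))) > 1e-8)
      "G %*% X must equal the identity (full-column-rank design)" else TRUE
  }
)

#' ERRCSet: event-related regression coefficients
#'
#' Regression coefficients b per predictor, channel and latency, in
#' channel-native units per predictor SD. EOG channels never enter the
#' regression, so the channel set excludes them.
#'
#' @slot coefficients numeric array `[predictors, channels, samples]`.
#' @slot predictors coefficient names (column names of the design).
#' @slot channels channel metadata data.frame (non-EOG).
#' @slot fs,t0 time base inherited from the epochs.
#' @exportClass ERRCSet
setClass("ERRCSet",
  representation(
    coefficients = "array",
    predictors = "character",
    channels = "data.frame",
    fs = "numeric",
    t0 = "numeric"
  ),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@coefficients)
    if (length(d) != 3L)
      msg <- c(msg, "coefficients must be predictors x channels x samples")
    else {
      if (d[1L] != length(object@predictors))
        msg <- c(msg, "predictor names do not match coefficient array")
      if (d[2L] != nrow(object@channels))
        msg <- c(msg, "channel metadata does not match coefficient array")
    }
    if (!all(is.finite(object@coefficients)))
      msg <- c(msg, "coefficients must be finite")
    if (is.null(msg)) TRUE else msg
  }
)

#' SummarySeries: a single unitless time course
#'
#' Used for SNR-RMS curves and ROI intensity time courses.
#'
#' @slot values one value per sample.
#' @slot fs,t0 time base.
#' @slot kind free-text tag, e.g. `"snr_rms"` or `"roi_intensity"`.
#' @exportClass SummarySeries
setClass("SummarySeries",
  representation(values = "numeric", fs = "numeric", t0 = "numeric",
                 kind = "character"),
  validity = function(object) {
    if (object@fs <= 0) "fs must be positive" else TRUE
  }
)

#' LeadField: forward gain from sources to sensors
#'
#' Fixed-orientation gain: one signed scalar amplitude per source, one column
#' of sensor topography per source.
#'
#' @slot gain numeric matrix, channels by sources, channel-native units per
#'   unit source amplitude.
#' @slot channels channel metadata data.frame.
#' @slot sourcePos numeric matrix of source positions (one row per source).
#' @exportClass LeadField
setClass("LeadField",
  representation(gain = "matrix", channels = "data.frame",
                 sourcePos = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@gain) != nrow(object@channels))
      msg <- c(msg, "gain rows must match channels")
    if (ncol(object@gain) != nrow(object@sourcePos))
      msg <- c(msg, "gain columns must match source positions")
    if (!all(is.finite(object@gain))) msg <- c(msg, "gain must be finite")
    if (is.null(msg)) TRUE else msg
  }
)

#' NoiseCovariance: baseline sensor noise covariance
#'
#' @slot C symmetric positive semi-definite channels-by-channels matrix,
#'   diagonally loaded.
#' @slot nSamples number of (trial, sample) pairs pooled.
#' @slot loading fraction of the mean diagonal added to the diagonal.
#' @slot channels channel metadata data.frame.
#' @exportClass NoiseCovariance
setClass("NoiseCovariance",
  representation(Cmat = "matrix", nSamples = "integer", loading = "numeric",
                 channels = "data.frame"),
  validity = function(object) {
    msg <- NULL
    C <- object@Cmat
    if (max(abs(C - t(C))) > 1e-12 * max(abs(C), 1))
      msg <- c(msg, "C must be symmetric")
    if (any(diag(C) <= 0))
      msg <- c(msg, "diagonal must be strictly positive after loading")
    if (is.null(msg)) TRUE else msg
  }
)

#' InverseOperator: regularized L2 minimum-norm inverse with dSPM norms
#'
#' @slot M sources-by-channels inverse kernel (whitener folded in).
#' @slot lambda2 regularization parameter, `1 / SNR^2`.
#' @slot whitener the whitening transform used (retained-rank rows by
#'   channels).
#' @slot sigma2 source-prior variance fixed by the trace convention
#'   `trace(L~ R L~') = n_whitened_channels`.
#' @slot dspmNorms per-source noise SD of the estimate under whitened unit
#'   noise; dividing by these yields dSPM values.
#' @slot channels channel metadata of the sensor space M applies to.
#' @exportClass InverseOperator
setClass("InverseOperator",
  representation(M = "matrix", lambda2 = "numeric", whitener = "matrix",
                 sigma2 = "numeric", dspmNorms = "numeric",
                 channels = "data.frame"),
  validity = function(object) {
    msg <- NULL
    if (object@lambda2 < 0) msg <- c(msg, "lambda2 must be >= 0")
    if (length(object@dspmNorms) != nrow(object@M))
      msg <- c(msg, "one dSPM norm per source required")
    if (any(object@dspmNorms <= 0)) msg <- c(msg, "dSPM norms must be > 0")
    if (is.null(msg)) TRUE else msg
  }
)

#' SourceEstimate: source-space coefficient or activity maps
#'
#' @slot values numeric matrix, sources by samples. `mne_amplitude` carries
#'   source amplitudes; `dspm` carries unitless noise-normalized values.
#' @slot flavor `"mne_amplitude"` or `"dspm"`.
#' @slot fs,t0 time base.
#' @exportClass SourceEstimate
setClass("SourceEstimate",
  representation(values = "matrix", flavor = "character", fs = "numeric",
                 t0 = "numeric"),
  validity = function(object) {
    if (!object@flavor %in% c("mne_amplitude", "dspm"))
      "flavor must be 'mne_amplitude' or 'dspm'" else TRUE
  }
)

#' ROIDefinition: a set of source-space vertices around a seed
#'
#' @slot name ROI label (e.g. `"Occ"`, `"pMTG"`).
#' @slot vertices unique vertex ids forming the ROI.
#' @slot seed the peak vertex the ROI was grown from.
#' @slot k requested neighborhood size.
#' @exportClass ROIDefinition
setClass("ROIDefinition",
  representation(name = "character", vertices = "integer", seed = "integer",
                 k = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@vertices) == 0L) msg <- c(msg, "ROI must be non-empty")
    if (anyDuplicated(object@vertices)) msg <- c(msg, "vertices must be unique")
    if (!(object@seed %in% object@vertices))
      msg <- c(msg, "seed must belong to the ROI")
    if (is.null(msg)) TRUE else msg
  }
)

## ---- show methods -------------------------------------------------------

setMethod("show", "PredictorSet", function(object) {
  cat("PredictorSet:", nrow(object@values), "items x",
      ncol(object@values), "predictors\n")
  cat("  predictors:", paste(colnames(object@values), collapse = ", "), "\n")
  ev <- object@explainedVariance
  if (length(ev) && any(is.finite(ev)))
    cat("  PC1 variance fraction:",
        paste(sprintf("%s=%.2f", names(ev)[is.finite(ev)],
                      ev[is.finite(ev)]), collapse = ", "), "\n")
})

setMethod("show", "CompositePredictor", function(object) {
  cat("CompositePredictor '", object@name, "': ", length(object@values),
      " items, PC1 explains ", sprintf("%.1f%%",
      100 * object@explainedVariance), " of measure correlation\n", sep = "")
  if (length(object@excludedItems))
    cat("  excluded (missing measures):",
        paste(object@excludedItems, collapse = ", "), "\n")
})

setMethod("show", "DesignMatrix", function(object) {
  cat("DesignMatrix:", nrow(object@X), "trials x", ncol(object@X),
      "columns", if (object@hasIntercept) "(incl. intercept)" else "", "\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat("EpochSet:", d[1L], "trials x", d[2L], "channels x", d[3L],
      "samples @", object@fs, "Hz\n")
  cat("  time:", object@t0, "to",
      object@t0 + (d[3L] - 1L) * 1000 / object@fs, "ms\n")
  cat("  channels:", paste(sprintf("%d %s", table(object@channels$kind),
      names(table(object@channels$kind))), collapse = ", "), "\n")
})

setMethod("show", "ERRCSet", function(object) {
  d <- dim(object@coefficients)
  cat("ERRCSet:", d[1L], "coefficients x", d[2L], "channels x", d[3L],
      "samples @", object@fs, "Hz\n")
  cat("  coefficients:", paste(object@predictors, collapse = ", "), "\n")
})

setMethod("show", "LinearEstimator", function(object) {
  cat("LinearEstimator: G is", nrow(object@G), "x", ncol(object@G),
      "(coefficients x trials)\n")
})

setMethod("show", "LeadField", function(object) {
  cat("LeadField:", nrow(object@gain), "channels x", ncol(object@gain),
      "sources (fixed orientation)\n")
})

setMethod("show", "NoiseCovariance", function(object) {
  cat("NoiseCovariance:", nrow(object@Cmat), "channels,", object@nSamples,
      "samples pooled, diagonal loading", object@loading, "\n")
})

setMethod("show", "InverseOperator", function(object) {
  cat("InverseOperator:", nrow(object@M), "sources x", ncol(object@M),
      "channels, lambda2 =", format(object@lambda2, digits = 4),
      sprintf("(SNR = %.3g)\n", 1 / sqrt(object@lambda2)))
})

setMethod("show", "SourceEstimate", function(object) {
  cat("SourceEstimate (", object@flavor, "): ", nrow(object@values),
      " sources x ", ncol(object@values), " samples @ ", object@fs,
      " Hz\n", sep = "")
})

setMethod("show", "ROIDefinition", function(object) {
  cat("ROI '", object@name, "': ", length(object@vertices),
      " vertices, seed ", object@seed, "\n", sep = "")
})

setMethod("show", "SummarySeries", function(object) {
  cat("SummarySeries (", object@kind, "): ", length(object@values),
      " samples @ ", object@fs, " Hz from ", object@t0, " ms\n", sep = "")
})
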