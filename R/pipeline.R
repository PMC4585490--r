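#' Run the sensor-to-source analysis for one subject
#'
#' Baseline-corrects the epochs, computes the ERRCs, estimates the baseline
#' noise covariance, assembles the minimum-norm inverse operator at the
#' given SNR and applies it to every coefficient plane, returning dSPM
#' source estimates.
#'
#' @param epochs the subject's [EpochSet-class].
#' @param design the subject's [DesignMatrix-class] (see [assembleDesign]).
#' @param lf the shared [LeadField-class].
#' @param snr regularization SNR, default 3.
#' @param baseline ms interval for baseline correction, ERRC SNR and the
#'   noise covariance, default -100..0.
#' @param loading diagonal loading for the covariance, default 0.1.
#' @param flavor source-estimate flavor, default `"dspm"`.
#' @return list with `errc`, `cov`, `inv` and `estimates` (named list of
#'   [SourceEstimate-class], one per coefficient).
#' @export
analyzeSubject <- function(epochs, design, lf, snr = 3,
                           baseline = c(-100, 0), loading = 0.1,
                           flavor = "dspm") {
  epochs <- baselineCorrect(epochs, baseline)
  errc <- computeERRC(epochs, design)
  cov <- noiseCovariance(epochs, baseline, loading)
  inv <- makeInverse(lf, cov, snr)
  est <- applyInverse(inv, errc, flavor)
  list(errc = errc, cov = cov, inv = inv, estimates = est)
}

#' Grand-average ERRC across subjects
#'
#' Plain average of the coefficient arrays; subjects must share predictors,
#' channels and time base.
#'
#' @param errcs list of [ERRCSet-class].
#' @return an [ERRCSet-class].
#' @export
grandAverageERRC <- function(errcs) {
  stopifnot(length(errcs) >= 1L)
  ref <- errcs[[1L]]
  acc <- ref@coefficients
  for (e in errcs[-1L]) {
    stopifnot(identical(dim(e@coefficients), dim(acc)),
              identical(e@predictors, ref@predictors))
    acc <- acc + e@coefficients
  }
  ref@coefficients <- acc / length(errcs)
  ref
}

#' Define the study ROIs from the grand-mean source estimate
#'
#' The grand mean is the across-subject average of the intercept (evoked
#' mean) dSPM maps — a condition orthogonal to the predictors. One ROI is
#' grown per candidate region mask ([defineROI]).
#'
#' @param estimates per-subject named lists of [SourceEstimate-class]
#'   containing an `"(Intercept)"` entry.
#' @param lf the [LeadField-class] (for source positions).
#' @param regions named list of candidate vertex masks (e.g.
#'   `toyGeometry()$regions`).
#' @param k ROI size in vertices; default 20, capped at each mask size.
#' @return named list of [ROIDefinition-class].
#' @export
defineStudyROIs <- function(estimates, lf, regions, k = 20) {
  grand <- estimates[[1L]][["(Intercept)"]]
  acc <- grand@values
  for (subj in estimates[-1L])
    acc <- acc + subj[["(Intercept)"]]@values
  grand@values <- acc / length(estimates)
  out <- lapply(names(regions), function(nm) {
    mask <- regions[[nm]]
    defineROI(grand, mask, min(k, length(mask)), lf@sourcePos, name = nm)
  })
  stats::setNames(out, names(regions))
}

#' Full group analysis of a (simulated or recorded) study
#'
#' Per subject: design assembly, baseline correction, ERRC computation,
#' noise covariance, minimum-norm inverse and dSPM maps. Group level:
#' ROIs from the grand-mean evoked estimate, bias-corrected windowed ROI
#' statistics per predictor, and grand-average ERRC SNR-RMS curves with
#' their peak latencies.
#'
#' @param study list of per-subject lists holding at least `epochs` (as
#'   returned by [simulateStudy]).
#' @param predictors the [PredictorSet-class] used for the designs.
#' @param lf the shared [LeadField-class].
#' @param regions named list of candidate ROI masks.
#' @param snr,baseline,loading passed to [analyzeSubject].
#' @param k ROI size, see [defineStudyROIs].
#' @param window,biasInterval,alpha,nTests passed to [roiGroupStats].
#' @param peakWindow ms window for SNR-RMS peak search.
#' @return list with `table` (ROI x predictor group statistics), `rois`,
#'   `snrRms` (named list of [SummarySeries-class] per coefficient),
#'   `peaks` (named list of peak latencies) and `subjects` (per-subject
#'   analysis results).
#' @export
analyzeStudy <- function(study, predictors, lf, regions, snr = 3,
                         baseline = c(-100, 0), loading = 0.1, k = 20,
                         window = c(130, 160), biasInterval = c(-50, 50),
                         alpha = 0.05, nTests = length(regions),
                         peakWindow = c(0, 300)) {
  subjects <- lapply(study, function(s) {
    design <- assembleDesign(predictors, trialItems(s$epochs))
    analyzeSubject(s$epochs, design, lf, snr, baseline, loading)
  })
  estimates <- lapply(subjects, `[[`, "estimates")
  rois <- defineStudyROIs(estimates, lf, regions, k)
  table <- roiGroupStats(estimates, rois, window = window,
                         biasInterval = biasInterval, alpha = alpha,
                         nTests = nTests)
  grand <- grandAverageERRC(lapply(subjects, `[[`, "errc"))
  snrRms <- errcSnrRms(grand, baseline)
  peaks <- lapply(snrRms, findPeaks, window = peakWindow)
  list(table = table, rois = rois, snrRms = snrRms, peaks = peaks,
       subjects = subjects)
}

#' Write a summary series as a two-column CSV (ms, value)
#'
#' @param series a [SummarySeries-class].
#' @param path output path.
#' @export
writeSummarySeries <- function(series, path) {
  utils::write.csv(data.frame(ms = epochTimes(series),
                              value = series@values),
                   path, row.names = FALSE)
  invisible(path)
}
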