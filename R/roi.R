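#' Define an ROI around the grand-mean activation peak in a region
#'
#' The seed is the vertex with the largest time-maximum |dSPM| of the
#' grand-mean source estimate within the candidate mask (a condition
#' orthogonal to the predictors, so ROI selection does not bias predictor
#' tests); ties go to the lowest vertex id. The ROI is the seed plus its
#' `k - 1` nearest neighbors by source-position distance, restricted to the
#' mask.
#'
#' @param grandMean a dSPM-flavored [SourceEstimate-class] of the average
#'   across all items.
#' @param mask candidate vertex ids (1-based, within the source space).
#' @param k ROI size in vertices, `1 <= k <= length(mask)`.
#' @param sourcePos source position matrix (e.g. the lead field's
#'   `sourcePos`).
#' @param name ROI label.
#' @return an [ROIDefinition-class].
#' @export
defineROI <- function(grandMean, mask, k, sourcePos, name = "roi") {
  mask <- sort(unique(as.integer(mask)))
  if (!length(mask)) stop("empty candidate mask")
  if (k < 1L || k > length(mask))
    stop("k must be between 1 and the mask size (", length(mask), ")")
  if (max(mask) > nrow(grandMean@values))
    stop("mask vertex outside the source space")
  score <- apply(abs(grandMean@values[mask, , drop = FALSE]), 1L, max)
  seed <- mask[which.max(score)]      # which.max takes the first (lowest id)
  sourcePos <- as.matrix(sourcePos)
  dist <- sqrt(rowSums((sourcePos[mask, , drop = FALSE] -
                        matrix(sourcePos[seed, ], length(mask),
                               ncol(sourcePos), byrow = TRUE))^2))
  ord <- order(dist, mask)
  new("ROIDefinition", name = name, vertices = sort(mask[ord[seq_len(k)]]),
      seed = as.integer(seed), k = as.integer(k))
}

#' ROI intensity time course
#'
#' Mean over the ROI vertices of |dSPM| at each latency. The magnitude is
#' taken because fixed-orientation estimates are signed and would cancel
#' across a folded patch of cortex; the resulting positive bias is removed
#' later by [windowedBiasCorrected].
#'
#' @param est a [SourceEstimate-class] (dSPM flavor expected).
#' @param roi an [ROIDefinition-class].
#' @return a [SummarySeries-class].
#' @export
roiTimecourse <- function(est, roi) {
  if (max(roi@vertices) > nrow(est@values))
    stop("ROI vertex missing from the source estimate")
  v <- colMeans(abs(est@values[roi@vertices, , drop = FALSE]))
  new("SummarySeries", values = v, fs = est@fs, t0 = est@t0,
      kind = "roi_intensity")
}

#' Windowed, bias-corrected ROI intensity
#'
#' `mean(series over window) - mean(series over bias interval)`. Because ROI
#' intensities are magnitudes, they have a positive mean even in pure noise;
#' subtracting the mean over an interval straddling stimulus onset
#' (default -50..+50 ms) removes that bias conservatively — the bias
#' estimate is temporally close to the effect window and tracks slow drifts
#' in noise level.
#'
#' @param series a [SummarySeries-class] (ROI intensity).
#' @param window analysis window in ms, default 130-160 ms.
#' @param biasInterval bias interval in ms, default -50..+50 ms.
#' @return scalar bias-corrected intensity.
#' @export
windowedBiasCorrected <- function(series, window = c(130, 160),
                                  biasInterval = c(-50, 50)) {
  n <- length(series@values)
  wi <- .intervalIndex(window, series@fs, series@t0, n, "analysis window")
  bi <- .intervalIndex(biasInterval, series@fs, series@t0, n,
                       "bias interval")
  mean(series@values[wi]) - mean(series@values[bi])
}

#' One-sample group test against zero
#'
#' Two-tailed one-sample t-test of per-subject values against 0,
#' `t = mean / (SD / sqrt(n))` on `n - 1` df.
#'
#' @param values per-subject scalars (e.g. bias-corrected ROI intensities),
#'   `n >= 2`.
#' @return list with `t`, `df` and two-sided `p`.
#' @export
groupTest <- function(values) {
  if (length(values) < 2L) stop("need at least 2 subjects")
  if (stats::sd(values) == 0)
    stop("degenerate input: zero variance across subjects")
  tt <- stats::t.test(values, mu = 0, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Bonferroni-corrected per-test alpha
#'
#' @param familyAlpha family-wise error rate, e.g. 0.05.
#' @param nTests number of tests in the family (e.g. 6 ROI loci per
#'   predictor).
#' @return per-test threshold `familyAlpha / nTests` (0.05 over 6 loci gives
#'   0.00833..., i.e. 0.008 at 3 decimals).
#' @export
correctedAlpha <- function(familyAlpha, nTests) {
  stopifnot(nTests >= 1L)
  familyAlpha / nTests
}

#' Group ROI statistics across subjects and coefficients
#'
#' For every ROI and predictor, extracts each subject's bias-corrected
#' windowed ROI intensity from that subject's dSPM coefficient map and runs
#' the one-sample group test, flagging significance at the
#' Bonferroni-corrected alpha.
#'
#' @param estimates list over subjects; each element a named list of dSPM
#'   [SourceEstimate-class] objects, one per predictor (as returned by
#'   [applyInverse] on an `ERRCSet`).
#' @param rois list of [ROIDefinition-class].
#' @param predictors which predictor names to test; defaults to all except
#'   `"(Intercept)"`.
#' @param window,biasInterval passed to [windowedBiasCorrected].
#' @param alpha family-wise alpha, default 0.05.
#' @param nTests tests per family; defaults to the number of ROIs (the loci
#'   examined with each predictor).
#' @return data.frame with columns `roi`, `predictor`, `mean`, `t`, `df`,
#'   `p`, `significant`, plus attribute `"values"` holding the per-subject
#'   matrix for each cell.
#' @export
roiGroupStats <- function(estimates, rois,
                          predictors = NULL,
                          window = c(130, 160), biasInterval = c(-50, 50),
                          alpha = 0.05, nTests = length(rois)) {
  stopifnot(length(estimates) >= 2L, length(rois) >= 1L)
  if (is.null(predictors))
    predictors <- setdiff(names(estimates[[1L]]), "(Intercept)")
  thr <- correctedAlpha(alpha, nTests)
  cells <- list()
  values <- list()
  for (roi in rois) {
    for (pred in predictors) {
      v <- vapply(estimates, function(subj) {
        windowedBiasCorrected(roiTimecourse(subj[[pred]], roi),
                              window, biasInterval)
      }, numeric(1L))
      gt <- groupTest(v)
      cells[[length(cells) + 1L]] <- data.frame(
        roi = roi@name, predictor = pred, mean = mean(v),
        t = gt$t, df = gt$df, p = gt$p, significant = gt$p < thr,
        stringsAsFactors = FALSE)
      values[[paste(roi@name, pred, sep = ":")]] <- v
    }
  }
  out <- do.call(rbind, cells)
  attr(out, "values") <- values
  attr(out, "correctedAlpha") <- thr
  out
}

#' Read / write ROI label files
#'
#' Plain-text format: a `#name: <label>` header line followed by one vertex
#' id per line.
#'
#' @param roi an [ROIDefinition-class].
#' @param path file path.
#' @export
writeROILabels <- function(roi, path) {
  writeLines(c(paste0("#name: ", roi@name),
               as.character(roi@vertices)), path)
  invisible(path)
}

#' @rdname writeROILabels
#' @export
readROILabels <- function(path) {
  lines <- readLines(path)
  header <- grepl("^#name:", lines)
  name <- if (any(header)) trimws(sub("^#name:", "", lines[header][1L]))
          else "roi"
  verts <- as.integer(lines[!header & nzchar(trimws(lines))])
  new("ROIDefinition", name = name, vertices = sort(unique(verts)),
      seed = sort(unique(verts))[1L], k = length(unique(verts)))
}
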