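#' Apply response-exclusion rules to naming-latency records
#'
#' Exclusions are applied sequentially, in the standard order for naming
#' data:
#' 1. responses with names other than the listed acceptable names,
#' 2. responses flagged as preceded by hesitations or stuttering,
#' 3. latencies outside `[fastMs, slowMs]`,
#' 4. per-subject outliers: responses whose latency deviates from the
#'    subject's mean by more than `sdMult` SDs, with mean and SD computed
#'    over that subject's responses surviving rules 1-3.
#'
#' @param records data.frame with columns `trial`, `item`, `subject`,
#'   `name`, `latency` (ms) and logical `hesitation`.
#' @param validNames named list mapping item id to its acceptable name(s).
#' @param fastMs,slowMs latency range bounds in ms, defaults 300 and 2000.
#' @param sdMult outlier multiplier, default 2.5.
#' @return list with `kept` (surviving records) and `tally`, a named count
#'   of exclusions per rule (`wrong_name`, `hesitation`, `out_of_range`,
#'   `outlier`).
#' @export
filterResponses <- function(records, validNames, fastMs = 300,
                            slowMs = 2000, sdMult = 2.5) {
  if (!nrow(records)) stop("no response records")
  stopifnot(fastMs > 0, slowMs > fastMs, sdMult > 0)
  need <- c("trial", "item", "subject", "name", "latency", "hesitation")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("records lack column(s): ", paste(missing, collapse = ", "))

  ok <- mapply(function(item, name) {
    name %in% validNames[[as.character(item)]]
  }, records$item, records$name)
  tally <- c(wrong_name = sum(!ok))
  records <- records[ok, , drop = FALSE]

  tally["hesitation"] <- sum(records$hesitation)
  records <- records[!records$hesitation, , drop = FALSE]

  inRange <- records$latency >= fastMs & records$latency <= slowMs
  tally["out_of_range"] <- sum(!inRange)
  records <- records[inRange, , drop = FALSE]

  outlier <- logical(nrow(records))
  for (s in unique(records$subject)) {
    i <- which(records$subject == s)
    lat <- records$latency[i]
    if (length(lat) >= 2L) {
      dev <- abs(lat - mean(lat))
      outlier[i] <- dev > sdMult * stats::sd(lat)
    }
  }
  tally["outlier"] <- sum(outlier)
  records <- records[!outlier, , drop = FALSE]
  list(kept = records, tally = tally)
}

#' Joint predictor regression on item-mean naming latencies
#'
#' Ordinary least squares of per-item mean latency on the composite
#' predictors (plus intercept), with the overall F-test of the joint model:
#' df = (p, n - p - 1), so 146 items and 4 predictors give F on (4, 141).
#'
#' @param latencies named numeric vector of item-mean latencies (names =
#'   item ids), or a data.frame with columns `item` and `latency`.
#' @param predictors a [PredictorSet-class] covering the latency items.
#' @return list with `coefficients` (incl. intercept), `F`, `df` (numerator,
#'   denominator) and the overall `p`.
#' @export
latencyRegression <- function(latencies, predictors) {
  if (is.data.frame(latencies))
    latencies <- stats::setNames(latencies$latency,
                                 as.character(latencies$item))
  items <- names(latencies)
  idx <- match(items, rownames(predictors@values))
  if (anyNA(idx))
    stop("latency item(s) missing from predictor set: ",
         paste(items[is.na(idx)], collapse = ", "))
  X <- predictors@values[idx, , drop = FALSE]
  p <- ncol(X)
  n <- length(latencies)
  if (n < p + 2L) stop("need at least predictors + 2 items")
  dat <- data.frame(.latency = as.numeric(latencies), X, check.names = FALSE)
  fit <- stats::lm(.latency ~ ., data = dat)
  if (fit$rank < p + 1L) stop("rank-deficient predictor matrix")
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(coefficients = stats::coef(fit),
       F = unname(fstat["value"]),
       df = unname(fstat[c("numdf", "dendf")]),
       p = unname(stats::pf(fstat["value"], fstat["numdf"], fstat["dendf"],
                            lower.tail = FALSE)))
}
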