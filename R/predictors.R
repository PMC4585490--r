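#' Standardize a vector to mean 0, SD 1
#'
#' Uses the sample SD (n - 1 denominator). Standardization makes composite
#' predictors and regression slopes comparable across measures recorded on
#' different scales (ratings, counts, log frequencies).
#'
#' @param values numeric vector with at least 2 finite values.
#' @return numeric vector of z-scores, order preserved, names kept.
#' @examples
#' standardize(c(1, 2, 3, 4))
#' @export
standardize <- function(values) {
  if (sum(is.finite(values)) < 2L)
    stop("standardize needs at least 2 finite values")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    stop("degenerate input: zero variance, cannot standardize")
  (values - mean(values)) / s
}

#' Read an item-level norm table
#'
#' CSV/TSV with a header; the `item_id` column is mandatory and must be
#' unique. All other columns are treated as real-valued item measures.
#'
#' @param path file path; tab-separated when the extension is `.tsv`.
#' @return data.frame with character `item_id` plus numeric measure columns.
#' @export
readNormTable <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"item_id" %in% names(tab)) stop("norm table must have an item_id column")
  tab$item_id <- as.character(tab$item_id)
  if (anyDuplicated(tab$item_id)) stop("duplicate item_id in norm table")
  tab
}

#' Derive a composite predictor by correlation PCA
#'
#' Each named measure is z-scored, PCA is computed on the correlation
#' structure of the z-scores, and the first principal component scores are
#' extracted and re-standardized to mean 0, SD 1. The PC1 sign is oriented so
#' that its loading on `orientation` is positive (PCA is sign-ambiguous).
#' With a single measure the composite is simply its standardized values.
#'
#' Items with any missing value among the contributing measures are excluded
#' from the PCA and carry no score (no imputation); they are listed in the
#' result's `excludedItems` slot.
#'
#' @param table data.frame with an `item_id` column and measure columns
#'   (see [readNormTable]).
#' @param measures character vector of measure column names to combine.
#' @param name label for the composite.
#' @param orientation measure whose PC1 loading is forced positive; defaults
#'   to the first entry of `measures`.
#' @return a [CompositePredictor-class].
#' @export
deriveComposite <- function(table, measures, name = "composite",
                            orientation = measures[1L]) {
  if (length(measures) < 1L) stop("at least one measure required")
  missing <- setdiff(measures, names(table))
  if (length(missing))
    stop("measure(s) not in table: ", paste(missing, collapse = ", "))
  if (!orientation %in% measures)
    stop("orientation measure must be one of the combined measures")
  Z <- as.matrix(table[, measures, drop = FALSE])
  storage.mode(Z) <- "double"
  rownames(Z) <- table$item_id
  complete <- stats::complete.cases(Z)
  excluded <- rownames(Z)[!complete]
  Z <- Z[complete, , drop = FALSE]
  if (nrow(Z) < 2L) stop("fewer than 2 items with complete measures")
  for (m in measures) {
    if (stats::sd(Z[, m]) == 0)
      stop("zero-variance measure: ", m)
    Z[, m] <- standardize(Z[, m])
  }
  if (length(measures) == 1L) {
    loadings <- stats::setNames(1, measures)
    scores <- Z[, 1L]
    ev <- 1
  } else {
    R <- stats::cor(Z)
    eg <- eigen(R, symmetric = TRUE)
    loadings <- stats::setNames(eg$vectors[, 1L], measures)
    ev <- eg$values[1L] / sum(eg$values)
    scores <- drop(Z %*% loadings)
  }
  if (loadings[[orientation]] < 0) {
    loadings <- -loadings
    scores <- -scores
  }
  new("CompositePredictor",
      name = name,
      values = standardize(scores),
      loadings = loadings,
      explainedVariance = ev,
      excludedItems = excluded)
}

#' Bundle composite predictors into a PredictorSet
#'
#' @param ... [CompositePredictor-class] objects. Items present in every
#'   composite form the set; items excluded from any composite are dropped.
#' @return a [PredictorSet-class].
#' @export
predictorSet <- function(...) {
  comps <- list(...)
  if (length(comps) == 1L && is.list(comps[[1L]]) &&
      !is(comps[[1L]], "CompositePredictor"))
    comps <- comps[[1L]]
  stopifnot(length(comps) >= 1L,
            all(vapply(comps, is, logical(1L), "CompositePredictor")))
  items <- Reduce(intersect, lapply(comps, function(p) names(p@values)))
  if (length(items) < 2L) stop("fewer than 2 items common to all composites")
  vals <- vapply(comps, function(p) p@values[items], numeric(length(items)))
  colnames(vals) <- vapply(comps, function(p) p@name, character(1L))
  rownames(vals) <- items
  new("PredictorSet",
      values = vals,
      loadings = stats::setNames(lapply(comps, function(p) p@loadings),
                                 colnames(vals)),
      explainedVariance = stats::setNames(
        vapply(comps, function(p) p@explainedVariance, numeric(1L)),
        colnames(vals)))
}

## bare-matrix constructor (synthetic predictors, tests)
.predictorSetFromMatrix <- function(values) {
  new("PredictorSet", values = values, loadings = list(),
      explainedVariance = stats::setNames(rep(NA_real_, ncol(values)),
                                          colnames(values)))
}

#' Pairwise correlations of predictors with predictors and raw measures
#'
#' Pearson correlations of every composite predictor with every other
#' composite and with every raw measure column of the norm table, over the
#' common item set. The predictor block is symmetric with unit diagonal.
#'
#' @param predictors a [PredictorSet-class].
#' @param table norm table data.frame with `item_id` (omit for the
#'   predictor-only block).
#' @return correlation matrix, rows = predictors, columns = predictors then
#'   measures.
#' @export
correlationReport <- function(predictors, table = NULL) {
  P <- predictors@values
  items <- rownames(P)
  M <- NULL
  if (!is.null(table)) {
    common <- intersect(items, table$item_id)
    if (length(common) < 3L) stop("fewer than 3 common items")
    P <- P[common, , drop = FALSE]
    M <- as.matrix(table[match(common, table$item_id),
                         setdiff(names(table), "item_id"), drop = FALSE])
    storage.mode(M) <- "double"
  } else if (length(items) < 3L) stop("fewer than 3 items")
  stats::cor(P, cbind(P, M), use = "pairwise.complete.obs")
}

#' Convert a Pearson correlation to a t statistic
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom, with
#' a two-sided p value. Reported when quoting item-level correlations between
#' measures (e.g. r over 146 items is tested on 144 df).
#'
#' @param r Pearson correlation, `|r| < 1`.
#' @param n number of items, at least 3.
#' @return list with `t`, `p` (two-sided) and `df = n - 2`.
#' @export
tFromR <- function(r, n) {
  stopifnot(length(r) == 1L, length(n) == 1L, n >= 3)
  if (abs(r) > 1) stop("|r| cannot exceed 1")
  df <- n - 2
  if (abs(r) == 1) {
    warning("|r| = 1: t statistic is infinite")
    return(list(t = sign(r) * Inf, p = 0, df = df))
  }
  t <- r * sqrt(df) / sqrt(1 - r^2)
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Assemble the trial-level design matrix
#'
#' Row i carries the composite predictor values of the item shown on trial i.
#' The intercept column (default on) absorbs the mean evoked response:
#' epochs are baseline-corrected, not predictor-mean-centered, so without it
#' the predictor slopes would be biased by the evoked mean.
#'
#' @param predictors a [PredictorSet-class].
#' @param trialItems character vector, item id per trial.
#' @param intercept prepend a column of ones? Default `TRUE`.
#' @return a [DesignMatrix-class].
#' @export
assembleDesign <- function(predictors, trialItems, intercept = TRUE) {
  trialItems <- as.character(trialItems)
  idx <- match(trialItems, rownames(predictors@values))
  if (anyNA(idx))
    stop("unknown item(s) on trial(s) ",
         paste(which(is.na(idx)), collapse = ", "), ": ",
         paste(unique(trialItems[is.na(idx)]), collapse = ", "))
  X <- predictors@values[idx, , drop = FALSE]
  rownames(X) <- NULL
  if (intercept)
    X <- cbind(`(Intercept)` = 1, X)
  new("DesignMatrix", X = X, trialItems = trialItems,
      hasIntercept = intercept)
}

#' Intercept-only design for grand-mean (evoked) analysis
#'
#' @param trialItems item id per trial.
#' @return a single-column [DesignMatrix-class] of ones.
#' @export
interceptDesign <- function(trialItems) {
  trialItems <- as.character(trialItems)
  X <- matrix(1, length(trialItems), 1L,
              dimnames = list(NULL, "(Intercept)"))
  new("DesignMatrix", X = X, trialItems = trialItems, hasIntercept = TRUE)
}

#' Export / import a predictor set as CSV
#'
#' The main file holds `item_id` plus one column per composite; loadings and
#' explained-variance fractions go to `<path>_loadings.csv` when available.
#'
#' @param predictors a [PredictorSet-class].
#' @param path output CSV path.
#' @export
writePredictorSet <- function(predictors, path) {
  df <- data.frame(item_id = rownames(predictors@values),
                   predictors@values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (length(predictors@loadings)) {
    rows <- do.call(rbind, lapply(names(predictors@loadings), function(p) {
      l <- predictors@loadings[[p]]
      data.frame(predictor = p, measure = names(l), loading = unname(l),
                 explained_variance = predictors@explainedVariance[[p]])
    }))
    utils::write.csv(rows, sub("(\\.csv)?$", "_loadings.csv", path),
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname writePredictorSet
#' @export
readPredictorSet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  vals <- as.matrix(df[, setdiff(names(df), "item_id"), drop = FALSE])
  rownames(vals) <- df$item_id
  .predictorSetFromMatrix(vals)
}
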