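#' Default inter-predictor correlation targets
#'
#' Correlation structure used when drawing synthetic item sets: predictors
#' are weakly correlated (|r| <= 0.23) except for a moderate negative
#' correlation (-0.39) between the visual and action predictors, matching
#' the structure typical of picture-naming norm sets.
#'
#' @return 4x4 correlation matrix over VisualComplexity,
#'   SpecificSemanticFeatures, ActionFeatures and WordForm.
#' @export
defaultPredictorCorr <- function() {
  nm <- c("VisualComplexity", "SpecificSemanticFeatures", "ActionFeatures",
          "WordForm")
  C <- diag(4)
  C[1, 2] <- C[2, 1] <- 0.12
  C[1, 3] <- C[3, 1] <- -0.39
  C[1, 4] <- C[4, 1] <- -0.23
  C[2, 3] <- C[3, 2] <- -0.20
  C[2, 4] <- C[4, 2] <- 0.08
  C[3, 4] <- C[4, 3] <- 0.19
  dimnames(C) <- list(nm, nm)
  C
}

#' Draw a synthetic item set with a target correlation structure
#'
#' Multivariate normal draws through the Cholesky factor of the target
#' correlation matrix, each predictor standardized to mean 0, SD 1 across
#' items. Reproducible from the seed.
#'
#' @param nItems number of items, default 146.
#' @param targetCorr symmetric positive-definite correlation matrix with
#'   unit diagonal; default [defaultPredictorCorr].
#' @param predictorNames names per predictor; defaults to the column names
#'   of `targetCorr`.
#' @param seed RNG seed.
#' @return a [PredictorSet-class] with items `item001`, `item002`, ...
#' @export
makeItemSet <- function(nItems = 146, targetCorr = defaultPredictorCorr(),
                        predictorNames = colnames(targetCorr), seed = 1) {
  targetCorr <- as.matrix(targetCorr)
  p <- ncol(targetCorr)
  if (max(abs(targetCorr - t(targetCorr))) > 1e-12 ||
      any(abs(diag(targetCorr) - 1) > 1e-12))
    stop("target matrix must be symmetric with unit diagonal")
  ch <- tryCatch(chol(targetCorr),
                 error = function(e) stop("target matrix is not positive ",
                                          "definite", call. = FALSE))
  if (is.null(predictorNames))
    predictorNames <- paste0("P", seq_len(p))
  set.seed(seed)
  Z <- matrix(stats::rnorm(nItems * p), nItems, p) %*% ch
  Z <- apply(Z, 2L, standardize)
  dimnames(Z) <- list(sprintf("item%03d", seq_len(nItems)), predictorNames)
  .predictorSetFromMatrix(Z)
}

#' Toy sensor/source geometry on a 1-D cortical strip
#'
#' Sources lie evenly on a posterior-to-anterior strip partitioned into six
#' contiguous, equally sized regions labelled in posterior-to-anterior order
#' Occ, pITG, pMTG, pSTG, IFG, vPMC. Two interleaved sensor arrays
#' (magnetometers and planar gradiometers) sit at a fixed height above the
#' strip. Distances are in cm.
#'
#' @param nSources number of sources, default 120 (20 per region).
#' @param nSensors named counts per sensor type, default 32 of each.
#' @param length strip length in cm, default 24.
#' @param sensorHeight sensor height above the strip in cm, default 3.
#' @param spread Gaussian spatial spread (SD, cm) of each source's gain
#'   profile, default 2.
#' @param typeScales peak gain per unit source amplitude, in native units:
#'   default 1e-13 T for magnetometers and 1e-11 T/m for gradiometers
#'   (distinct orders of magnitude, as for real arrays).
#' @return list with `sourcePos`, `sensorPos`, `channels`, `regions` (named
#'   list of vertex id vectors), `spread`, `typeScales`.
#' @export
toyGeometry <- function(nSources = 120,
                        nSensors = c(magnetometer = 32, gradiometer = 32),
                        length = 24, sensorHeight = 3, spread = 2,
                        typeScales = c(magnetometer = 1e-13,
                                       gradiometer = 1e-11)) {
  stopifnot(nSources >= 6L, all(nSensors >= 1L), spread > 0,
            all(typeScales > 0))
  sourcePos <- cbind(x = seq(0, length, length.out = nSources), y = 0)
  regionNames <- c("Occ", "pITG", "pMTG", "pSTG", "IFG", "vPMC")
  regions <- split(seq_len(nSources),
                   cut(seq_len(nSources), 6L, labels = regionNames))
  sensors <- do.call(rbind, lapply(names(nSensors), function(kind) {
    n <- nSensors[[kind]]
    data.frame(name = sprintf("%s%02d", toupper(substr(kind, 1L, 3L)),
                              seq_len(n)),
               kind = kind,
               x = seq(0, length, length.out = n), y = sensorHeight,
               stringsAsFactors = FALSE)
  }))
  channels <- channelInfo(sensors$name, sensors$kind)
  list(sourcePos = sourcePos,
       sensorPos = cbind(x = sensors$x, y = sensors$y),
       channels = channels,
       regions = lapply(regions, as.integer),
       spread = spread, typeScales = typeScales)
}

#' Build a toy lead field from a geometry
#'
#' Gain of source s at sensor c is
#' `typeScale(kind_c) * exp(-||pos_c - pos_s||^2 / (2 spread^2))`, with the
#' sign alternating across consecutive gradiometers (planar gradiometers
#' see alternating field-gradient polarity). A small seeded jitter of the
#' spread per sensor keeps gain columns of nearby sources non-identical.
#'
#' @param geometry from [toyGeometry].
#' @param seed RNG seed (deterministic output for a given seed).
#' @param alternateGradiometerSign alternate gradiometer polarity? Default
#'   `TRUE`.
#' @return a [LeadField-class].
#' @export
makeLeadfield <- function(geometry, seed = 1,
                          alternateGradiometerSign = TRUE) {
  sp <- geometry$sourcePos
  d2src <- as.matrix(stats::dist(sp))
  if (any(d2src[upper.tri(d2src)] == 0))
    stop("degenerate geometry: coincident sources")
  set.seed(seed)
  nc <- nrow(geometry$sensorPos)
  spreads <- geometry$spread * (1 + stats::runif(nc, -0.05, 0.05))
  gain <- matrix(0, nc, nrow(sp))
  for (c in seq_len(nc)) {
    d2 <- rowSums((sp - matrix(geometry$sensorPos[c, ], nrow(sp), 2L,
                               byrow = TRUE))^2)
    scale <- geometry$typeScales[[geometry$channels$kind[c]]]
    gain[c, ] <- scale * exp(-d2 / (2 * spreads[c]^2))
  }
  if (alternateGradiometerSign) {
    grad <- which(geometry$channels$kind == "gradiometer")
    flip <- grad[seq_along(grad) %% 2L == 0L]
    gain[flip, ] <- -gain[flip, ]
  }
  rownames(gain) <- geometry$channels$name
  leadField(gain, geometry$channels, sp)
}

#' Specify a predictor-scaled source effect
#'
#' A Gaussian activation bump at one source whose amplitude scales linearly
#' with an item-level predictor: source amplitude contribution on trial t is
#' `beta * predictor(item_t) * exp(-(time - latency)^2 / (2 width^2))`.
#'
#' @param predictor predictor name the effect is tied to.
#' @param source target source (vertex) id.
#' @param latency peak latency in ms (e.g. ~100 for visual, ~150 for
#'   semantic/phonological effects).
#' @param width Gaussian SD in ms, default 20.
#' @param beta source amplitude per predictor SD, default 1.
#' @return an `effectSpec` list.
#' @export
effectSpec <- function(predictor, source, latency, width = 20, beta = 1) {
  stopifnot(width > 0)
  structure(list(predictor = predictor, source = as.integer(source),
                 latency = latency, width = width, beta = beta),
            class = "effectSpec")
}

#' Canonical study effects on the toy geometry
#'
#' Visual complexity at the centre of the occipital region at 100 ms, a
#' specific-semantic effect at the centre of pITG and a word-form effect at
#' the centre of pMTG, both at 150 ms.
#'
#' @param geometry from [toyGeometry].
#' @param beta common effect amplitude (source units per predictor SD).
#' @param width bump SD in ms.
#' @return list of [effectSpec] objects.
#' @export
defaultStudyEffects <- function(geometry, beta = 1, width = 20) {
  centre <- function(region) {
    v <- geometry$regions[[region]]
    v[ceiling(length(v) / 2)]
  }
  list(effectSpec("VisualComplexity", centre("Occ"), 100, width, beta),
       effectSpec("SpecificSemanticFeatures", centre("pITG"), 150, width,
                  beta),
       effectSpec("WordForm", centre("pMTG"), 150, width, beta))
}

#' Default per-kind sensor noise SDs
#'
#' Tuned once so that, with unit effect amplitudes and ~121 trials, the
#' predictor-specific ERRC SNR-RMS curves show clearly prominent peaks
#' (moderate single-trial SNR), comparable in prominence to real
#' picture-naming grand averages.
#'
#' @return named numeric vector (native units).
#' @export
defaultNoiseSD <- function() {
  c(magnetometer = 2e-13, gradiometer = 2e-11, eog = 1e-5)
}

#' Simulate one subject's epochs with known source effects
#'
#' Trial items are drawn without replacement up to the item count (each
#' picture named once), then with replacement. Source activity per trial is
#' the sum of the configured predictor-scaled effects plus an optional
#' predictor-independent evoked component; sensor data are the lead-field
#' projection plus independent Gaussian noise per channel scaled by the
#' channel kind's SD.
#'
#' @param lf a [LeadField-class].
#' @param predictors a [PredictorSet-class].
#' @param effects list of [effectSpec] objects (possibly empty).
#' @param nTrials trials to simulate, default 121.
#' @param noiseSD named per-kind noise SDs (native units); default
#'   [defaultNoiseSD]. Use 0 for noise-free data.
#' @param fs sampling rate, default 250 Hz.
#' @param tmin,tmax epoch window in ms, default -100..500.
#' @param evoked optional list of predictor-independent bumps, each a list
#'   with `source`, `latency`, `width`, `amplitude`.
#' @param seed RNG seed.
#' @return list with `epochs` (an [EpochSet-class]) and `truth` (effects,
#'   trial items, noise SDs, seed).
#' @export
simulateSubject <- function(lf, predictors, effects = list(),
                            nTrials = 121, noiseSD = defaultNoiseSD(),
                            fs = 250, tmin = -100, tmax = 500,
                            evoked = NULL, seed = 1) {
  times <- seq(tmin, tmax, by = 1000 / fs)
  ns <- length(times)
  for (e in effects)
    if (e$latency < tmin || e$latency > tmax)
      stop("effect latency ", e$latency, " ms outside the epoch")
  items <- rownames(predictors@values)
  set.seed(seed)
  trialItems <- if (nTrials <= length(items)) {
    sample(items, nTrials)
  } else {
    c(sample(items),
      sample(items, nTrials - length(items), replace = TRUE))
  }
  bump <- function(lat, wid) exp(-(times - lat)^2 / (2 * wid^2))
  nc <- nrow(lf@gain)
  base <- matrix(0, nc, ns)                  # evoked, shared across trials
  for (ev in evoked)
    base <- base + ev$amplitude * outer(lf@gain[, ev$source],
                                        bump(ev$latency, ev$width))
  ## trial-varying part: channels x samples contribution per effect
  effGain <- if (length(effects))
    vapply(effects, function(e) lf@gain[, e$source], numeric(nc))
  effWave <- if (length(effects))
    t(vapply(effects, function(e) e$beta * bump(e$latency, e$width),
             numeric(ns)))
  effX <- if (length(effects))
    vapply(effects, function(e) predictors@values[trialItems, e$predictor],
           numeric(nTrials))
  sdCh <- rep(0, nc)
  known <- intersect(names(noiseSD), unique(lf@channels$kind))
  sdCh <- unname(ifelse(lf@channels$kind %in% known,
                        noiseSD[lf@channels$kind], 0))
  data <- array(0, dim = c(nTrials, nc, ns))
  for (tr in seq_len(nTrials)) {
    sig <- base
    if (length(effects))
      sig <- sig + effGain %*% (effX[tr, ] * effWave)
    if (any(sdCh > 0))
      sig <- sig + matrix(stats::rnorm(nc * ns), nc, ns) * sdCh
    data[tr, , ] <- sig
  }
  epochs <- epochSet(data, lf@channels, fs, tmin, trialItems)
  list(epochs = epochs,
       truth = list(effects = effects, trialItems = trialItems,
                    noiseSD = noiseSD, evoked = evoked, seed = seed))
}

#' Simulate a multi-subject study
#'
#' Independent subject simulations sharing one lead field and item set.
#' Per-subject seeds are derived from the master seed by drawing
#' `nSubjects` integers from the master-seeded RNG; subject-level
#' variability is modelled as additive Gaussian jitter on each effect's
#' beta.
#'
#' @param nSubjects number of subjects, default 17.
#' @param lf,predictors,effects,nTrials,noiseSD,fs,tmin,tmax,evoked passed
#'   to [simulateSubject].
#' @param betaJitterSD SD of the per-subject additive beta jitter, default
#'   0.2.
#' @param seed master seed.
#' @return list of per-subject results (`epochs`, `truth`).
#' @export
simulateStudy <- function(nSubjects = 17, lf, predictors,
                          effects = list(), nTrials = 121,
                          noiseSD = defaultNoiseSD(), fs = 250,
                          tmin = -100, tmax = 500, evoked = NULL,
                          betaJitterSD = 0.2, seed = 1) {
  stopifnot(nSubjects >= 2L)
  set.seed(seed)
  subjectSeeds <- sample.int(.Machine$integer.max - 1L, nSubjects)
  jitter <- if (betaJitterSD > 0 && length(effects))
    matrix(stats::rnorm(nSubjects * length(effects), 0, betaJitterSD),
           nSubjects)
  else matrix(0, nSubjects, max(1L, length(effects)))
  lapply(seq_len(nSubjects), function(i) {
    eff <- effects
    for (j in seq_along(eff))
      eff[[j]]$beta <- eff[[j]]$beta + jitter[i, j]
    simulateSubject(lf, predictors, eff, nTrials, noiseSD, fs, tmin,
                    tmax, evoked, seed = subjectSeeds[i])
  })
}
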