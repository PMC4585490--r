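test_that("makeItemSet reproduces the target correlation structure", {
  # identity target at large n: all off-diagonal correlations near zero
  big <- makeItemSet(nItems = 10000, targetCorr = diag(4),
                     predictorNames = paste0("P", 1:4), seed = 2)
  C <- cor(big@values)
  expect_lt(max(abs(C[upper.tri(C)])), 0.05)
  # default target carries the moderate visual-action correlation
  expect_equal(defaultPredictorCorr()["VisualComplexity", "ActionFeatures"],
               -0.39)
  ps <- makeItemSet(nItems = 5000, seed = 3)
  expect_equal(cor(ps@values)["VisualComplexity", "ActionFeatures"], -0.39,
               tolerance = 0.05)
  # columns exactly standardized, determinism from the seed
  expect_equal(unname(colMeans(ps@values)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(ps@values, 2, sd)), rep(1, 4),
               tolerance = 1e-12)
  expect_identical(makeItemSet(seed = 7)@values, makeItemSet(seed = 7)@values)
  bad <- matrix(0.99, 3, 3); diag(bad) <- 1; bad[1, 2] <- bad[2, 1] <- -0.99
  expect_error(makeItemSet(10, targetCorr = bad), "positive")
})

test_that("makeLeadfield builds distance-decaying, type-scaled gains", {
  geom <- toyGeometry(nSources = 10,
                      nSensors = c(magnetometer = 5, gradiometer = 5))
  lf <- makeLeadfield(geom, seed = 4)
  # the source right under a sensor has that sensor's largest gain
  mag1 <- which(geom$channels$kind == "magnetometer")[3]   # mid-array
  nearest <- which.min(abs(geom$sourcePos[, 1] -
                           geom$sensorPos[mag1, 1]))
  expect_equal(which.max(abs(lf@gain[mag1, ])), nearest)
  # type scales separate magnetometers and gradiometers by orders of magnitude
  magMax <- max(abs(lf@gain[geom$channels$kind == "magnetometer", ]))
  gradMax <- max(abs(lf@gain[geom$channels$kind == "gradiometer", ]))
  expect_equal(gradMax / magMax, 100, tolerance = 0.2)
  # determinism and distinct gain columns
  expect_identical(lf@gain, makeLeadfield(geom, seed = 4)@gain)
  expect_gt(min(vapply(2:10, function(s)
    max(abs(lf@gain[, s] - lf@gain[, s - 1])), numeric(1))), 0)
  geomBad <- geom; geomBad$sourcePos[2, ] <- geomBad$sourcePos[1, ]
  expect_error(makeLeadfield(geomBad, seed = 4), "coincident")
})

test_that("simulateSubject injects exact predictor-scaled source effects", {
  geom <- unitGeometry()
  lf <- makeLeadfield(geom, seed = 5)
  preds <- makeItemSet(nItems = 24, seed = 5)
  noiseOff <- c(magnetometer = 0, gradiometer = 0)
  # no effects, no noise, no evoked: silence
  quiet <- simulateSubject(lf, preds, effects = list(), nTrials = 10,
                           noiseSD = noiseOff, seed = 6)
  expect_equal(max(abs(quiet$epochs@data)), 0)
  # noise-free single effect: sensor data are exactly gain x beta x predictor x bump
  eff <- list(effectSpec("WordForm", source = 3, latency = 150, width = 20,
                         beta = 2))
  sim <- simulateSubject(lf, preds, eff, nTrials = 12, noiseSD = noiseOff,
                         fs = 250, seed = 6)
  times <- epochTimes(sim$epochs)
  bump <- exp(-(times - 150)^2 / (2 * 20^2))
  x <- preds@values[sim$truth$trialItems, "WordForm"]
  for (tr in c(1, 7)) {
    expect_equal(sim$epochs@data[tr, , ],
                 unname(outer(lf@gain[, 3], 2 * x[tr] * bump)),
                 tolerance = 1e-12)
  }
  # determinism; latency validation
  sim2 <- simulateSubject(lf, preds, eff, nTrials = 12, noiseSD = noiseOff,
                          fs = 250, seed = 6)
  expect_identical(sim$epochs@data, sim2$epochs@data)
  expect_error(simulateSubject(lf, preds,
                               list(effectSpec("WordForm", 1, 900)),
                               seed = 1),
               "outside the epoch")
})

test_that("trial items are drawn without replacement up to the item count", {
  geom <- unitGeometry()
  lf <- makeLeadfield(geom, seed = 5)
  preds <- makeItemSet(nItems = 20, seed = 5)
  s <- simulateSubject(lf, preds, nTrials = 20,
                       noiseSD = c(magnetometer = 0, gradiometer = 0),
                       seed = 8)
  expect_setequal(s$truth$trialItems, rownames(preds@values))
  s2 <- simulateSubject(lf, preds, nTrials = 30,
                        noiseSD = c(magnetometer = 0, gradiometer = 0),
                        seed = 8)
  expect_true(all(table(s2$truth$trialItems[1:20]) == 1))
})

test_that("slope estimates are unbiased over replicate noisy subjects", {
  geom <- unitGeometry(nSources = 6,
                       nSensors = c(magnetometer = 4, gradiometer = 4))
  lf <- makeLeadfield(geom, seed = 9)
  preds <- makeItemSet(nItems = 20, seed = 9)
  eff <- list(effectSpec("VisualComplexity", source = 2, latency = 100,
                         width = 20, beta = 2))
  # channel and sample where the effect projects most strongly
  ch <- which.max(abs(lf@gain[, 2]))
  nrep <- 200
  est <- numeric(nrep)
  for (r in seq_len(nrep)) {
    s <- simulateSubject(lf, preds, eff, nTrials = 20,
                         noiseSD = c(magnetometer = 0.5, gradiometer = 0.5),
                         fs = 100, tmin = -100, tmax = 300, seed = 1000 + r)
    design <- assembleDesign(preds, trialItems(s$epochs))
    errc <- computeERRC(baselineCorrect(s$epochs), design)
    ti <- which.min(abs(epochTimes(errc) - 100))
    est[r] <- errc@coefficients["VisualComplexity", ch, ti]
  }
  truth <- 2 * lf@gain[ch, 2]            # beta x gain at the peak latency
  mcse <- sd(est) / sqrt(nrep)
  expect_lt(abs(mean(est) - truth), 3 * mcse)
})

test_that("effects do not leak across orthogonal predictors", {
  geom <- unitGeometry()
  lf <- makeLeadfield(geom, seed = 10)
  preds <- .predictorSetFromMatrix(
    {set.seed(12); m <- qr.Q(qr(matrix(rnorm(40), 20, 2))) * sqrt(19)
     dimnames(m) <- list(sprintf("item%03d", 1:20), c("A", "B")); m})
  eff <- list(effectSpec("A", source = 2, latency = 150, width = 20,
                         beta = 3))
  s <- simulateSubject(lf, preds, eff, nTrials = 20,
                       noiseSD = c(magnetometer = 0, gradiometer = 0),
                       fs = 250, seed = 13)
  errc <- computeERRC(baselineCorrect(s$epochs),
                      assembleDesign(preds, trialItems(s$epochs)))
  expect_gt(max(abs(errc@coefficients["A", , ])), 0.5)
  expect_lt(max(abs(errc@coefficients["B", , ])), 1e-10)
})

test_that("simulateStudy derives reproducible per-subject simulations", {
  geom <- unitGeometry()
  lf <- makeLeadfield(geom, seed = 5)
  preds <- makeItemSet(nItems = 12, seed = 5)
  study <- simulateStudy(nSubjects = 17, lf = lf, predictors = preds,
                         nTrials = 6, seed = 14)
  expect_length(study, 17L)
  expect_identical(
    study[[3]]$epochs@data,
    simulateStudy(nSubjects = 17, lf = lf, predictors = preds, nTrials = 6,
                  seed = 14)[[3]]$epochs@data)
  # zero jitter, zero noise: subjects identical up to trial order
  eff <- list(effectSpec("WordForm", 3, 150, 20, 2))
  st <- simulateStudy(nSubjects = 2, lf = lf, predictors = preds,
                      effects = eff, nTrials = 12,
                      noiseSD = c(magnetometer = 0, gradiometer = 0),
                      betaJitterSD = 0, seed = 15)
  o1 <- order(st[[1]]$truth$trialItems)
  o2 <- order(st[[2]]$truth$trialItems)
  expect_equal(st[[1]]$epochs@data[o1, , ], st[[2]]$epochs@data[o2, , ],
               tolerance = 1e-12)
})

test_that("the full pipeline recovers an injected effect's latency and locus", {
  geom <- toyGeometry()
  lf <- makeLeadfield(geom, seed = 2)
  preds <- makeItemSet(seed = 3)
  eff <- defaultStudyEffects(geom)
  study <- simulateStudy(nSubjects = 17, lf = lf, predictors = preds,
                         effects = eff, seed = 11)
  res <- analyzeStudy(study, preds, lf, geom$regions)
  # SNR-RMS peak of the word-form coefficient within 10 ms of 150
  wfPeaks <- res$peaks$WordForm
  expect_true(any(abs(wfPeaks - 150) <= 10))
  # the pMTG x WordForm cell has the largest intensity for WordForm
  wf <- res$table[res$table$predictor == "WordForm", ]
  expect_equal(wf$roi[which.max(wf$mean)], "pMTG")
  expect_true(wf$significant[wf$roi == "pMTG"])
})
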