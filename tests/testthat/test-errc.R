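test_that("linearEstimator reproduces the normal equations and weights", {
  # intercept-only: every trial weighted 1/n (the plain average)
  est <- linearEstimator(interceptDesign(rep("a", 7)))
  expect_equal(unname(est@G), matrix(1 / 7, 1, 7))
  # orthonormal design: G = X'
  Q <- qr.Q(qr(matrix(rnorm(30), 10, 3)))
  est2 <- linearEstimator(rawDesign(Q))
  expect_equal(unname(est2@G), t(Q), tolerance = 1e-10)
  # random design vs normal-equation oracle
  set.seed(11)
  X <- cbind(1, matrix(rnorm(40), 20, 2))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  est3 <- linearEstimator(rawDesign(X, intercept = TRUE))
  expect_equal(max(abs(est3@G %*% X - diag(3))), 0, tolerance = 1e-10)
  expect_equal(unname(est3@G), unname(solve(t(X) %*% X) %*% t(X)),
               tolerance = 1e-10)
  # rank deficiency is an error naming the collinear column
  Xb <- cbind(a = rnorm(10), b = 1:10, c = 2 * (1:10))
  expect_error(linearEstimator(rawDesign(Xb)), "collinear")
  expect_error(linearEstimator(rawDesign(matrix(rnorm(6), 2, 3))),
               "as many trials")
  # a saturated (square, invertible) design is allowed: exact interpolation
  sat <- linearEstimator(rawDesign(cbind(a = c(1, 1), b = c(1, 0))))
  expect_equal(unname(sat@G %*% sat@design@X), diag(2), tolerance = 1e-12)
})

test_that("computeERRC equals per-point OLS and recovers exact slopes", {
  set.seed(21)
  nTr <- 30; nCh <- 4; nS <- 25
  x <- standardize(rnorm(nTr))
  X <- cbind(`(Intercept)` = 1, pred = x)
  dm <- rawDesign(X, intercept = TRUE)
  # identical data on every trial: slope 0, intercept = the common signal
  common <- matrix(rnorm(nCh * nS), nCh)
  data <- array(rep(common, each = nTr), c(nTr, nCh, nS))
  ep <- epochSet(data, channelInfo(paste0("c", 1:nCh), "magnetometer"),
                 fs = 1000, t0 = 0)
  errc <- computeERRC(ep, dm)
  expect_equal(unname(errc@coefficients[2, , ]), matrix(0, nCh, nS),
               tolerance = 1e-10)
  expect_equal(unname(errc@coefficients[1, , ]), common, tolerance = 1e-10)
  # noise-free y = 2 * x * w(t): slope recovered exactly
  w <- sin(seq(0, pi, length.out = nS))
  data2 <- array(0, c(nTr, 1, nS))
  for (tr in seq_len(nTr)) data2[tr, 1, ] <- 2 * x[tr] * w
  ep2 <- epochSet(data2, channelInfo("c1", "magnetometer"), 1000, 0)
  errc2 <- computeERRC(ep2, rawDesign(X, intercept = TRUE))
  expect_equal(unname(errc2@coefficients[2, 1, ]), 2 * w, tolerance = 1e-12)
  # trial mismatch is an error
  expect_error(computeERRC(ep, rawDesign(X[1:10, ], intercept = TRUE)),
               "mismatch")
})

test_that("computeERRC is linear and its intercept is the grand mean", {
  set.seed(22)
  nTr <- 15; nCh <- 3; nS <- 10
  x <- standardize(rnorm(nTr))           # centered predictor
  dm <- rawDesign(cbind(`(Intercept)` = 1, x = x), intercept = TRUE)
  mk <- function() randomEpochs(nTr, nCh, nS, fs = 1000, t0 = 0)
  a <- mk(); b <- mk()
  ab <- a; ab@data <- a@data + b@data
  ea <- computeERRC(a, dm); eb <- computeERRC(b, dm)
  eab <- computeERRC(ab, dm)
  expect_equal(eab@coefficients, ea@coefficients + eb@coefficients,
               tolerance = 1e-10)
  expect_equal(unname(ea@coefficients[1, , ]), apply(a@data, c(2, 3), mean),
               tolerance = 1e-10)
})

test_that("EOG channels are excluded from the regression", {
  set.seed(23)
  ch <- channelInfo(c("m1", "g1", "eog1"),
                    c("magnetometer", "gradiometer", "eog"))
  ep <- epochSet(array(rnorm(10 * 3 * 8), c(10, 3, 8)), ch, 1000, 0)
  errc <- computeERRC(ep, interceptDesign(ep@trialItems))
  expect_equal(nrow(errc@channels), 2L)
  expect_false("eog1" %in% errc@channels$name)
})

test_that("factorialWeights reduce regression to a condition-mean difference", {
  expect_equal(factorialWeights(3, 2), c(1/3, 1/3, 1/3, -1/2, -1/2))
  expect_equal(factorialWeights(1, 1), c(1, -1))
  expect_equal(sum(factorialWeights(3, 2) * c(1, 2, 3, 10, 20)), -13)
  expect_error(factorialWeights(0, 2))
  # dummy-coded binary design: ERRC slope = difference of category means
  y <- c(1, 2, 3, 10, 20)
  X <- cbind(`(Intercept)` = 1, grp = c(1, 1, 1, 0, 0))
  ep <- epochSet(array(y, c(5, 1, 1)), channelInfo("c", "magnetometer"),
                 1000, 0)
  errc <- computeERRC(ep, rawDesign(X, intercept = TRUE))
  expect_equal(errc@coefficients[2, 1, 1], mean(y[1:3]) - mean(y[4:5]),
               tolerance = 1e-12)
  expect_equal(errc@coefficients[2, 1, 1],
               sum(factorialWeights(3, 2) * y), tolerance = 1e-12)
})

test_that("snrTimecourse scales by baseline SD and is unit-invariant", {
  fs <- 1000; t0 <- -100
  set.seed(31)
  base <- matrix(rnorm(2 * 101, sd = 2), 2)    # baseline -100..0
  sig <- matrix(6, 2, 100)
  series <- cbind(base, sig)
  snr <- snrTimecourse(series, fs, t0, baseline = c(-100, 0))
  sd1 <- sd(base[1, ])
  expect_equal(snr[1, 150], 6 / sd1, tolerance = 1e-12)
  snr2 <- snrTimecourse(series * c(10, 1), fs, t0, baseline = c(-100, 0))
  expect_equal(snr, snr2, tolerance = 1e-12)
  expect_error(snrTimecourse(rbind(series, 0), fs, t0, c(-100, 0)), "zero")
  # white noise: SNR values have SD ~ 1
  noise <- matrix(rnorm(10000), 1)
  s <- snrTimecourse(noise, 1000, -5000, baseline = c(-5000, 0))
  expect_equal(sd(s), 1, tolerance = 0.05)
})

test_that("rmsAcrossChannels is the root mean square over channels", {
  fs <- 1000; t0 <- 0
  expect_equal(seriesValues(rmsAcrossChannels(matrix(3, 5, 4), fs, t0)),
               rep(3, 4))
  expect_equal(seriesValues(rmsAcrossChannels(matrix(c(3, 4), 2, 1), fs, t0)),
               sqrt(25 / 2), tolerance = 1e-12)
  set.seed(32)
  m <- matrix(rnorm(60), 6)
  expect_equal(seriesValues(rmsAcrossChannels(m, fs, t0)),
               apply(m, 2, function(col) sqrt(mean(col^2))),
               tolerance = 1e-12)
})

test_that("findPeaks locates prominent local maxima within the window", {
  fs <- 1000; t <- seq(-100, 500)
  g <- function(mu, sd, a = 1) a * exp(-(t - mu)^2 / (2 * sd^2))
  one <- new("SummarySeries", values = g(150, 30), fs = fs, t0 = -100,
             kind = "snr_rms")
  expect_equal(findPeaks(one), 150)
  two <- new("SummarySeries", values = g(100, 15) + 0.9 * g(165, 15),
             fs = fs, t0 = -100, kind = "snr_rms")
  expect_equal(findPeaks(two), c(100, 165))
  ramp <- new("SummarySeries", values = seq_along(t) / 100, fs = fs,
              t0 = -100, kind = "snr_rms")
  expect_equal(findPeaks(ramp), numeric(0))
  # low-prominence shoulder is filtered out
  shoulder <- new("SummarySeries", values = g(150, 30) + 0.05 * g(250, 8),
                  fs = fs, t0 = -100, kind = "snr_rms")
  expect_equal(findPeaks(shoulder, minProminence = 0.25), 150)
})
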