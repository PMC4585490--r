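# fixtures and independent mini-oracles shared across test files

# sum-formula Pearson correlation, independent of stats::cor
pearsonOracle <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  num / den
}

# random magnetometer-only epochs with unit-scale noise
randomEpochs <- function(nTrials, nCh, nS, fs = 1000, t0 = -100,
                         trialItems = paste0("trial", seq_len(nTrials))) {
  epochSet(array(rnorm(nTrials * nCh * nS), c(nTrials, nCh, nS)),
           channelInfo(paste0("ch", seq_len(nCh)), "magnetometer"),
           fs = fs, t0 = t0, trialItems = trialItems)
}

# bare design matrix without going through a PredictorSet
rawDesign <- function(X, intercept = FALSE,
                      trialItems = paste0("trial", seq_len(nrow(X)))) {
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  new("DesignMatrix", X = X, trialItems = trialItems,
      hasIntercept = intercept)
}

# small unit-scale geometry: well-separated sources, order-1 gains
unitGeometry <- function(nSources = 6, nSensors = c(magnetometer = 5,
                                                    gradiometer = 5)) {
  toyGeometry(nSources = nSources, nSensors = nSensors,
              typeScales = c(magnetometer = 1, gradiometer = 0.5))
}

# norm table fixture: 2 correlated measures + 1 independent, n items
normFixture <- function(n = 20, seed = 7) {
  set.seed(seed)
  a <- rnorm(n)
  data.frame(item_id = sprintf("it%02d", seq_len(n)),
             m1 = a + rnorm(n, sd = 0.5),
             m2 = a + rnorm(n, sd = 0.5),
             m3 = rnorm(n))
}

# behavioral response fixture constructed to the exclusion rules:
# 20 records, 2 wrong names, 1 hesitation, 2 out of range, 1 outlier
responseFixture <- function() {
  lat <- c(700, 720, 680, 710, 690, 705, 715, 695, 700, 710,
           720, 690, 700, 250, 2500, 705, 695, 1400, 700, 710)
  rec <- data.frame(
    trial = 1:20,
    item = rep(sprintf("it%02d", 1:10), 2),
    subject = "s1",
    name = rep("ok", 20),
    latency = lat,
    hesitation = FALSE,
    stringsAsFactors = FALSE)
  rec$name[c(3, 8)] <- "wrong"        # rule 1
  rec$hesitation[5] <- TRUE           # rule 2
  # rows 14 (250 ms) and 15 (2500 ms) violate the range (rule 3);
  # row 18 (1400 ms) is the sole >2.5 SD outlier among survivors (rule 4)
  rec
}

validNamesFixture <- function() {
  nm <- as.list(rep("ok", 10))
  names(nm) <- sprintf("it%02d", 1:10)
  nm
}
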