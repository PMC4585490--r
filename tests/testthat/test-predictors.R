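test_that("standardize matches the n-1 SD convention and is affine-equivariant", {
  expect_equal(standardize(c(-1, 1)), c(-1, 1) / sqrt(2))
  expect_equal(standardize(c(1, 2, 3, 4)),
               c(-1.161895, -0.387298, 0.387298, 1.161895),
               tolerance = 1e-6)
  v <- rnorm(25)
  z <- standardize(v)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(standardize(3.2 * v - 7), z)
  expect_equal(standardize(-2 * v + 1), -z)
  expect_error(standardize(c(5, 5, 5)), "zero variance")
  expect_error(standardize(c(1, NA, NA)), "finite")
})

test_that("deriveComposite reduces to standardization for degenerate inputs", {
  tab <- data.frame(item_id = letters[1:4], m = c(1, 2, 3, 4))
  comp <- deriveComposite(tab, "m", name = "single")
  expect_equal(unname(comp@values), standardize(c(1, 2, 3, 4)))
  expect_equal(comp@explainedVariance, 1)

  # exact duplicate measures: rank-1 correlation, PC1 carries everything
  tab2 <- data.frame(item_id = letters[1:5], a = c(3, 1, 4, 1, 5),
                     b = 2 * c(3, 1, 4, 1, 5) + 7)
  comp2 <- deriveComposite(tab2, c("a", "b"))
  expect_equal(comp2@explainedVariance, 1, tolerance = 1e-12)
  expect_equal(unname(comp2@values), standardize(tab2$a), tolerance = 1e-10)
})

test_that("deriveComposite matches an independent PCA and fixes the sign", {
  tab <- normFixture(5)
  comp <- deriveComposite(tab, c("m1", "m2"))
  # independent oracle: prcomp on the scaled measures (SVD route)
  pc1 <- prcomp(tab[, c("m1", "m2")], center = TRUE, scale. = TRUE)$x[, 1]
  ref <- standardize(pc1)
  if (cor(ref, comp@values) < 0) ref <- -ref
  expect_equal(unname(comp@values), unname(ref), tolerance = 1e-10)
  expect_gt(comp@loadings[["m1"]], 0)          # orientation measure
  # two z-scored measures always load (1,1)/sqrt(2) on PC1
  expect_equal(unname(abs(comp@loadings)), rep(1 / sqrt(2), 2),
               tolerance = 1e-12)
})

test_that("composites are invariant to affine rescaling of input measures", {
  tab <- normFixture(30)
  comp <- deriveComposite(tab, c("m1", "m2"), orientation = "m1")
  tab2 <- tab
  tab2$m2 <- 100 * tab2$m2 - 3          # rescale one measure
  comp2 <- deriveComposite(tab2, c("m1", "m2"), orientation = "m1")
  expect_equal(comp@values, comp2@values, tolerance = 1e-10)
})

test_that("deriveComposite validates inputs and logs missing-item exclusion", {
  tab <- normFixture(10)
  expect_error(deriveComposite(tab, c("m1", "nope")), "nope")
  tab$flat <- 1
  expect_error(deriveComposite(tab, c("m1", "flat")), "zero-variance")
  tab$m2[3] <- NA
  comp <- deriveComposite(tab, c("m1", "m2"))
  expect_equal(comp@excludedItems, tab$item_id[3])
  expect_equal(length(comp@values), 9L)
})

test_that("correlationReport matches a brute-force Pearson oracle", {
  set.seed(42)
  tab <- normFixture(100, seed = 42)
  ps <- predictorSet(deriveComposite(tab, c("m1", "m2"), name = "AB"),
                     deriveComposite(tab, "m3", name = "C"))
  rep <- correlationReport(ps, tab)
  expect_equal(rep["AB", "AB"], 1)
  expect_equal(abs(rep["C", "m3"]), 1, tolerance = 1e-12)  # monotone affine
  for (i in rownames(rep)) {
    for (j in colnames(rep)) {
      a <- ps@values[, i]
      b <- if (j %in% colnames(ps@values)) ps@values[, j]
           else tab[match(rownames(ps@values), tab$item_id), j]
      expect_equal(rep[i, j], pearsonOracle(a, b), tolerance = 1e-12)
    }
  }
  expect_error(correlationReport(ps, tab[1:2, ]), "common items")
})

test_that("tFromR implements the closed form and behaves monotonically", {
  expect_equal(tFromR(0, 146)$t, 0)
  expect_equal(tFromR(0, 146)$df, 144)
  expect_equal(tFromR(0.5, 146)$t, 0.5 * 12 / sqrt(0.75), tolerance = 1e-12)
  r49 <- tFromR(0.49, 146)
  expect_equal(r49$t, 0.49 * sqrt(144) / sqrt(1 - 0.49^2), tolerance = 1e-12)
  expect_equal(r49$t, 6.7459, tolerance = 1e-4)
  expect_lt(r49$p, 1e-4)
  # strictly increasing in r (fixed n) and n (fixed r > 0)
  rs <- seq(0.1, 0.9, by = 0.1)
  ts <- vapply(rs, function(r) tFromR(r, 50)$t, numeric(1))
  expect_true(all(diff(ts) > 0))
  ns <- c(10, 20, 50, 100, 200)
  tn <- vapply(ns, function(n) tFromR(0.3, n)$t, numeric(1))
  expect_true(all(diff(tn) > 0))
  expect_warning(out <- tFromR(1, 20), "infinite")
  expect_identical(out$t, Inf)
})

test_that("assembleDesign maps items to trials with an optional intercept", {
  ps <- makeItemSet(nItems = 8, seed = 1)
  trials <- c("item001", "item002", "item001", "item005")
  dm <- assembleDesign(ps, trials)
  expect_true(dm@hasIntercept)
  expect_equal(ncol(dm@X), 5L)                  # intercept + 4 predictors
  expect_equal(dm@X[1, -1], dm@X[3, -1])        # same item, same row
  expect_equal(unname(dm@X[2, -1]), unname(ps@values["item002", ]))
  dm2 <- assembleDesign(ps, trials, intercept = FALSE)
  expect_equal(ncol(dm2@X), 4L)
  expect_error(assembleDesign(ps, c("item001", "ghost")), "ghost")
  # intercept-only design: a column of ones
  i5 <- interceptDesign(rep("item001", 5))
  expect_equal(unname(i5@X), matrix(1, 5, 1))
})

test_that("predictor sets round-trip through CSV", {
  tab <- normFixture(20)
  ps <- predictorSet(deriveComposite(tab, c("m1", "m2"), name = "AB"),
                     deriveComposite(tab, "m3", name = "C"))
  path <- tempfile(fileext = ".csv")
  writePredictorSet(ps, path)
  back <- readPredictorSet(path)
  expect_equal(back@values, ps@values, tolerance = 1e-12)
  expect_true(file.exists(sub("\\.csv$", "_loadings.csv", path)))
})
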