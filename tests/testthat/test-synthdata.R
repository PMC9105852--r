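test_that("default configuration yields the canonical 200 normal + 300 cirrhosis dataset", {
  ds <- generateDataset(syntheticConfig(seed = 3))
  expect_equal(nImages(ds), 500L)
  cc <- classCounts(ds)
  expect_equal(unname(cc[["normal"]]), 200L)
  expect_equal(unname(cc[["cirrhosis"]]), 300L)
  expect_equal(imageSide(ds), 32L)
  expect_equal(fmaxLevel(ds), 255L)
  expect_true(min(ds@images) >= 0L && max(ds@images) <= 255L)
  expect_false(anyDuplicated(roiIds(ds)) > 0)
})

test_that("generation is byte-identical under one seed and differs across seeds", {
  cfg <- syntheticConfig(nNormal = 10, nCirrhosis = 15, size = 8, seed = 9)
  a <- generateDataset(cfg)
  b <- generateDataset(cfg)
  expect_identical(a@images, b@images)
  expect_identical(roiIds(a), roiIds(b))
  c <- generateDataset(syntheticConfig(nNormal = 10, nCirrhosis = 15, size = 8,
                                       seed = 10))
  expect_false(identical(a@images, c@images))
  # single-ROI determinism contract
  r1 <- generateROI(100, cfg, seed = 5)
  r2 <- generateROI(100, cfg, seed = 5)
  expect_identical(pixels(r1), pixels(r2))
})

test_that("the near-noiseless limit produces a uniform image at the class mean", {
  cfg <- syntheticConfig(speckleScale = 1e-6, size = 16, seed = 1)
  img <- generateROI(137.2, cfg, seed = 1)
  expect_true(all(pixels(img) == 137L))
})

test_that("the speckle field is unit-mean: sample mean tracks the class mean", {
  cfg <- syntheticConfig(seed = 4)
  img <- generateROI(100, cfg, seed = 21)
  expect_lt(abs(mean(pixels(img)) - 100), 10)
  # and across many ROIs the average is tighter
  ms <- vapply(1:40, function(s) mean(pixels(generateROI(100, cfg, seed = s))),
               numeric(1))
  expect_lt(abs(mean(ms) - 100), 3)
})

test_that("a planted class-mean gap is recovered in the generated data", {
  ds <- generateDataset(syntheticConfig(muNormal = 90, muCirrhosis = 120, seed = 8))
  gap <- mean(ds@images[, , roiLabels(ds) == "cirrhosis"]) -
         mean(ds@images[, , roiLabels(ds) == "normal"])
  expect_lt(abs(gap - 30), 5)
})

test_that("equal class means leave no systematic class difference", {
  ds <- generateDataset(syntheticConfig(muNormal = 100, muCirrhosis = 100, seed = 6))
  gap <- mean(ds@images[, , roiLabels(ds) == "cirrhosis"]) -
         mean(ds@images[, , roiLabels(ds) == "normal"])
  expect_lt(abs(gap), 3)
})

test_that("cirrhosis images are lighter than normal under the default config", {
  ds <- generateDataset(syntheticConfig(seed = 2))
  expect_gt(mean(ds@images[, , roiLabels(ds) == "cirrhosis"]),
            mean(ds@images[, , roiLabels(ds) == "normal"]))
})

test_that("invalid generator configurations are rejected", {
  expect_error(syntheticConfig(nNormal = 0), "counts")
  expect_error(syntheticConfig(muNormal = 0), "class means")
  expect_error(syntheticConfig(muCirrhosis = 300), "class means")
  expect_error(syntheticConfig(speckleScale = 0), "speckleScale")
  expect_error(syntheticConfig(correlationSigma = -1), "correlationSigma")
})

test_that("smoothing correlates neighbouring pixels relative to the raw field", {
  cfg0 <- syntheticConfig(correlationSigma = 0, seed = 1)
  cfg2 <- syntheticConfig(correlationSigma = 2, seed = 1)
  lag1 <- function(img) {
    p <- pixels(img)
    stats::cor(as.numeric(p[, -1]), as.numeric(p[, -ncol(p)]))
  }
  r0 <- mean(vapply(1:10, function(s) lag1(generateROI(100, cfg0, seed = s)), numeric(1)))
  r2 <- mean(vapply(1:10, function(s) lag1(generateROI(100, cfg2, seed = s)), numeric(1)))
  expect_gt(r2, r0 + 0.3)
})
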