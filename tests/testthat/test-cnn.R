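test_that("the architecture arithmetic matches the 32 -> 16 -> 8 reduction", {
  m <- buildCNN(cnnConfig())
  expect_equal(flattenWidth(m), 2048L)
  expect_equal(m@layers$shape[m@layers$layer == "flatten"], "2048")
  expect_equal(m@layers$shape[m@layers$layer == "maxpool1"], "16x16x32")
  expect_equal(m@layers$shape[m@layers$layer == "maxpool2"], "8x8x32")
  expect_equal(m@layers$shape[m@layers$layer == "dense+softmax"], "2")
  # a larger input is rejected unless the flatten spec adapts
  expect_error(cnnConfig(inputSide = 64), "flattenWidth")
  m64 <- buildCNN(cnnConfig(inputSide = 64, flattenWidth = 8192L))
  expect_equal(flattenWidth(m64), 8192L)
  expect_error(cnnConfig(inputSide = 30), "multiple of 4")
})

test_that("a linearly separable degenerate task is learned to zero training error", {
  ds <- constantDataset(50, 50, 40L, 215L)
  fit <- trainCNN(cnnConfig(seed = 3), ds, epochs = 20L, batchSize = 10L)
  p <- predict(fit, ds)
  expect_equal(mean(p$class != roiLabels(ds)), 0)
  # held-out constant images on either side of the trained values
  held <- constantDataset(5, 5, 55L, 200L)
  ph <- predict(fit, held)
  expect_equal(mean(ph$class != roiLabels(held)), 0)
})

test_that("softmax probabilities are a valid distribution and predict is pure", {
  ds <- constantDataset(10, 10, 60L, 180L)
  fit <- trainCNN(cnnConfig(seed = 1), ds, epochs = 3L, batchSize = 5L)
  p1 <- predict(fit, ds)
  expect_true(all(abs(rowSums(p1$prob) - 1) < 1e-6))
  expect_true(all(p1$prob >= 0))
  p2 <- predict(fit, ds)
  expect_identical(p1$prob, p2$prob)
  expect_identical(p1$class, p2$class)
})

test_that("training is deterministic in the seed and does not mutate the data", {
  ds <- smallSpeckleDataset(10, 15, side = 16)
  before <- ds@images
  cfg <- cnnConfig(inputSide = 16L, flattenWidth = 32L * 16L, seed = 11)
  f1 <- trainCNN(cfg, ds, epochs = 4L, batchSize = 5L)
  f2 <- trainCNN(cfg, ds, epochs = 4L, batchSize = 5L)
  expect_identical(trainingHistory(f1)$loss, trainingHistory(f2)$loss)
  expect_identical(f1@weights$W4, f2@weights$W4)
  expect_identical(ds@images, before)
  f3 <- trainCNN(cfg, ds, seed = 12, epochs = 4L, batchSize = 5L)
  expect_false(identical(trainingHistory(f1)$loss, trainingHistory(f3)$loss))
})

test_that("training error runs below test error on a noisy task (overfitting direction)", {
  ds <- generateDataset(syntheticConfig(nNormal = 60, nCirrhosis = 90,
                                        muNormal = 90, muCirrhosis = 110,
                                        seed = 31))
  sp <- makeSplits(ds, splitSpec(nTrials = 3, trainNormal = 48,
                                 trainCirrhosis = 72, testNormal = 12,
                                 testCirrhosis = 18, baseSeed = 2))
  gaps <- vapply(seq_len(3), function(i) {
    tr <- sp@trials[[i]]
    fit <- trainCNN(cnnConfig(seed = sp@classifierSeeds[i]), ds[tr$train],
                    epochs = 25L, batchSize = 40L)
    trainErr <- mean(predict(fit, ds[tr$train])$class != roiLabels(ds)[tr$train])
    testErr <- mean(predict(fit, ds[tr$test])$class != roiLabels(ds)[tr$test])
    testErr - trainErr
  }, numeric(1))
  expect_gte(mean(gaps), 0)
})

test_that("input contract violations are caught", {
  ds <- constantDataset(3, 3, 10L, 200L, side = 16L)
  cfg16 <- cnnConfig(inputSide = 16L, flattenWidth = 512L)
  fit <- trainCNN(cfg16, ds, epochs = 1L)
  expect_error(predict(fit, constantDataset(2, 2, 5L, 9L, side = 32L)), "side")
  expect_error(trainCNN(cnnConfig(), ds), "input side")
  expect_error(trainCNN(cfg16, ds[integer(0)]), "empty")
})
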