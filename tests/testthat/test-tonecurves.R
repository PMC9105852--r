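test_that("each curve type reproduces its frozen golden values", {
  cases <- list(
    list(curve = toneCurve(0), f = 137, g = 137),
    list(curve = toneCurve(1, t = 20), f = c(19, 20), g = c(0, 20)),
    list(curve = toneCurve(2, t = 20), f = 137, g = 127),       # 255*117/235 = 126.957
    list(curve = toneCurve(3, gamma = 1/2), f = 128, g = 64),   # 255*(128/255)^2 = 64.25
    list(curve = toneCurve(4), f = c(0, 255), g = c(255, 0)),
    list(curve = toneCurve(5, t = 160), f = c(159, 160), g = c(96, 0)),
    list(curve = toneCurve(6, t = 200), f = c(50, 100), g = c(191, 128)),
    list(curve = toneCurve(7, gamma = 1), f = 0:255, g = 255:0))
  for (cs in cases) {
    expect_identical(evaluateCurve(cs$curve, cs$f), as.integer(cs$g),
                     info = curveLabel(cs$curve))
  }
})

test_that("threshold comparisons are strict: f == t takes the otherwise branch", {
  expect_identical(evaluateCurve(toneCurve(1, t = 100), c(99, 100)), c(0L, 100L))
  expect_identical(evaluateCurve(toneCurve(2, t = 100), c(99, 100)), c(0L, 0L))
  expect_identical(evaluateCurve(toneCurve(5, t = 100), c(99, 100)), c(156L, 0L))
  expect_identical(evaluateCurve(toneCurve(6, t = 100), c(99, 100)), c(3L, 0L))
})

test_that("parameter validation names the type and the violated bound", {
  expect_error(toneCurve(2, t = 255), "type II.*0 <= t <= 254")
  expect_error(toneCurve(6, t = 0), "type VI.*1 <= t <= 255")
  expect_error(toneCurve(1, t = 256), "type I.*0 <= t <= 255")
  expect_error(toneCurve(3, gamma = 0), "type III.*gamma > 0")
  expect_error(toneCurve(7, gamma = -1), "type VII.*gamma > 0")
  expect_error(toneCurve(0, t = 10), "type 0 takes no threshold")
  expect_error(toneCurve(4, gamma = 2), "type IV takes no gamma")
  expect_error(toneCurve(9), "0..7")
  expect_error(toneCurve(1, t = 10, fmax = 100), "fmax")
})

test_that("out-of-range input grey levels are rejected", {
  expect_error(evaluateCurve(toneCurve(0), 256), "\\[0, 255\\]")
  expect_error(evaluateCurve(toneCurve(0), -1), "\\[0, 255\\]")
  expect_silent(evaluateCurve(toneCurve(0, fmax = 4095), 4095))
})

test_that("roman-numeral and integer type labels are interchangeable", {
  expect_identical(toneCurve("VI", t = 200), toneCurve(6, t = 200))
  expect_identical(toneCurve("6", t = 200), toneCurve(6, t = 200))
  expect_identical(curveLabel(toneCurve("II", t = 20)), "II(t=20)")
  expect_identical(curveParam(toneCurve(3, gamma = 1/3)), 1/3)
  expect_true(is.na(curveParam(toneCurve(4))))
})

test_that("lookup tables match direct evaluation entry-by-entry", {
  for (fmax in c(255L, 4095L)) {
    lut <- buildLUT(toneCurve(0, fmax = fmax))
    expect_identical(lutEntries(lut), 0:fmax)
    expect_identical(lutEntries(buildLUT(toneCurve(4, fmax = fmax))), fmax:0)
    expect_length(lutEntries(buildLUT(toneCurve(3, gamma = 5, fmax = fmax))),
                  fmax + 1L)
  }
  # spot-check a nonlinear type against the independent oracle
  ent <- lutEntries(buildLUT(toneCurve(6, t = 200)))
  expect_identical(ent, as.integer(oracleToneCurve(6, 0:255, t = 200)))
})

test_that("applying a curve preserves shape, leaves the input unmodified, and uses the LUT", {
  set.seed(1)
  px <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32)
  img <- greyImage(px)
  curve <- toneCurve(6, t = 200)
  out <- applyCurve(img, curve)
  expect_identical(dim(out), dim(img))
  expect_identical(pixels(img), px)   # input untouched
  # brute-force per-pixel formula evaluation, no LUT
  direct <- matrix(oracleToneCurve(6, as.numeric(px), t = 200), 32, 32)
  expect_identical(pixels(out), matrix(as.integer(direct), 32, 32))
})

test_that("boundary pixels at the threshold are not blacked out by type I", {
  img <- greyImage(matrix(20L, 8, 8))
  expect_identical(pixels(applyCurve(img, toneCurve(1, t = 20))), pixels(img))
})

test_that("type IV applied twice is the identity on any image", {
  set.seed(2)
  img <- greyImage(matrix(sample(0:255, 64, replace = TRUE), 8, 8))
  expect_identical(pixels(applyCurve(applyCurve(img, toneCurve(4)), toneCurve(4))),
                   pixels(img))
})

test_that("curve application refuses an fmax mismatch", {
  img <- greyImage(matrix(0L, 4, 4), fmax = 4095L)
  expect_error(applyCurve(img, toneCurve(0, fmax = 255L)), "fmax")
})

test_that("monotonicity of the LUT families holds on a parameter grid", {
  for (t in seq(20, 240, by = 20)) {
    expect_true(all(diff(lutEntries(buildLUT(toneCurve(1, t = t)))) >= 0))
    if (t <= 254) {
      expect_true(all(diff(lutEntries(buildLUT(toneCurve(2, t = t)))) >= 0))
    }
    lut6 <- lutEntries(buildLUT(toneCurve(6, t = t)))
    expect_true(all(diff(lut6[1:t]) <= 0))            # non-increasing below t
    expect_true(all(lut6[(t + 1):256] == 0L))         # zero at and beyond t
  }
  for (g in c(1/10, 1/5, 1/3, 1/2, 1, 2, 3, 5)) {
    expect_true(all(diff(lutEntries(buildLUT(toneCurve(3, gamma = g)))) >= 0))
  }
  expect_true(all(diff(lutEntries(buildLUT(toneCurve(4)))) == -1L))
})
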