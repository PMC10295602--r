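test_that("grayscale conversion follows the luminance weights", {
  g <- matrix(runif(16), 4, 4)
  expect_identical(toGrayscale(g), g)                 # idempotent on 2-d
  rgb1 <- array(1, c(1, 1, 3))
  expect_equal(as.numeric(toGrayscale(rgb1)), 1)      # weights sum to 1
  px <- array(c(0.2, 0.6, 0.4), c(1, 1, 3))
  expect_equal(as.numeric(toGrayscale(px)), 0.4576)   # hand-computed
  expect_equal(as.numeric(toGrayscale(px, "green_channel")), 0.6)
  expect_error(toGrayscale(array(1, c(2, 2, 4))), "channel")
})

test_that("bilateral filter matches the double-loop oracle", {
  set.seed(21)
  img <- matrix(runif(16 * 16), 16, 16)
  cfg <- preprocessConfig(bilateralDiameter = 5L, bilateralSigmaColor = 0.15,
                          bilateralSigmaSpace = 2)
  got <- bilateralFilter(img, cfg)
  ref <- bilateral_oracle(img, 5, 0.15, 2)
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("bilateral filter is a convex window average", {
  cst <- matrix(0.42, 12, 12)
  expect_equal(bilateralFilter(cst), cst)             # fixed point
  imp <- matrix(0, 11, 11); imp[6, 6] <- 1
  out <- bilateralFilter(imp, preprocessConfig(bilateralSigmaColor = 0.5))
  expect_lt(max(out), 1)                              # peak attenuated
  # output bounded by local window extrema
  set.seed(8)
  img <- matrix(runif(10 * 10), 10, 10)
  cfg <- preprocessConfig(bilateralDiameter = 5L)
  out <- bilateralFilter(img, cfg)
  r <- 2
  for (i in seq_len(10)) for (j in seq_len(10)) {
    win <- img[max(1, i - r):min(10, i + r), max(1, j - r):min(10, j + r)]
    expect_gte(out[i, j], min(win) - 1e-12)
    expect_lte(out[i, j], max(win) + 1e-12)
  }
})

test_that("bilateral filter preserves a step edge better than Gaussian blur", {
  step <- matrix(rep(c(0, 1), each = 8), 16, 16, byrow = TRUE)
  cfg <- preprocessConfig(bilateralDiameter = 9L, bilateralSigmaColor = 0.1,
                          bilateralSigmaSpace = 3)
  bil <- bilateralFilter(step, cfg)
  edge_bil <- abs(mean(bil[, 9]) - mean(bil[, 8]))
  # plain Gaussian blur of equal spatial sigma = bilateral with a range
  # sigma so wide the range kernel is flat
  cfg_g <- preprocessConfig(bilateralDiameter = 9L, bilateralSigmaColor = 1e6,
                            bilateralSigmaSpace = 3)
  gau <- bilateralFilter(step, cfg_g)
  edge_gau <- abs(mean(gau[, 9]) - mean(gau[, 8]))
  expect_gte(edge_bil, 0.8)
  expect_lt(edge_gau, edge_bil)
})

test_that("CLAHE raises contrast on a low-contrast vessel image", {
  cfg <- vesselSimConfig(imageSize = c(64L, 64L), nTrees = 2L,
                         branchDepth = 3L, rootWidthPx = 2,
                         vesselContrast = 0.1, noiseSigma = 0.01, seed = 9L)
  img <- generateSample(cfg, 0)@image
  out <- claheEnhance(img)
  expect_gt(sd(out), sd(img))
  expect_gte(min(out), 0)
  expect_lte(max(out), 1)
})

test_that("CLAHE fixes constants and respects [0,1] on random images", {
  cst <- matrix(0.3, 32, 32)
  expect_equal(claheEnhance(cst), cst)
  set.seed(5)
  for (i in 1:10) {
    img <- matrix(runif(32 * 32), 32, 32)
    out <- claheEnhance(img)
    expect_gte(min(out), 0)
    expect_lte(max(out), 1)
  }
  expect_error(claheEnhance(matrix(0.5, 4, 4),
                            preprocessConfig(claheTileGrid = c(8L, 8L))),
               "tile grid")
})

test_that("gamma correction is the elementwise power law", {
  img <- matrix(runif(25), 5, 5)
  expect_identical(gammaCorrect(img, 1), img)
  expect_equal(gammaCorrect(matrix(0.25), 2)[1], 0.0625)
  expect_true(all(gammaCorrect(img, 0.5) >= img))  # concave on [0,1]
  # strictly increasing transform keeps monotone inputs monotone
  mono <- matrix(seq(0, 1, length.out = 16), 4, 4)
  expect_true(all(diff(as.vector(gammaCorrect(mono, 1.7))) >= 0))
  expect_error(gammaCorrect(img, 0), "gamma")
})

test_that("the pipeline composes the stages in order and is deterministic", {
  rgb <- array(runif(32 * 32 * 3), c(32, 32, 3))
  cfg_off <- preprocessConfig(enabled = FALSE)
  expect_equal(preprocessImage(rgb, cfg_off), toGrayscale(rgb))
  cst <- array(0.5, c(32, 32, 3))
  out <- preprocessImage(cst)
  expect_equal(max(out) - min(out), 0)             # constants stay constant
  a <- preprocessImage(rgb)
  b <- preprocessImage(rgb)
  expect_identical(a, b)
  expect_gte(min(a), 0); expect_lte(max(a), 1)
})

test_that("preprocessDataset rewrites a manifest with processed images", {
  out <- withr::local_tempdir()
  man <- generateDataset(tiny_sim_config(seed = 6L), 2, out)
  pre <- preprocessDataset(man, preprocessConfig(), file.path(out, "pre"))
  expect_equal(nrow(pre@entries), 2L)
  s0 <- loadSample(man, 1)
  s1 <- loadSample(pre, 1)
  expect_equal(dim(s1@image), dim(s0@image))
  expect_identical(s1@mask, s0@mask)               # masks pass through
})
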