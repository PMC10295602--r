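test_that("degenerate ranges always draw the identity transform", {
  cfg <- augmentConfig(10L, rotationRangeDeg = 0, shiftFraction = 0,
                       allowHflip = FALSE, allowVflip = FALSE)
  set.seed(1)
  for (i in 1:5) {
    p <- randomTransformParams(cfg, 64)
    expect_equal(p$angle, 0)
    expect_equal(p$dx, 0); expect_equal(p$dy, 0)
    expect_false(p$hflip); expect_false(p$vflip)
  }
})

test_that("parameter draws are seeded and match the folded-uniform mean", {
  cfg <- augmentConfig(10L, rotationRangeDeg = 30)
  set.seed(42); p1 <- replicate(20, randomTransformParams(cfg, 64)$angle)
  set.seed(42); p2 <- replicate(20, randomTransformParams(cfg, 64)$angle)
  expect_identical(p1, p2)
  # |U(-30, 30)| has mean 15 and variance 75; 4-sd band for n = 10000
  set.seed(7)
  draws <- abs(replicate(10000, randomTransformParams(cfg, 64)$angle))
  expect_lt(abs(mean(draws) - 15), 4 * sqrt(75 / 10000))
})

test_that("identity parameters leave a sample unchanged", {
  s <- generateSample(tiny_sim_config(seed = 3L), 0)
  id <- list(angle = 0, dx = 0, dy = 0, hflip = FALSE, vflip = FALSE)
  t <- applyTransform(s, id)
  expect_equal(t@image, s@image)
  expect_identical(t@mask, s@mask)
})

test_that("180-degree rotation is an exact involution on masks", {
  s <- generateSample(tiny_sim_config(seed = 4L), 0)
  p <- list(angle = 180, dx = 0, dy = 0, hflip = FALSE, vflip = FALSE)
  once <- applyTransform(s, p)
  twice <- applyTransform(once, p)
  expect_identical(twice@mask, s@mask)
  expect_equal(twice@image, s@image, tolerance = 1e-12)
  # 180 degrees maps row r to H-1-r and column c to W-1-c exactly
  expect_identical(once@mask, s@mask[nrow(s@mask):1, ncol(s@mask):1])
})

test_that("horizontal flip matches the index-reversal oracle", {
  set.seed(10)
  m <- matrix(as.numeric(rbinom(32 * 32, 1, 0.4)), 32, 32)
  s <- imageSample(m * 0.5, m)
  p <- list(angle = 0, dx = 0, dy = 0, hflip = TRUE, vflip = FALSE)
  t <- applyTransform(s, p)
  # column c (0-based) maps to W-1-c
  expect_identical(t@mask, m[, 32:1])
  expect_equal(sum(t@mask), sum(m))               # flips conserve count
})

test_that("image and mask stay aligned under random transforms", {
  set.seed(77)
  cfg <- augmentConfig(10L)
  s <- generateSample(tiny_sim_config(seed = 8L, size = 96L), 0)
  painted <- imageSample(s@mask * 1.0, s@mask, sampleId = "painted")
  for (i in 1:5) {
    p <- randomTransformParams(cfg, 96)
    t <- applyTransform(painted, p)
    extracted <- (t@image > 0.5) * 1
    agree <- mean(extracted == t@mask)
    expect_gte(agree, 0.99)
  }
})

test_that("rotation approximately conserves interior vessel area", {
  # mask kept away from borders so nothing rotates out of frame
  m <- matrix(0, 64, 64)
  m[25:40, 28:36] <- 1
  s <- imageSample(m * 0.5, m)
  for (ang in c(15, 45, 90, 137)) {
    p <- list(angle = ang, dx = 0, dy = 0, hflip = FALSE, vflip = FALSE)
    t <- applyTransform(s, p)
    expect_lt(abs(sum(t@mask) - sum(m)) / sum(m), 0.05)
  }
})

test_that("ROI masks transform with the same parameters and stay binary", {
  m <- matrix(0, 48, 48); m[20:28, 20:28] <- 1
  roi <- matrix(0, 48, 48); roi[10:38, 10:38] <- 1
  s <- imageSample(m * 0.3, m, roi = roi)
  p <- list(angle = 30, dx = 2, dy = -3, hflip = TRUE, vflip = FALSE)
  t <- applyTransform(s, p)
  expect_true(all(t@roi %in% c(0, 1)))
  expect_true(all(t@mask %in% c(0, 1)))
  expect_true(all(t@mask <= t@roi))                # mask stays inside ROI
})

test_that("augmentToCount returns the target count with originals first", {
  sim <- tiny_sim_config(seed = 12L, size = 48L)
  sources <- lapply(0:19, function(i) generateSample(sim, i))
  cfg <- augmentConfig(2000L, seed = 5L)
  aug <- augmentToCount(sources, cfg)
  expect_length(aug, 2000L)
  for (i in 1:20) expect_identical(aug[[i]]@mask, sources[[i]]@mask)
  expect_match(aug[[21]]@sampleId, "_aug1$")
  # target = n returns the originals untouched
  same <- augmentToCount(sources, augmentConfig(20L))
  expect_identical(lapply(same, slot, "image"), lapply(sources, slot, "image"))
  # seeded reproducibility
  aug2 <- augmentToCount(sources, cfg)
  expect_identical(aug[[1500]]@image, aug2[[1500]]@image)
  expect_error(augmentToCount(sources, augmentConfig(10L)), "below source")
})
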