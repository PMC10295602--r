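test_that("encoder level shapes follow the channel-doubling arithmetic", {
  m <- buildModel(modelConfig(depth = 4L, baseChannels = 32L), seed = 1)
  tape <- vesselseg:::new_tape(training = FALSE)
  x <- vesselseg:::tp_node(tape, array(runif(64 * 64), c(64, 64, 1, 1)))
  maps <- vesselseg:::.encoder_fw(tape, m, x)
  dims <- lapply(maps, function(nd) dim(nd$value))
  expect_equal(dims[[1]], c(64L, 64L, 32L, 1L))
  expect_equal(dims[[2]], c(32L, 32L, 64L, 1L))
  expect_equal(dims[[3]], c(16L, 16L, 128L, 1L))
  expect_equal(dims[[4]], c(8L, 8L, 256L, 1L))
})

test_that("a zeroed residual block reduces to a rectified shortcut", {
  m <- buildModel(modelConfig(depth = 2L, baseChannels = 1L), seed = 2)
  for (nm in c("enc1.res.conv1.w", "enc1.res.conv1.b",
               "enc1.res.conv2.w", "enc1.res.conv2.b"))
    m@env$params[[nm]][] <- 0
  tape <- vesselseg:::new_tape(training = FALSE)
  xv <- array(rnorm(8 * 8 * 2), c(8, 8, 1, 2))
  x <- vesselseg:::tp_node(tape, xv)
  out <- vesselseg:::.res_block_fw(tape, m, x, "enc1.res")
  expect_equal(out$value, pmax(xv, 0), tolerance = 1e-12)
})

test_that("the inception bottleneck preserves spatial size and projects channels", {
  cfg <- modelConfig(depth = 3L, baseChannels = 8L, fusionChannels = 16L)
  m <- buildModel(cfg, seed = 3)
  tape <- vesselseg:::new_tape(training = FALSE)
  x <- vesselseg:::tp_node(tape, array(runif(8 * 8 * 32), c(8, 8, 32, 1)))
  out <- vesselseg:::.inception_fw(tape, m, x)
  expect_equal(dim(out$value), c(8L, 8L, cfg@bottleneckChannels, 1L))
  # three parallel branch convolutions with kernels 1, 3, 5 feed the fusion
  for (k in c(1, 3, 5)) {
    w <- m@env$params[[sprintf("bottleneck.branch%d.conv.w", k)]]
    expect_equal(dim(w), c(k, k, 32L, cfg@bottleneckChannels))
  }
  pw <- m@env$params[["bottleneck.proj.conv.w"]]
  expect_equal(dim(pw)[3], 3L * cfg@bottleneckChannels)  # concat conservation
})

test_that("every decoder stage fuses one source per network level", {
  for (cfg in list(modelConfig(depth = 3L, baseChannels = 8L, fusionChannels = 8L),
                   modelConfig(depth = 4L, baseChannels = 8L, fusionChannels = 8L))) {
    m <- buildModel(cfg, seed = 4)
    side <- 2^(cfg@depth - 1) * 4
    invisible(modelForward(m, array(runif(side * side), c(side, side, 1, 1))))
    expect_equal(fusionSourceCounts(m), rep(cfg@depth, cfg@depth - 1))
  }
})

test_that("the shallowest stage upsamples every deeper map by 2, 4 and 8", {
  # depth 4, target level 1: sources are encoder level 1 (native) plus the
  # maps at levels 2, 3, 4, which live at 1/2, 1/4 and 1/8 resolution
  cfg <- modelConfig(depth = 4L, baseChannels = 8L, fusionChannels = 8L)
  factors <- vapply(1:4, function(l) 2^abs(l - 1), numeric(1))
  expect_equal(sort(factors[factors > 1]), c(2, 4, 8))
  # and those source convolutions exist with the right input widths
  m <- buildModel(cfg, seed = 5)
  ec <- cfg@baseChannels * 2^(0:3)
  for (l in 1:4) {
    w <- m@env$params[[sprintf("dec1.src%d.conv.w", l)]]
    cin_expect <- if (l == 4) cfg@bottleneckChannels else ec[l]
    expect_equal(dim(w)[3], as.integer(cin_expect))
  }
})

test_that("parameter counts match the closed-form oracle", {
  configs <- list(
    modelConfig(depth = 3L, baseChannels = 8L),
    modelConfig(depth = 4L, baseChannels = 16L),
    modelConfig(depth = 4L, baseChannels = 32L),
    modelConfig(depth = 3L, baseChannels = 8L, fusionChannels = 16L,
                inChannels = 3L))
  for (cfg in configs) {
    m <- buildModel(cfg, seed = 1)
    expect_equal(parameterCount(m), param_count_oracle(cfg))
  }
  # two builds of the same config report identical counts
  expect_equal(parameterCount(buildModel(configs[[1]], seed = 1)),
               parameterCount(buildModel(configs[[1]], seed = 99)))
})

test_that("doubling base channels roughly quadruples the parameter count", {
  c1 <- param_count_oracle(modelConfig(depth = 4L, baseChannels = 16L))
  c2 <- param_count_oracle(modelConfig(depth = 4L, baseChannels = 32L))
  expect_gt(c2 / c1, 3)
  expect_lt(c2 / c1, 4.5)
})

test_that("forward output matches input size with values in (0,1)", {
  m <- buildModel(tiny_model_config(), seed = 6)
  x <- array(runif(64 * 64 * 2), c(64, 64, 1, 2))
  p <- modelForward(m, x)
  expect_equal(dim(p), c(64L, 64L, 1L, 2L))
  expect_gt(min(p), 0); expect_lt(max(p), 1)
  # identical batch rows give identical outputs in evaluation mode
  x2 <- array(rep(x[, , , 1], 2), c(64, 64, 1, 2))
  p2 <- modelForward(m, x2)
  expect_identical(p2[, , 1, 1], p2[, , 1, 2])
  expect_error(modelForward(m, array(runif(50 * 50), c(50, 50, 1, 1))),
               "divisible")
})

test_that("initialization is fully determined by the seed", {
  m1 <- buildModel(tiny_model_config(), seed = 7)
  m2 <- buildModel(tiny_model_config(), seed = 7)
  expect_identical(m1@env$params, m2@env$params)
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  expect_identical(modelForward(m1, x), modelForward(m2, x))
  m3 <- buildModel(tiny_model_config(), seed = 8)
  expect_false(identical(m1@env$params, m3@env$params))
})

test_that("model gradients agree with central finite differences", {
  cfg <- modelConfig(depth = 2L, baseChannels = 2L, fusionChannels = 2L)
  m <- buildModel(cfg, seed = 9)
  set.seed(9)
  xx <- array(runif(8 * 8 * 2), c(8, 8, 1, 2))
  tt <- array(rbinom(8 * 8 * 2, 1, 0.3), c(8, 8, 1, 2))
  loss_value <- function() {
    tape <- vesselseg:::new_tape(TRUE)
    fw <- vesselseg:::.model_fw(tape, m, xx)
    vesselseg:::op_bce_logits(tape, fw$logits, tt)$value
  }
  tape <- vesselseg:::new_tape(TRUE)
  fw <- vesselseg:::.model_fw(tape, m, xx)
  ln <- vesselseg:::op_bce_logits(tape, fw$logits, tt)
  grads <- new.env(parent = emptyenv())
  vesselseg:::tape_backward(tape, ln, grads)
  eps <- 1e-5
  for (nm in sample(names(m@env$params), 8)) {
    arr <- m@env$params[[nm]]
    i <- sample(length(arr), 1)
    m@env$params[[nm]][i] <- arr[i] + eps; l1 <- loss_value()
    m@env$params[[nm]][i] <- arr[i] - eps; l2 <- loss_value()
    m@env$params[[nm]][i] <- arr[i]
    g_fd <- (l1 - l2) / (2 * eps)
    g_an <- grads[[nm]][i]
    expect_lt(abs(g_fd - g_an), 1e-6 + 1e-4 * abs(g_fd))
  }
})

test_that("checkpoints round-trip weights and running statistics", {
  d <- withr::local_tempdir()
  m <- buildModel(tiny_model_config(), seed = 10)
  p <- file.path(d, "ck.rds")
  saveCheckpoint(m, p)
  m2 <- loadCheckpoint(p)
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  expect_identical(modelForward(m, x), modelForward(m2, x))
  expect_true(file.exists(file.path(d, "ck_config.json")))
})

test_that("arbitrary image sizes are padded, predicted and cropped back", {
  m <- buildModel(tiny_model_config(), seed = 11)
  img <- matrix(runif(50 * 37), 50, 37)
  out <- predictProbability(m, img)
  expect_equal(dim(out$prob), c(50L, 37L))
  expect_true(all(is.finite(out$prob)))
  expect_equal(unname(out$pad), c((4 - 50 %% 4) %% 4, (4 - 37 %% 4) %% 4))
})
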