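#' @include AllClasses.R tape.R
NULL

# ---- parameter construction ------------------------------------------------

.he_init <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

.add_conv <- function(env, name, k, cin, cout) {
  env$params[[paste0(name, ".w")]] <- .he_init(k, cin, cout)
  env$params[[paste0(name, ".b")]] <- numeric(cout)
  invisible(NULL)
}

.add_bn <- function(env, name, c) {
  env$params[[paste0(name, ".gamma")]] <- rep(1, c)
  env$params[[paste0(name, ".beta")]] <- numeric(c)
  env$state[[paste0(name, ".running_mean")]] <- numeric(c)
  env$state[[paste0(name, ".running_var")]] <- rep(1, c)
  invisible(NULL)
}

.add_res_block <- function(env, prefix, cin, cout) {
  .add_conv(env, paste0(prefix, ".conv1"), 3, cin, cout)
  .add_bn(env, paste0(prefix, ".bn1"), cout)
  .add_conv(env, paste0(prefix, ".conv2"), 3, cout, cout)
  .add_bn(env, paste0(prefix, ".bn2"), cout)
  if (cin != cout) .add_conv(env, paste0(prefix, ".proj"), 1, cin, cout)
  invisible(NULL)
}

.enc_channels <- function(config) {
  config@baseChannels * 2^(seq_len(config@depth) - 1)
}

#' Build an untrained segmentation network
#'
#' Constructs the improved U-Net: a residual-block encoder of `depth` levels
#' with channel doubling, an inception bottleneck (parallel 1x1 / 3x3 / 5x5
#' convolutions fused by a 1x1 projection), and a decoder in which every
#' stage aggregates all encoder scales plus the decoder chain below it
#' (full-scale skip connections), each source resized to the stage's
#' resolution and reduced to a common fusion width before a residual block
#' extracts the fused features. Weights use fan-in-scaled ("He") Gaussian
#' initialization drawn from R's RNG, so results are reproducible for a
#' given `seed`.
#'
#' @param config a [ModelConfig-class] object.
#' @param seed integer RNG seed used for weight initialization.
#' @return a [VesselSegModel-class] object.
#' @examples
#' m <- buildModel(modelConfig(depth = 3, baseChannels = 8), seed = 1)
#' parameterCount(m)
#' @export
buildModel <- function(config, seed = 1L) {
  stopifnot(is(config, "ModelConfig"))
  validObject(config)
  env <- new.env(parent = emptyenv())
  env$params <- list()
  env$state <- list()
  env$fusion_sources <- integer(0)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(as.integer(seed))

  L <- config@depth
  ec <- .enc_channels(config)
  bc <- config@bottleneckChannels
  fc <- config@fusionChannels

  cin <- config@inChannels
  for (i in seq_len(L)) {
    .add_res_block(env, sprintf("enc%d.res", i), cin, ec[i])
    cin <- ec[i]
  }
  for (k in c(1, 3, 5)) {
    .add_conv(env, sprintf("bottleneck.branch%d.conv", k), k, ec[L], bc)
    .add_bn(env, sprintf("bottleneck.branch%d.bn", k), bc)
  }
  .add_conv(env, "bottleneck.proj.conv", 1, 3 * bc, bc)
  .add_bn(env, "bottleneck.proj.bn", bc)

  for (t in seq.int(L - 1, 1)) {
    for (l in seq_len(L)) {
      sc <- if (l <= t) ec[l] else if (l == L) bc else ec[l]
      .add_conv(env, sprintf("dec%d.src%d.conv", t, l), 3, sc, fc)
      .add_bn(env, sprintf("dec%d.src%d.bn", t, l), fc)
    }
    .add_res_block(env, sprintf("dec%d.res", t), L * fc, ec[t])
  }
  .add_conv(env, "head.conv", 1, ec[1], 1)

  new("VesselSegModel", config = config, env = env)
}

#' Number of trainable parameters
#'
#' Counts every element of every trainable array (convolution weights and
#' biases, batch-norm scale and shift). Batch-norm running statistics are
#' buffers, not parameters, and are excluded.
#'
#' @param model a [VesselSegModel-class] object.
#' @return integer parameter count.
#' @export
parameterCount <- function(model) {
  sum(vapply(model@env$params, length, numeric(1)))
}

# ---- forward pass ----------------------------------------------------------

.p <- function(tape, model, name) {
  op_leaf(tape, model@env$params[[name]], param = name)
}

.conv_bn_relu <- function(tape, model, x, prefix) {
  h <- op_conv2d(tape, x, .p(tape, model, paste0(prefix, ".conv.w")),
                 .p(tape, model, paste0(prefix, ".conv.b")))
  h <- op_batchnorm(tape, h, .p(tape, model, paste0(prefix, ".bn.gamma")),
                    .p(tape, model, paste0(prefix, ".bn.beta")),
                    model@env, paste0(prefix, ".bn"))
  op_relu(tape, h)
}

# conv-BN-ReLU, conv-BN, add shortcut (identity or 1x1 projection),
# final ReLU after the addition.
.res_block_fw <- function(tape, model, x, prefix) {
  pn <- function(s) paste0(prefix, ".", s)
  h <- op_conv2d(tape, x, .p(tape, model, pn("conv1.w")),
                 .p(tape, model, pn("conv1.b")))
  h <- op_batchnorm(tape, h, .p(tape, model, pn("bn1.gamma")),
                    .p(tape, model, pn("bn1.beta")), model@env, pn("bn1"))
  h <- op_relu(tape, h)
  h <- op_conv2d(tape, h, .p(tape, model, pn("conv2.w")),
                 .p(tape, model, pn("conv2.b")))
  h <- op_batchnorm(tape, h, .p(tape, model, pn("bn2.gamma")),
                    .p(tape, model, pn("bn2.beta")), model@env, pn("bn2"))
  s <- if (!is.null(model@env$params[[pn("proj.w")]])) {
    op_conv2d(tape, x, .p(tape, model, pn("proj.w")),
              .p(tape, model, pn("proj.b")))
  } else {
    x
  }
  op_relu(tape, op_add(tape, h, s))
}

.encoder_fw <- function(tape, model, x) {
  L <- model@config@depth
  maps <- vector("list", L)
  h <- x
  for (i in seq_len(L)) {
    if (i > 1) h <- op_maxpool(tape, h, 2)
    h <- .res_block_fw(tape, model, h, sprintf("enc%d.res", i))
    maps[[i]] <- h
  }
  maps
}

.inception_fw <- function(tape, model, x) {
  branches <- lapply(c(1, 3, 5), function(k) {
    .conv_bn_relu(tape, model, x, sprintf("bottleneck.branch%d", k))
  })
  h <- op_concat_ch(tape, branches)
  .conv_bn_relu(tape, model, h, "bottleneck.proj")
}

# Full-scale fusion at decoder stage `t`: encoder levels 1..t are max-pooled
# down by 2^(t-l); the decoder chain below (stages t+1..L-1 and the
# bottleneck at level L) is bilinearly upsampled by 2^(l-t). Each source is
# reduced to the common fusion width by conv-BN-ReLU, all are concatenated,
# and a residual block maps the stack to the stage's channel count.
.fusion_fw <- function(tape, model, enc_maps, deeper, t) {
  L <- model@config@depth
  srcs <- vector("list", L)
  for (l in seq_len(L)) {
    src <- if (l <= t) enc_maps[[l]] else deeper[[l]]
    f <- 2^abs(l - t)
    if (l < t) src <- op_maxpool(tape, src, f)
    if (l > t) src <- op_upsample(tape, src, f)
    srcs[[l]] <- .conv_bn_relu(tape, model, src, sprintf("dec%d.src%d", t, l))
  }
  model@env$fusion_sources <- c(model@env$fusion_sources, length(srcs))
  h <- op_concat_ch(tape, srcs)
  .res_block_fw(tape, model, h, sprintf("dec%d.res", t))
}

# Full forward pass on a (H, W, Cin, N) batch; returns the logits node and
# the sigmoid probability node on the given tape.
.model_fw <- function(tape, model, x) {
  cfg <- model@config
  d <- dim(x)
  if (length(d) != 4 || d[3] != cfg@inChannels)
    stop("input must be (H, W, ", cfg@inChannels, ", N)")
  div <- 2^(cfg@depth - 1)
  if (d[1] %% div != 0 || d[2] %% div != 0)
    stop("spatial dims must be divisible by ", div,
         " (got ", d[1], "x", d[2], "); pad the input first")
  L <- cfg@depth
  model@env$fusion_sources <- integer(0)
  xin <- tp_node(tape, x)
  enc <- .encoder_fw(tape, model, xin)
  deeper <- vector("list", L)
  deeper[[L]] <- .inception_fw(tape, model, enc[[L]])
  for (t in seq.int(L - 1, 1)) {
    deeper[[t]] <- .fusion_fw(tape, model, enc, deeper, t)
  }
  logits <- op_conv2d(tape, deeper[[1]], .p(tape, model, "head.conv.w"),
                      .p(tape, model, "head.conv.b"))
  list(logits = logits, prob = op_sigmoid(tape, logits))
}

#' Forward a batch through the network
#'
#' Runs the network in evaluation mode (batch norm uses running statistics)
#' and returns the sigmoid probability maps.
#'
#' @param model a [VesselSegModel-class] object.
#' @param x numeric array `(H, W, inChannels, N)`, or a 2-d `(H, W)` matrix
#'   for a single grayscale image. Spatial dimensions must be divisible by
#'   `2^(depth-1)`; see [predictProbability()] for automatic padding.
#' @return array of probabilities in (0, 1) with the same spatial shape.
#' @export
modelForward <- function(model, x) {
  if (length(dim(x)) == 2 || is.null(dim(x))) {
    x <- array(x, c(nrow(x), ncol(x), 1, 1))
    drop2d <- TRUE
  } else drop2d <- FALSE
  tape <- new_tape(training = FALSE)
  out <- .model_fw(tape, model, x)$prob$value
  if (drop2d) out <- out[, , 1, 1]
  out
}

#' Number of fusion sources consumed by each decoder stage
#'
#' After a forward pass, reports how many resized feature maps each decoder
#' stage concatenated (deepest stage first). A full-scale decoder consumes
#' one source per network level at every stage.
#'
#' @param model a [VesselSegModel-class] object that has run a forward pass.
#' @return integer vector, one entry per decoder stage.
#' @export
fusionSourceCounts <- function(model) {
  model@env$fusion_sources
}

#' Segment an image of arbitrary size
#'
#' Pads the image by reflection to the next multiple of `2^(depth-1)`, runs
#' the network, and crops the probability map back to the original size, so
#' inputs such as 565x584 (DRIVE) or 304x304 (ROSE) work with any depth.
#'
#' @param model a [VesselSegModel-class] object.
#' @param image 2-d matrix on `[0,1]` (grayscale) or `(H, W, 3)` RGB array
#'   when the model was built with `inChannels = 3`.
#' @return list with `prob` (2-d probability matrix, original size) and
#'   `pad` (the `(bottom, right)` padding that was applied).
#' @export
predictProbability <- function(model, image) {
  cfg <- model@config
  if (cfg@inChannels == 1 && length(dim(image)) == 3)
    stop("model expects grayscale input; preprocess or convert first")
  d <- if (length(dim(image)) >= 2) dim(image) else stop("image must be 2-d")
  div <- 2^(cfg@depth - 1)
  padb <- (div - d[1] %% div) %% div
  padr <- (div - d[2] %% div) %% div
  img <- .pad_reflect(image, padb, padr)
  x <- array(img, c(dim(img)[1], dim(img)[2], cfg@inChannels, 1))
  prob <- modelForward(model, x)
  prob <- array(prob, dim(img)[1:2])[seq_len(d[1]), seq_len(d[2])]
  list(prob = prob, pad = c(bottom = padb, right = padr))
}

# reflect-pad bottom/right edges of a 2-d or 3-d (H, W, C) array
.pad_reflect <- function(x, padb, padr) {
  if (padb == 0 && padr == 0) return(x)
  d <- dim(x)
  if (length(d) == 2) dim(x) <- c(d, 1)
  d3 <- dim(x)
  H <- d3[1]; W <- d3[2]
  rows <- c(seq_len(H), H - seq_len(padb))
  cols <- c(seq_len(W), W - seq_len(padr))
  out <- x[rows, cols, , drop = FALSE]
  if (length(d) == 2) dim(out) <- c(length(rows), length(cols))
  out
}

# ---- checkpoints -----------------------------------------------------------

#' Save model weights to a checkpoint
#'
#' Writes the weights and batch-norm running statistics as an RDS file with
#' a JSON sidecar describing the architecture configuration.
#'
#' @param model a [VesselSegModel-class] object.
#' @param path checkpoint file path (`.rds`).
#' @return `path`, invisibly.
#' @export
saveCheckpoint <- function(model, path) {
  cfg <- model@config
  cfg_list <- list(depth = cfg@depth, baseChannels = cfg@baseChannels,
                   bottleneckChannels = cfg@bottleneckChannels,
                   fusionChannels = cfg@fusionChannels,
                   inChannels = cfg@inChannels)
  saveRDS(list(config = cfg_list, params = model@env$params,
               state = model@env$state), path)
  side <- paste0(tools::file_path_sans_ext(path), "_config.json")
  jsonlite::write_json(cfg_list, side, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load model weights from a checkpoint
#'
#' @param path checkpoint file written by [saveCheckpoint()].
#' @return a [VesselSegModel-class] object.
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(modelConfig, ck$config)
  m <- buildModel(cfg, seed = 0L)
  m@env$params <- ck$params
  m@env$state <- ck$state
  m
}
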