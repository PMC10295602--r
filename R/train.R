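#' @include AllClasses.R model.R metrics.R io.R
NULL

#' Binarize a probability map
#'
#' Pixels with probability greater than or equal to `threshold` become 1.
#'
#' @param prob numeric array with values in `[0,1]`.
#' @param threshold cutoff in (0,1); at exactly the threshold a pixel is
#'   positive.
#' @return binary array of the same shape.
#' @export
binarize <- function(prob, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  (prob >= threshold) * 1
}

# resolve a manifest or a list of ImageSample into a list of samples
.as_samples <- function(x) {
  if (is(x, "DatasetManifest"))
    lapply(seq_len(nrow(x@entries)), function(i) loadSample(x, i))
  else if (is.list(x) && all(vapply(x, is, logical(1), "ImageSample")))
    x
  else stop("expected a DatasetManifest or a list of ImageSample objects")
}

# Stack samples into (H, W, 1, N) input/target plus a validity mask that is
# 0 on reflect-padded border pixels (so padding never enters the loss).
.batch_arrays <- function(samples, idx, div) {
  s1 <- samples[[idx[1]]]
  d <- dim(s1@mask)
  padb <- (div - d[1] %% div) %% div
  padr <- (div - d[2] %% div) %% div
  H <- d[1] + padb; W <- d[2] + padr
  N <- length(idx)
  x <- array(0, c(H, W, 1, N))
  t <- array(0, c(H, W, 1, N))
  w <- array(0, c(H, W, 1, N))
  for (j in seq_len(N)) {
    s <- samples[[idx[j]]]
    if (length(dim(s@image)) == 3)
      stop("sample '", s@sampleId, "' is RGB; run preprocessImage() first")
    if (!all(dim(s@mask) == d)) stop("all samples in a batch must share (H, W)")
    x[, , 1, j] <- .pad_reflect(s@image, padb, padr)
    t[seq_len(d[1]), seq_len(d[2]), 1, j] <- s@mask
    w[seq_len(d[1]), seq_len(d[2]), 1, j] <-
      if (is.null(s@roi)) 1 else s@roi
  }
  list(x = x, t = t, w = w)
}

.adam_step <- function(model, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  env <- model@env
  for (nm in names(env$params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is.null(env$adam_m[[nm]])) {
      env$adam_m[[nm]] <- g * 0
      env$adam_v[[nm]] <- g * 0
    }
    env$adam_m[[nm]] <- beta1 * env$adam_m[[nm]] + (1 - beta1) * g
    env$adam_v[[nm]] <- beta2 * env$adam_v[[nm]] + (1 - beta2) * g * g
    mhat <- env$adam_m[[nm]] / (1 - beta1^t)
    vhat <- env$adam_v[[nm]] / (1 - beta2^t)
    env$params[[nm]] <- env$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(NULL)
}

#' Train the segmentation network
#'
#' Runs `epochs * stepsPerEpoch` Adam steps over shuffled batches drawn from
#' the training samples (seeded, hence reproducible on a single-threaded
#' CPU). The loss is mean binary cross-entropy over valid pixels —
#' optionally plus a soft Dice term (`loss = "bce_plus_dice"`) for class
#' imbalance. Images whose sides are not divisible by `2^(depth-1)` are
#' reflect-padded; padded pixels are excluded from the loss through a
#' validity mask. Per-epoch mean loss and pixel accuracy are logged, and
#' the parameters of the best-loss epoch are restored at the end.
#'
#' @param model a [VesselSegModel-class] object (modified in place).
#' @param data a [DatasetManifest-class] or list of [ImageSample-class]
#'   objects; images must be grayscale (preprocess first).
#' @param config a [TrainConfig-class] object.
#' @param verbose print a line per epoch.
#' @return list with `model` and `history` (data.frame: epoch, loss,
#'   accuracy, seconds).
#' @export
trainModel <- function(model, data, config = trainConfig(), verbose = FALSE) {
  validObject(config)
  samples <- .as_samples(data)
  if (length(samples) == 0) stop("no training samples")
  div <- 2^(model@config@depth - 1)
  env <- model@env
  env$adam_m <- list(); env$adam_v <- list()

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config@seed)

  n <- length(samples)
  perm <- sample.int(n)
  pos <- 1L
  next_batch <- function() {
    idx <- integer(0)
    while (length(idx) < config@batchSize) {
      take <- min(config@batchSize - length(idx), n - pos + 1L)
      idx <- c(idx, perm[seq.int(pos, pos + take - 1L)])
      pos <<- pos + take
      if (pos > n) { perm <<- sample.int(n); pos <<- 1L }
    }
    idx
  }

  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0), seconds = numeric(0))
  best <- list(loss = Inf, params = NULL, state = NULL)
  step_t <- 0L
  for (ep in seq_len(config@epochs)) {
    t0 <- proc.time()[["elapsed"]]
    ep_loss <- 0; ep_acc <- 0
    for (st in seq_len(config@stepsPerEpoch)) {
      b <- .batch_arrays(samples, next_batch(), div)
      tape <- new_tape(training = TRUE)
      fw <- .model_fw(tape, model, b$x)
      loss_nd <- op_bce_logits(tape, fw$logits, b$t, b$w)
      if (config@loss == "bce_plus_dice")
        loss_nd <- op_scale_add(tape, loss_nd,
                                op_dice_loss(tape, fw$prob, b$t), 1, 1)
      if (!is.finite(loss_nd$value))
        stop("non-finite loss at epoch ", ep, ", step ", st)
      grads <- new.env(parent = emptyenv())
      tape_backward(tape, loss_nd, grads)
      step_t <- step_t + 1L
      .adam_step(model, grads, config@learningRate, step_t)
      ep_loss <- ep_loss + loss_nd$value
      valid <- b$w == 1
      ep_acc <- ep_acc +
        mean((fw$prob$value[valid] >= config@threshold) == (b$t[valid] == 1))
    }
    ep_loss <- ep_loss / config@stepsPerEpoch
    ep_acc <- ep_acc / config@stepsPerEpoch
    secs <- proc.time()[["elapsed"]] - t0
    history <- rbind(history, data.frame(epoch = ep, loss = ep_loss,
                                         accuracy = ep_acc, seconds = secs))
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f  acc %.4f  (%.1fs)",
                      ep, ep_loss, ep_acc, secs))
    if (ep_loss < best$loss)
      best <- list(loss = ep_loss, params = env$params, state = env$state)
  }
  env$params <- best$params
  env$state <- best$state
  list(model = model, history = history)
}

#' Evaluate a model on a dataset
#'
#' Forwards every image (reflect-padding to the required divisibility and
#' cropping the prediction back, so padding never changes the counts),
#' binarizes at `threshold`, tallies per-image confusion counts (inside the
#' ROI when one exists), and aggregates.
#'
#' @param model a [VesselSegModel-class] object.
#' @param data a [DatasetManifest-class] or list of [ImageSample-class].
#' @param threshold binarization cutoff in (0,1).
#' @param aggregation `"micro"` or `"macro"`.
#' @return list with `report` (aggregate [MetricsReport-class]), `table`
#'   (per-image data.frame of counts and metrics) and `counts` (list of
#'   per-image [ConfusionCounts-class]).
#' @export
evaluateModel <- function(model, data, threshold = 0.5,
                          aggregation = c("micro", "macro")) {
  aggregation <- match.arg(aggregation)
  samples <- .as_samples(data)
  counts <- vector("list", length(samples))
  rows <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    img <- if (length(dim(s@image)) == 3)
      toGrayscale(s@image, "luminance") else s@image
    prob <- predictProbability(model, img)$prob
    pred <- binarize(prob, threshold)
    cc <- confusionCounts(pred, s@mask, roi = s@roi)
    counts[[i]] <- cc
    rows[[i]] <- metricsAsRow(computeMetrics(cc), cc, s@sampleId)
  }
  list(report = aggregateMetrics(counts, aggregation),
       table = do.call(rbind, rows), counts = counts)
}
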