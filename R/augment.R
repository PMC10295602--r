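#' @include AllClasses.R synthetic.R
NULL

#' Draw one set of random transform parameters
#'
#' Draws from the current R RNG stream: rotation angle uniform on
#' `(-range, +range)` degrees, translations uniform on
#' `(-shiftFraction, +shiftFraction)` of the image side, and fair-coin
#' flips where allowed.
#'
#' @param config an [AugmentConfig-class] object.
#' @param side image side length in pixels (scales the translation draw).
#' @return list with `angle` (degrees), `dx`, `dy` (pixels), `hflip`,
#'   `vflip` (logical).
#' @export
randomTransformParams <- function(config, side) {
  list(
    angle = stats::runif(1, -config@rotationRangeDeg, config@rotationRangeDeg),
    dx = stats::runif(1, -config@shiftFraction, config@shiftFraction) * side,
    dy = stats::runif(1, -config@shiftFraction, config@shiftFraction) * side,
    hflip = if (config@allowHflip) stats::runif(1) < 0.5 else FALSE,
    vflip = if (config@allowVflip) stats::runif(1) < 0.5 else FALSE)
}

# Inverse-mapped affine resampling. Forward transform: rotate about the
# image centre by `angle`, translate by (dy, dx), then flip. `interp` is
# "bilinear" or "nearest"; out-of-frame fills with 0. 0-based (row, col)
# coordinates, centre at ((H-1)/2, (W-1)/2), so a 180-degree rotation maps
# row r to exactly H-1-r and is an exact involution.
.warp <- function(x, params, interp) {
  H <- nrow(x); W <- ncol(x)
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  gr <- matrix(seq_len(H) - 1, H, W)
  gc <- matrix(seq_len(W) - 1, H, W, byrow = TRUE)
  if (params$hflip) gc <- W - 1 - gc
  if (params$vflip) gr <- H - 1 - gr
  gr <- gr - params$dy
  gc <- gc - params$dx
  th <- -params$angle * pi / 180
  sr <- cy + cos(th) * (gr - cy) - sin(th) * (gc - cx)
  sc <- cx + sin(th) * (gr - cy) + cos(th) * (gc - cx)
  # snap coordinates within numeric noise of the frame onto it, so exact
  # angles (90/180/270, pure flips) never lose border pixels
  eps <- 1e-9
  sr <- pmin(pmax(sr, ifelse(sr >= -eps, 0, sr)), ifelse(sr <= H - 1 + eps, H - 1, sr))
  sc <- pmin(pmax(sc, ifelse(sc >= -eps, 0, sc)), ifelse(sc <= W - 1 + eps, W - 1, sc))
  out <- matrix(0, H, W)
  if (interp == "nearest") {
    ri <- round(sr); ci <- round(sc)
    ok <- ri >= 0 & ri <= H - 1 & ci >= 0 & ci <= W - 1
    out[ok] <- x[cbind(ri[ok] + 1, ci[ok] + 1)]
  } else {
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- as.vector(sr - r0); fc <- as.vector(sc - c0)
    ok <- sr >= 0 & sr <= H - 1 & sc >= 0 & sc <= W - 1
    r0k <- as.vector(pmin(pmax(r0, 0), H - 1))
    c0k <- as.vector(pmin(pmax(c0, 0), W - 1))
    r1k <- pmin(r0k + 1, H - 1); c1k <- pmin(c0k + 1, W - 1)
    v <- (1 - fr) * (1 - fc) * x[cbind(r0k + 1, c0k + 1)] +
         (1 - fr) * fc       * x[cbind(r0k + 1, c1k + 1)] +
         fr * (1 - fc)       * x[cbind(r1k + 1, c0k + 1)] +
         fr * fc             * x[cbind(r1k + 1, c1k + 1)]
    out[ok] <- v[as.vector(ok)]
  }
  out
}

#' Apply a geometric transform identically to image, mask and ROI
#'
#' The image is resampled bilinearly; mask and ROI use nearest-neighbour so
#' they stay strictly binary. Regions moved in from outside the frame are
#' filled with 0 (background).
#'
#' @param sample an [ImageSample-class] object.
#' @param params transform parameters from [randomTransformParams()] (any
#'   list with `angle`, `dx`, `dy`, `hflip`, `vflip` works).
#' @param sampleId identifier for the transformed sample.
#' @return a transformed [ImageSample-class] object.
#' @export
applyTransform <- function(sample, params,
                           sampleId = paste0(sample@sampleId, "_t")) {
  img <- sample@image
  if (length(dim(img)) == 3) {
    for (ch in seq_len(dim(img)[3]))
      img[, , ch] <- .warp(img[, , ch], params, "bilinear")
  } else {
    img <- .warp(img, params, "bilinear")
  }
  msk <- .warp(sample@mask, params, "nearest")
  roi <- if (!is.null(sample@roi)) .warp(sample@roi, params, "nearest") else NULL
  if (!is.null(roi)) msk <- msk * roi
  imageSample(img, msk, roi = roi, sampleId = sampleId)
}

#' Expand a sample list to a target count by random transforms
#'
#' Returns exactly `config@targetCount` samples: every original (unchanged,
#' first), plus transformed copies drawn by cycling the source list with
#' fresh random parameters. Replicate provenance is recorded in the sample
#' id (`<source>_aug<k>`). The RNG stream is seeded from `config@seed`, so
#' the augmented set is reproducible.
#'
#' @param samples non-empty list of [ImageSample-class] objects.
#' @param config an [AugmentConfig-class] object.
#' @return list of `targetCount` samples.
#' @export
augmentToCount <- function(samples, config) {
  validObject(config)
  n <- length(samples)
  if (n == 0) stop("source list is empty")
  if (config@targetCount < n)
    stop("targetCount (", config@targetCount, ") below source count (", n, ")")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config@seed)
  out <- vector("list", config@targetCount)
  out[seq_len(n)] <- samples
  for (j in seq_len(config@targetCount - n)) {
    src <- samples[[(j - 1L) %% n + 1L]]
    params <- randomTransformParams(config, min(dim(src@mask)))
    out[[n + j]] <- applyTransform(src, params,
                                   sampleId = sprintf("%s_aug%d", src@sampleId, j))
  }
  out
}

#' Augment a dataset on disk
#'
#' Loads every manifest entry, expands to `config@targetCount` with
#' [augmentToCount()], and writes the augmented set (PNG images/masks plus
#' `manifest.json`) to `outDir`, so a dataset size is a reproducible
#' artifact rather than a property of the training loop.
#'
#' @param manifest a [DatasetManifest-class] object.
#' @param config an [AugmentConfig-class] object.
#' @param outDir output directory.
#' @return the augmented [DatasetManifest-class] object.
#' @export
augmentDataset <- function(manifest, config, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  samples <- lapply(seq_len(nrow(manifest@entries)),
                    function(i) loadSample(manifest, i))
  aug <- augmentToCount(samples, config)
  split <- rep_len(manifest@entries$split, length(aug))
  rows <- vector("list", length(aug))
  for (i in seq_along(aug)) {
    s <- aug[[i]]
    ip <- sprintf("%s_image.png", s@sampleId)
    mp <- sprintf("%s_mask.png", s@sampleId)
    writeImageFile(s@image, file.path(outDir, ip))
    writeMaskFile(s@mask, file.path(outDir, mp))
    rp <- NA_character_
    if (!is.null(s@roi)) {
      rp <- sprintf("%s_roi.png", s@sampleId)
      writeMaskFile(s@roi, file.path(outDir, rp))
    }
    rows[[i]] <- data.frame(sample_id = s@sampleId, image_path = ip,
                            mask_path = mp, roi_path = rp, split = split[i],
                            stringsAsFactors = FALSE)
  }
  man <- new("DatasetManifest", entries = do.call(rbind, rows), root = outDir)
  saveManifest(man, file.path(outDir, "manifest.json"))
  man
}
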