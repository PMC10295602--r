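#' @include AllClasses.R
NULL

# Render one soft stroke (distance-based, 1-px anti-aliased edge) into the
# accumulation canvas. Canvas indexed [row, col]; coordinates are 0-based
# (row, col) with origin top-left.
.draw_segment <- function(soft, r0, c0, r1, c1, halfw) {
  H <- nrow(soft); W <- ncol(soft)
  pad <- halfw + 1.5
  rmin <- max(1L, floor(min(r0, r1) - pad) + 1L)
  rmax <- min(H, ceiling(max(r0, r1) + pad) + 1L)
  cmin <- max(1L, floor(min(c0, c1) - pad) + 1L)
  cmax <- min(W, ceiling(max(c0, c1) + pad) + 1L)
  if (rmin > rmax || cmin > cmax) return(soft)
  rr <- seq.int(rmin, rmax) - 1
  cc <- seq.int(cmin, cmax) - 1
  gr <- matrix(rr, length(rr), length(cc))
  gc <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  dr <- r1 - r0; dc <- c1 - c0
  len2 <- dr * dr + dc * dc
  if (len2 < 1e-12) {
    d <- sqrt((gr - r0)^2 + (gc - c0)^2)
  } else {
    t <- pmin(pmax(((gr - r0) * dr + (gc - c0) * dc) / len2, 0), 1)
    d <- sqrt((gr - (r0 + t * dr))^2 + (gc - (c0 + t * dc))^2)
  }
  sval <- pmin(pmax(halfw + 0.5 - d, 0), 1)
  blk <- soft[rmin:rmax, cmin:cmax]
  soft[rmin:rmax, cmin:cmax] <- pmax(blk, sval)
  soft
}

# Grow one vessel tree depth-first; each branch is a short polyline with
# angular jitter, children halve off with perturbed directions and decayed
# width until the recursion level is exhausted.
.grow_tree <- function(soft, r, c, angle, halfw, level, config) {
  H <- nrow(soft); W <- ncol(soft)
  seg_len <- stats::runif(1, 0.12, 0.2) * min(H, W)
  nsub <- 3L
  for (s in seq_len(nsub)) {
    angle <- angle + stats::rnorm(1, sd = 8 * pi / 180)
    r1 <- r + sin(angle) * seg_len / nsub
    c1 <- c + cos(angle) * seg_len / nsub
    soft <- .draw_segment(soft, r, c, r1, c1, halfw)
    r <- r1; c <- c1
  }
  if (level < config@branchDepth) {
    spread <- config@branchAngleDeg * pi / 180
    for (sgn in c(-1, 1)) {
      da <- sgn * spread * stats::runif(1, 0.6, 1.4)
      soft <- .grow_tree(soft, r, c, angle + da,
                         halfw * config@widthDecay, level + 1L, config)
    }
  }
  soft
}

# Smooth low-frequency illumination field spanning exactly
# `illuminationGradient` peak-to-trough: a random-direction linear ramp
# plus a random-centre radial vignette, rescaled.
.illumination_field <- function(H, W, gradient) {
  theta <- stats::runif(1, 0, 2 * pi)
  cx <- stats::runif(1, 0.2, 0.8) * W
  cy <- stats::runif(1, 0.2, 0.8) * H
  gr <- matrix(seq_len(H) - 1, H, W)
  gc <- matrix(seq_len(W) - 1, H, W, byrow = TRUE)
  ramp <- (cos(theta) * gc + sin(theta) * gr) / sqrt(H^2 + W^2)
  vign <- -sqrt((gr - cy)^2 + (gc - cx)^2) / sqrt(H^2 + W^2)
  raw <- ramp + 0.8 * vign
  rng <- range(raw)
  if (diff(rng) < 1e-12) return(matrix(0, H, W))
  ((raw - rng[1]) / diff(rng) - 0.5) * gradient
}

.sample_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 100003 + as.numeric(index)) %% 2147483647)
}

#' Generate one synthetic vascular image/mask pair
#'
#' Grows `nTrees` recursive branching vessel trees (polyline strokes whose
#' half-width decays by `widthDecay` per level), rasterizes them with a
#' 1-pixel anti-aliased edge, and thresholds the soft rendering at 0.5 for
#' the binary mask so mask and image stay geometrically aligned. The image
#' is a smooth illumination field at base level 0.6, darkened by
#' `vesselContrast` under the (soft-edged) vessels, plus Gaussian sensor
#' noise, clipped to `[0,1]`.
#'
#' The pair is fully determined by `(config@seed, index)`; the generator
#' saves and restores the caller's RNG state.
#'
#' @param config a [VesselSimConfig-class] object.
#' @param index non-negative sample index.
#' @return an [ImageSample-class] object.
#' @examples
#' s <- generateSample(vesselSimConfig(seed = 3L), index = 0)
#' mean(s@mask)   # vessel pixel fraction
#' @export
generateSample <- function(config, index = 0L) {
  stopifnot(is(config, "VesselSimConfig"))
  validObject(config)
  if (index < 0) stop("index must be >= 0")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.sample_seed(config@seed, index))

  H <- config@imageSize[1]; W <- config@imageSize[2]
  soft <- matrix(0, H, W)
  if (config@nTrees > 0) {
    for (i in seq_len(config@nTrees)) {
      r0 <- stats::runif(1, 0.1, 0.9) * H
      c0 <- stats::runif(1, 0.1, 0.9) * W
      ang <- stats::runif(1, 0, 2 * pi)
      soft <- .grow_tree(soft, r0, c0, ang, config@rootWidthPx, 1L, config)
    }
  }
  mask <- (soft >= 0.5) * 1
  background <- 0.6 + .illumination_field(H, W, config@illuminationGradient)
  image <- background - config@vesselContrast * soft
  if (config@noiseSigma > 0)
    image <- image + matrix(stats::rnorm(H * W, sd = config@noiseSigma), H, W)
  image <- pmin(pmax(image, 0), 1)
  imageSample(image, mask, sampleId = sprintf("synthetic_%04d", index))
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n` image/mask pairs as 8-bit PNGs plus a JSON manifest
#' (`{"samples": [{"id", "image_path", "mask_path", "split"}, ...]}`).
#'
#' @param config a [VesselSimConfig-class] object.
#' @param n number of samples (>= 1).
#' @param outDir output directory (created if needed).
#' @param split split tag(s), `"train"`/`"test"`, recycled to length `n`.
#' @return a [DatasetManifest-class] object (also written to
#'   `manifest.json` in `outDir`).
#' @export
generateDataset <- function(config, n, outDir, split = "train") {
  stopifnot(n >= 1)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  split <- rep_len(split, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- generateSample(config, i - 1L)
    ip <- sprintf("%s_image.png", s@sampleId)
    mp <- sprintf("%s_mask.png", s@sampleId)
    writeImageFile(s@image, file.path(outDir, ip))
    writeMaskFile(s@mask, file.path(outDir, mp))
    rows[[i]] <- data.frame(sample_id = s@sampleId, image_path = ip,
                            mask_path = mp, roi_path = NA_character_,
                            split = split[i], stringsAsFactors = FALSE)
  }
  entries <- do.call(rbind, rows)
  man <- new("DatasetManifest", entries = entries, root = outDir)
  saveManifest(man, file.path(outDir, "manifest.json"))
  man
}
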