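#' @include AllClasses.R io.R
NULL

#' Convert an image to grayscale
#'
#' @param image 2-d matrix or `(H, W, 3)` RGB array on `[0,1]`.
#' @param mode `"luminance"` (weights 0.299, 0.587, 0.114) or
#'   `"green_channel"` (the channel with highest vessel contrast in fundus
#'   photography).
#' @return 2-d matrix on `[0,1]`; 2-d input is returned unchanged.
#' @export
toGrayscale <- function(image, mode = c("luminance", "green_channel")) {
  mode <- match.arg(mode)
  d <- dim(image)
  if (length(d) == 2) return(image)
  if (length(d) != 3 || !d[3] %in% c(1L, 3L))
    stop("image must be 2-d or (H, W, 3); got channel count ",
         if (length(d) == 3) d[3] else "?")
  if (d[3] == 1) return(image[, , 1])
  if (mode == "green_channel") return(image[, , 2])
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Edge-preserving bilateral filter
#'
#' Each output pixel is the normalized weighted mean of its square window,
#' with weights the product of a spatial Gaussian (sigma
#' `bilateralSigmaSpace`, pixels) and a range Gaussian on intensity
#' difference (sigma `bilateralSigmaColor`, `[0,1]` units). Borders use edge
#' replication, so every output value is a convex combination of window
#' values and stays within the local window extrema. Smooths noise while
#' keeping vessel edges: across a strong edge the range kernel suppresses
#' the contribution of the far side.
#'
#' @param image 2-d matrix on `[0,1]`.
#' @param config a [PreprocessConfig-class] object (window diameter and the
#'   two sigmas are taken from it).
#' @return filtered 2-d matrix.
#' @export
bilateralFilter <- function(image, config = preprocessConfig()) {
  stopifnot(length(dim(image)) == 2)
  r <- (config@bilateralDiameter - 1L) %/% 2L
  ss <- config@bilateralSigmaSpace
  sc <- config@bilateralSigmaColor
  H <- nrow(image); W <- ncol(image)
  acc <- matrix(0, H, W)
  wacc <- matrix(0, H, W)
  for (dy in -r:r) {
    ri <- pmin(H, pmax(1L, seq_len(H) + dy))
    for (dx in -r:r) {
      ci <- pmin(W, pmax(1L, seq_len(W) + dx))
      shifted <- image[ri, ci, drop = FALSE]
      w <- exp(-(dy * dy + dx * dx) / (2 * ss * ss)) *
        exp(-(shifted - image)^2 / (2 * sc * sc))
      acc <- acc + w * shifted
      wacc <- wacc + w
    }
  }
  acc / wacc
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise histogram equalization with the histogram clipped at
#' `claheClipLimit` (excess redistributed) and bilinear interpolation
#' between neighbouring tile mappings. Raises the contrast between vessels
#' and background without amplifying noise the way unlimited equalization
#' would. A constant image is returned unchanged.
#'
#' @param image 2-d matrix on `[0,1]`.
#' @param config a [PreprocessConfig-class] object.
#' @return equalized 2-d matrix on `[0,1]`.
#' @export
claheEnhance <- function(image, config = preprocessConfig()) {
  stopifnot(length(dim(image)) == 2)
  tiles <- config@claheTileGrid
  if (any(tiles > dim(image)))
    stop("tile grid (", tiles[1], "x", tiles[2],
         ") larger than image (", nrow(image), "x", ncol(image), ")")
  if (diff(range(image)) < 1e-12) return(image)
  # EBImage uses (x, y) orientation; transpose in and out
  out <- t(EBImage::clahe(t(image), nx = tiles[2], ny = tiles[1],
                          limit = config@claheClipLimit))
  pmin(pmax(out, 0), 1)
}

#' Power-law (gamma) intensity correction
#'
#' `out = in^gamma` elementwise on the `[0,1]` scale; gamma < 1 brightens,
#' gamma > 1 darkens, preserving monotone ordering of intensities.
#'
#' @param image 2-d matrix on `[0,1]`.
#' @param gamma exponent, > 0.
#' @return corrected matrix.
#' @export
gammaCorrect <- function(image, gamma) {
  if (gamma <= 0) stop("gamma must be > 0")
  image^gamma
}

#' Full preprocessing chain
#'
#' Grayscale conversion, then bilateral smoothing, CLAHE and gamma
#' correction, in that order. With `config@enabled = FALSE` only the
#' grayscale conversion is applied (the ablation arm; also the recommended
#' setting for OCT-A-style data where the enhancement chain can blur thin
#' vessels into the background).
#'
#' @param image 2-d or `(H, W, 3)` array on `[0,1]`.
#' @param config a [PreprocessConfig-class] object.
#' @return preprocessed 2-d matrix on `[0,1]`.
#' @examples
#' s <- generateSample(vesselSimConfig(), 0)
#' p <- preprocessImage(s@image, preprocessConfig())
#' @export
preprocessImage <- function(image, config = preprocessConfig()) {
  validObject(config)
  g <- toGrayscale(image, config@grayscaleMode)
  if (!config@enabled) return(g)
  b <- bilateralFilter(g, config)
  cl <- claheEnhance(b, config)
  gammaCorrect(cl, config@gamma)
}

#' Preprocess every image in a manifest
#'
#' Applies [preprocessImage()] to each entry, writes processed images (and
#' copies masks/ROIs) to `outDir`, and returns the updated manifest.
#'
#' @param manifest a [DatasetManifest-class] object.
#' @param config a [PreprocessConfig-class] object.
#' @param outDir output directory.
#' @return a [DatasetManifest-class] object rooted at `outDir`.
#' @export
preprocessDataset <- function(manifest, config, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  e <- manifest@entries
  rows <- vector("list", nrow(e))
  for (i in seq_len(nrow(e))) {
    s <- loadSample(manifest, i)
    img <- preprocessImage(s@image, config)
    ip <- sprintf("%s_pre.png", s@sampleId)
    mp <- sprintf("%s_mask.png", s@sampleId)
    writeImageFile(img, file.path(outDir, ip))
    writeMaskFile(s@mask, file.path(outDir, mp))
    rp <- NA_character_
    if (!is.null(s@roi)) {
      rp <- sprintf("%s_roi.png", s@sampleId)
      writeMaskFile(s@roi, file.path(outDir, rp))
    }
    rows[[i]] <- data.frame(sample_id = s@sampleId, image_path = ip,
                            mask_path = mp, roi_path = rp,
                            split = e$split[i], stringsAsFactors = FALSE)
  }
  man <- new("DatasetManifest", entries = do.call(rbind, rows), root = outDir)
  saveManifest(man, file.path(outDir, "manifest.json"))
  man
}
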