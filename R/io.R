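#' @include AllClasses.R
NULL

.img_ext <- function(path) tolower(tools::file_ext(path))

#' Read an image file as a `[0,1]` intensity array
#'
#' Supports PNG, TIFF and JPEG. Values are normalized to `[0,1]` whatever
#' the stored bit depth; RGB is kept as an `(H, W, 3)` array, grayscale
#' (and grayscale+alpha, whose alpha is dropped) collapses to a 2-d matrix.
#' Arrays are row-major with origin top-left.
#'
#' @param path file path.
#' @return numeric matrix `(H, W)` or array `(H, W, 3)` on `[0,1]`.
#' @export
readImageFile <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  ext <- .img_ext(path)
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = jpeg::readJPEG(path),
    gif = stop("GIF decoding is not supported (", path,
               "); convert to PNG or TIFF first"),
    stop("unrecognized image format '", ext, "' for: ", path))
  d <- dim(img)
  if (length(d) == 3) {
    if (d[3] == 1) {
      img <- img[, , 1]
    } else if (d[3] == 2) {        # gray + alpha
      img <- img[, , 1]
    } else if (d[3] == 4) {        # RGBA
      img <- img[, , 1:3]
    } else if (d[3] != 3) {
      stop("unsupported channel count ", d[3], " in: ", path)
    }
  }
  pmin(pmax(img, 0), 1)
}

#' Read a binary mask file
#'
#' Reads the file as an image (first channel if multi-channel) and
#' binarizes: normalized values strictly greater than `positiveThreshold`
#' become 1, all others 0.
#'
#' @param path file path.
#' @param positiveThreshold cutoff on the normalized `[0,1]` scale.
#' @return binary matrix `(H, W)`.
#' @export
readMaskFile <- function(path, positiveThreshold = 0.5) {
  img <- readImageFile(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  (img > positiveThreshold) * 1
}

#' Write a `[0,1]` image as 8-bit PNG
#'
#' @param image matrix or `(H, W, 3)` array on `[0,1]` (clipped if outside).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeImageFile <- function(image, path) {
  ok <- try(png::writePNG(pmin(pmax(image, 0), 1), path), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write image: ", path)
  invisible(path)
}

#' Write a binary mask as 8-bit PNG (0 / 255)
#'
#' @param mask binary matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMaskFile <- function(mask, path) {
  writeImageFile((mask > 0.5) * 1, path)
}

#' Save a dataset manifest as JSON
#'
#' @param manifest a [DatasetManifest-class] object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
saveManifest <- function(manifest, path) {
  e <- manifest@entries
  samples <- lapply(seq_len(nrow(e)), function(i) {
    s <- list(id = e$sample_id[i], image_path = e$image_path[i],
              mask_path = e$mask_path[i], split = e$split[i])
    if (!is.na(e$roi_path[i])) s$roi_path <- e$roi_path[i]
    s
  })
  jsonlite::write_json(list(samples = samples), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

.manifest_from_rows <- function(rows, root) {
  man <- new("DatasetManifest", entries = rows, root = root)
  missing <- character(0)
  for (col in c("image_path", "mask_path", "roi_path")) {
    p <- rows[[col]]
    p <- p[!is.na(p)]
    bad <- p[!file.exists(file.path(root, p))]
    missing <- c(missing, bad)
  }
  if (length(missing))
    stop("manifest references missing files:\n  ",
         paste(missing, collapse = "\n  "))
  validObject(man)
  man
}

# numeric prefix ("21_training.tif" -> "21") used for DRIVE-style pairing
.num_prefix <- function(x) sub("^([0-9]+).*$", "\\1", basename(x))

#' Load a dataset manifest
#'
#' Three on-disk layouts are supported:
#' \describe{
#'   \item{`json`}{a `manifest.json` written by [generateDataset()] /
#'     [saveManifest()]; `path` may be the file or its directory.}
#'   \item{`drive_style`}{DRIVE-like: `images/` paired with vessel
#'     annotations in `1st_manual/` and optional field-of-view masks in
#'     `mask/`, matched by shared leading numeric prefix (e.g.
#'     `21_training.tif` with `21_manual1.gif`).}
#'   \item{`rose_style`}{ROSE-like: `img/` paired with `gt/` by identical
#'     file stem.}
#' }
#' An image without a vessel mask is an error (all unpairable files are
#' listed); a missing ROI is not. All referenced files must exist.
#'
#' @param path manifest file or dataset directory.
#' @param layout one of `"json"`, `"drive_style"`, `"rose_style"`.
#' @param split split tag assigned to directory layouts (JSON manifests
#'   carry their own tags).
#' @return a [DatasetManifest-class] object.
#' @export
loadManifest <- function(path, layout = c("json", "drive_style", "rose_style"),
                         split = "train") {
  layout <- match.arg(layout)
  if (layout == "json") {
    mf <- if (dir.exists(path)) file.path(path, "manifest.json") else path
    if (!file.exists(mf)) stop("manifest not found: ", mf)
    root <- dirname(mf)
    js <- jsonlite::read_json(mf)
    rows <- do.call(rbind, lapply(js$samples, function(s) {
      data.frame(sample_id = s$id, image_path = s$image_path,
                 mask_path = s$mask_path,
                 roi_path = if (is.null(s$roi_path)) NA_character_ else s$roi_path,
                 split = s$split, stringsAsFactors = FALSE)
    }))
    if (is.null(rows)) stop("manifest has no samples: ", mf)
    return(.manifest_from_rows(rows, root))
  }
  if (!dir.exists(path)) stop("dataset directory does not exist: ", path)
  if (layout == "drive_style") {
    imgs <- list.files(file.path(path, "images"))
    manuals <- list.files(file.path(path, "1st_manual"))
    rois <- list.files(file.path(path, "mask"))
    key_m <- .num_prefix(manuals)
    key_r <- .num_prefix(rois)
    key_i <- .num_prefix(imgs)
    unpaired <- imgs[!key_i %in% key_m]
    if (length(unpaired))
      stop("images without a vessel annotation:\n  ",
           paste(unpaired, collapse = "\n  "))
    rows <- data.frame(
      sample_id = key_i,
      image_path = file.path("images", imgs),
      mask_path = file.path("1st_manual", manuals[match(key_i, key_m)]),
      roi_path = ifelse(key_i %in% key_r,
                        file.path("mask", rois[match(key_i, key_r)]),
                        NA_character_),
      split = split, stringsAsFactors = FALSE)
  } else {  # rose_style
    imgs <- list.files(file.path(path, "img"))
    gts <- list.files(file.path(path, "gt"))
    stem <- function(x) tools::file_path_sans_ext(basename(x))
    unpaired <- imgs[!stem(imgs) %in% stem(gts)]
    if (length(unpaired))
      stop("images without a vessel annotation:\n  ",
           paste(unpaired, collapse = "\n  "))
    rows <- data.frame(
      sample_id = stem(imgs),
      image_path = file.path("img", imgs),
      mask_path = file.path("gt", gts[match(stem(imgs), stem(gts))]),
      roi_path = NA_character_, split = split, stringsAsFactors = FALSE)
  }
  if (nrow(rows) == 0) stop("no images found under: ", path)
  .manifest_from_rows(rows, path)
}

#' Load one manifest entry as an ImageSample
#'
#' @param manifest a [DatasetManifest-class] object.
#' @param i entry index (1-based).
#' @return an [ImageSample-class] object.
#' @export
loadSample <- function(manifest, i) {
  e <- manifest@entries[i, ]
  img <- readImageFile(file.path(manifest@root, e$image_path))
  msk <- readMaskFile(file.path(manifest@root, e$mask_path))
  roi <- if (!is.na(e$roi_path))
    readMaskFile(file.path(manifest@root, e$roi_path)) else NULL
  if (!is.null(roi)) msk <- msk * roi  # annotations outside the FOV are void
  imageSample(img, msk, roi = roi, sampleId = e$sample_id)
}
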