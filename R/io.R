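# Image and mask readers/writers plus the overlay renderer.
#
# Images are H x W x 3 integer arrays in 0..255. Masks are H x W integer
# matrices over {0, 1} and are stored as black/yellow PNGs following the
# labeling convention of the source imagery (ridge = yellow, crop = black).

.mask_yellow <- c(255L, 255L, 0L)

file_ext <- function(path) tolower(sub(".*\\.", "", path))

#' Read an aerial image
#'
#' Supports PNG, TIFF, and JPEG by file extension. Grayscale images are
#' expanded to three channels; an alpha channel is dropped.
#'
#' @param path input file.
#' @return H x W x 3 integer array, values 0..255.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- file_ext(path)
  a <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("JPEG support needs the 'jpeg' package", call. = FALSE)
      jpeg::readJPEG(path)
    },
    stop("unsupported image format '.", ext, "' for ", path, call. = FALSE))
  if (is.matrix(a)) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  img <- round(a * 255)
  storage.mode(img) <- "integer"
  img
}

#' Write an aerial image
#'
#' @param img H x W x 3 array, values 0..255.
#' @param path output file (PNG or TIFF by extension).
#' @export
write_image <- function(img, path) {
  a <- img / 255
  switch(file_ext(path),
    png = png::writePNG(a, path),
    tif = , tiff = tiff::writeTIFF(a, path),
    stop("unsupported output format for ", path, call. = FALSE))
  invisible(path)
}

#' Write / read a segmentation mask
#'
#' Masks are written as RGB PNGs using the field's labeling convention:
#' label 1 (ridge) maps to yellow, label 0 (crop/background) to black.
#' `read_mask` inverts the convention back to integer labels. A
#' write-then-read round trip is exact.
#'
#' @param mask H x W integer matrix over \{0, 1\}.
#' @param path PNG file path.
#' @return `read_mask` returns the H x W integer label matrix.
#' @export
write_mask <- function(mask, path) {
  check_labels(mask)
  h <- nrow(mask); w <- ncol(mask)
  rgb <- array(0, c(h, w, 3))
  for (ch in 1:3) rgb[, , ch] <- (mask == 1L) * (.mask_yellow[ch] / 255)
  png::writePNG(rgb, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  a <- png::readPNG(path)
  if (is.matrix(a)) {
    lab <- (a > 0.5) * 1L
  } else {
    # yellow (R and G high, B low) -> 1, black -> 0
    lab <- (a[, , 1] > 0.5 & a[, , 2] > 0.5) * 1L
  }
  storage.mode(lab) <- "integer"
  lab
}

#' Render a segmentation overlay
#'
#' Two views of a predicted mask: the label-style view paints ridge pixels
#' yellow on a black background (everything except the ridge is painted
#' black); the overlay view alpha-blends the yellow ridge tint over the
#' source photo, leaving background pixels untouched.
#'
#' @param img H x W x 3 image, values 0..255.
#' @param mask H x W integer mask over \{0, 1\}.
#' @param mode `"label"` or `"overlay"`.
#' @param alpha blend weight of the tint in overlay mode (0 = photo only).
#' @return H x W x 3 integer array.
#' @export
render_overlay <- function(img, mask, mode = c("label", "overlay"),
                           alpha = 0.5) {
  mode <- match.arg(mode)
  if (!identical(dim(img)[1:2], dim(mask)))
    stop("image and mask shapes disagree", call. = FALSE)
  check_labels(mask)
  out <- array(0, dim(img))
  ridge <- mask == 1L
  for (ch in 1:3) {
    plane <- if (mode == "label") matrix(0, nrow(mask), ncol(mask))
             else img[, , ch]
    tint <- .mask_yellow[ch]
    plane[ridge] <- if (mode == "label") tint else
      (1 - alpha) * plane[ridge] + alpha * tint
    out[, , ch] <- plane
  }
  out <- round(out)
  storage.mode(out) <- "integer"
  out
}
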