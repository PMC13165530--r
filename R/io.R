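# PNG I/O. On disk: 8-bit PNG; in memory: floats in [0,1].
# Masks are auto-binarized (0/255 and 0/1 dialects both read correctly
# because readPNG rescales to [0,1]).

#' Read an RGB image PNG as an (H, W, 3) array in [0,1]
#' @param path PNG file.
#' @return numeric array (H, W, 3).
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (is.matrix(x)) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3]
  x
}

#' Read a binary mask PNG
#' @param path PNG file.
#' @return 0/1 matrix.
#' @export
read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (!is.matrix(x)) x <- x[, , 1L]
  (x > 0.5) + 0
}

#' Read a probability-map PNG (continuous values in [0,1])
#' @param path PNG file.
#' @return numeric matrix.
#' @export
read_probability_png <- function(path) {
  x <- png::readPNG(path)
  if (!is.matrix(x)) x <- x[, , 1L]
  x
}

quantize8 <- function(x) round(pmin(pmax(x, 0), 1) * 255) / 255

#' Write an image/map as an 8-bit PNG
#' @param x matrix or (H, W, 3) array in [0,1]; @param path destination.
#' @export
write_png8 <- function(x, path) {
  png::writePNG(quantize8(x), path)
  invisible(path)
}

#' List paired image/mask files of a Kvasir-SEG-style directory
#'
#' Expects `images/` and `masks/` subdirectories with matching stems.
#'
#' @param dir dataset directory.
#' @return data.frame(stem, image, mask).
#' @export
list_pairs <- function(dir) {
  im <- list.files(file.path(dir, "images"), pattern = "\\.png$", full.names = TRUE)
  mk <- list.files(file.path(dir, "masks"), pattern = "\\.png$", full.names = TRUE)
  is <- sub("\\.png$", "", basename(im))
  ms <- sub("\\.png$", "", basename(mk))
  common <- sort(intersect(is, ms))
  if (length(common) == 0L) {
    stop(sprintf("validation error: no paired images/masks under %s", dir))
  }
  data.frame(stem = common,
             image = file.path(dir, "images", paste0(common, ".png")),
             mask = file.path(dir, "masks", paste0(common, ".png")),
             stringsAsFactors = FALSE)
}
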