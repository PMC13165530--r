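# Paired geometric augmentation. The same geometric transform is applied to
# image and mask (mask via nearest-neighbour resampling so labels stay
# binary); cutout applies to the image only.

rot90_arr <- function(x, k) {
  # x: (H, W, C) array; counter-clockwise quarter turns
  k <- k %% 4L
  if (k == 0L) return(x)
  for (i in seq_len(k)) {
    d <- dim(x)
    x <- aperm(x, c(2L, 1L, 3L))[d[2]:1, , , drop = FALSE]
  }
  x
}

#' Augment one image/mask pair
#'
#' Horizontal/vertical flip (p = 0.5 each), rotation by a multiple of 90
#' degrees composed with scale jitter from {0.75, 1, 1.25} (resize out and
#' back; nearest-neighbour for the mask), and cutout of one random
#' rectangle covering at most 25% of the area, image only, p = 0.3. Draws
#' come from the current RNG state; seed the session for reproducibility.
#'
#' @param image (H, W, 3) array in [0,1].
#' @param mask (H, W) binary matrix.
#' @return list(image, mask).
#' @export
augment_sample <- function(image, mask) {
  if (!all(dim(image)[1:2] == dim(mask))) stop("image and mask shapes differ")
  m3 <- array(mask, c(dim(mask), 1L))
  if (stats::runif(1) < 0.5) {                       # horizontal flip
    image <- image[, dim(image)[2]:1, , drop = FALSE]
    m3 <- m3[, dim(m3)[2]:1, , drop = FALSE]
  }
  if (stats::runif(1) < 0.5) {                       # vertical flip
    image <- image[dim(image)[1]:1, , , drop = FALSE]
    m3 <- m3[dim(m3)[1]:1, , , drop = FALSE]
  }
  k <- sample(0:3, 1L)
  image <- rot90_arr(image, k)
  m3 <- rot90_arr(m3, k)
  sc <- sample(c(0.75, 1.0, 1.25), 1L)
  if (sc != 1.0) {
    d <- dim(image)
    hs <- max(round(d[1] * sc), 8L); ws <- max(round(d[2] * sc), 8L)
    im4 <- as_feature_map(image)
    image <- resize_bilinear(resize_bilinear(im4, hs, ws)$y, d[1], d[2])$y[, , , 1L]
    m4 <- as_feature_map(m3[, , 1L])
    m3 <- array(resize_nearest(resize_nearest(m4, hs, ws), d[1], d[2])[, , 1L, 1L],
                c(d[1], d[2], 1L))
  }
  if (stats::runif(1) < 0.3) {                       # cutout, image only
    d <- dim(image)
    fw <- stats::runif(1, 0.1, 0.5)
    fh <- stats::runif(1, 0.1, 0.5)
    if (fw * fh > 0.25) fh <- 0.25 / fw
    cw <- max(1L, floor(fw * d[2])); ch <- max(1L, floor(fh * d[1]))
    r0 <- sample.int(d[1] - ch + 1L, 1L)
    c0 <- sample.int(d[2] - cw + 1L, 1L)
    image[r0:(r0 + ch - 1L), c0:(c0 + cw - 1L), ] <- 0
  }
  list(image = image, mask = m3[, , 1L])
}
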