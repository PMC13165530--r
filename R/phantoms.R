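# Synthetic endoscopy phantoms: a smooth low-frequency "mucosa" field with
# a vignette, one (or more) star-convex lesion(s) whose intensity is shifted
# by a contrast delta and blended over a soft boundary, specular highlights,
# and Gaussian texture noise. The binary mask is the pre-blur lesion
# support; the edge map is its morphological gradient. Controllable
# difficulty emulates the hard cases of real colonoscopy: low-contrast
# camouflaged lesions, small lesions, and saturated reflections.

#' Phantom generation parameters
#'
#' @param side image side length in pixels.
#' @param r_range lesion radius range as fractions of the side; r_max must
#'   be below 0.5.
#' @param contrast intensity shift delta between lesion and mucosa, in
#'   [0.02, 0.5] of the dynamic range.
#' @param noise_sd Gaussian texture-noise standard deviation.
#' @param n_highlights number of saturated specular ellipses (>= 0).
#' @param softness boundary softness b: Gaussian blur sigma (pixels) of the
#'   lesion blend weight; 0 gives a hard edge.
#' @param texture_scale amplitude multiplier of the low-frequency mucosa
#'   harmonics.
#' @param n_lesions lesions per image (default 1).
#' @return parameter list.
#' @export
phantom_params <- function(side = 128L, r_range = c(0.12, 0.30),
                           contrast = 0.25, noise_sd = 0.02,
                           n_highlights = 2L, softness = 1,
                           texture_scale = 1, n_lesions = 1L) {
  if (r_range[2] >= 0.5) stop("parameter error: r_max must be < 0.5")
  if (contrast <= 0) stop("parameter error: contrast delta must be > 0")
  if (n_highlights < 0) stop("parameter error: n_highlights must be >= 0")
  if (softness < 0) stop("parameter error: softness must be >= 0")
  list(side = as.integer(side), r_range = r_range, contrast = contrast,
       noise_sd = noise_sd, n_highlights = as.integer(n_highlights),
       softness = softness, texture_scale = texture_scale,
       n_lesions = as.integer(n_lesions))
}

#' Named difficulty presets
#'
#' "easy" (high contrast, hard boundary), "camouflage" (low contrast, soft
#' boundary — the flat/camouflaged phenotype), "small" (small lesions).
#'
#' @param name preset id.
#' @param side image side.
#' @return parameter list from [phantom_params()].
#' @export
phantom_preset <- function(name = c("easy", "camouflage", "small"), side = 128L) {
  name <- match.arg(name)
  switch(name,
    easy = phantom_params(side, r_range = c(0.15, 0.30), contrast = 0.4,
                          noise_sd = 0.02, n_highlights = 2L, softness = 0),
    camouflage = phantom_params(side, r_range = c(0.12, 0.28), contrast = 0.05,
                                noise_sd = 0.03, n_highlights = 3L, softness = 3),
    small = phantom_params(side, r_range = c(0.05, 0.10), contrast = 0.3,
                           noise_sd = 0.02, n_highlights = 2L, softness = 1)
  )
}

star_convex_mask <- function(side, cx, cy, r0, modes, amps, phases) {
  xs <- matrix(rep(seq_len(side), each = side), side, side)
  ys <- matrix(rep(seq_len(side), times = side), side, side)
  dx <- xs - cx; dy <- ys - cy
  rr <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  rad <- r0 * (1 + Reduce(`+`, lapply(seq_along(modes), function(i)
    amps[i] * cos(modes[i] * th + phases[i])), accumulate = FALSE))
  (rr <= rad) + 0
}

#' Generate one synthetic phantom
#'
#' Bit-identical output for identical seed and parameters.
#'
#' @param params from [phantom_params()] or [phantom_preset()].
#' @param seed integer seed.
#' @return PhantomSample: list(image (H,W,3), mask (H,W), edge_map (H,W),
#'   meta).
#' @export
generate_phantom <- function(params = phantom_params(), seed = 1L) {
  s <- params$side
  set.seed(seed)
  xs <- matrix(rep(seq_len(s), each = s), s, s) / s
  ys <- matrix(rep(seq_len(s), times = s), s, s) / s

  # mucosa base: pinkish tone + low-order harmonics + vignette
  base_rgb <- c(0.72, 0.45, 0.40) + stats::runif(3, -0.05, 0.05)
  field <- matrix(0, s, s)
  n_harm <- 4L
  for (m in seq_len(n_harm)) {
    fx <- stats::runif(1, 0.5, 3); fy <- stats::runif(1, 0.5, 3)
    ph <- stats::runif(1, 0, 2 * pi)
    amp <- 0.06 * params$texture_scale
    field <- field + amp * cos(2 * pi * (fx * xs + fy * ys) + ph)
  }
  vign <- 1 - 0.35 * ((xs - 0.5)^2 + (ys - 0.5)^2) / 0.5

  # star-convex lesion(s)
  mask <- matrix(0, s, s)
  lesions <- list()
  for (li in seq_len(params$n_lesions)) {
    cx <- stats::runif(1, 0.38, 0.62) * s
    cy <- stats::runif(1, 0.38, 0.62) * s
    r0 <- stats::runif(1, params$r_range[1], params$r_range[2]) * s
    modes <- 2:8
    raw <- stats::runif(length(modes), -1, 1) / modes
    amps <- raw * (0.2 / max(sum(abs(raw)), 1e-9))   # total perturbation <= 0.2
    phases <- stats::runif(length(modes), 0, 2 * pi)
    mask <- pmax(mask, star_convex_mask(s, cx, cy, r0, modes, amps, phases))
    lesions[[li]] <- list(center = c(cx, cy), radius = r0)
  }
  blend <- if (params$softness > 0) blur2d(mask, params$softness) else mask

  img <- array(0, c(s, s, 3L))
  for (ch in 1:3) {
    img[, , ch] <- base_rgb[ch] * vign + field - params$contrast * blend
  }

  # specular highlights: small saturated ellipses on lesion and background
  if (params$n_highlights > 0L) for (hi in seq_len(params$n_highlights)) {
    hx <- stats::runif(1, 0.1, 0.9) * s
    hy <- stats::runif(1, 0.1, 0.9) * s
    ra <- stats::runif(1, 1.5, 3.5)
    rb <- stats::runif(1, 1.5, 3.5)
    hl <- exp(-(((xs * s - hx) / ra)^2 + ((ys * s - hy) / rb)^2))
    for (ch in 1:3) img[, , ch] <- img[, , ch] + 1.5 * hl
  }

  if (params$noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), sd = params$noise_sd), dim(img))
  }
  img <- pmin(pmax(img, 0), 1)

  list(image = img, mask = mask, edge_map = make_edge_target(mask),
       meta = list(seed = seed, side = s, contrast = params$contrast,
                   softness = params$softness, noise_sd = params$noise_sd,
                   n_highlights = params$n_highlights, lesions = lesions))
}

#' Generate a phantom dataset split on disk
#'
#' Writes `images/`, `masks/` and `edges/` with zero-padded stems, plus a
#' `manifest.json` of the parameters and per-sample seeds (seed + i).
#'
#' @param n number of samples (>= 1).
#' @param params from [phantom_params()].
#' @param seed base seed; sample i uses seed + i.
#' @param out_dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return invisible out_dir.
#' @export
generate_split <- function(n, params = phantom_params(), seed = 1L, out_dir,
                           overwrite = FALSE) {
  if (n < 1L) stop("parameter error: n must be >= 1")
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !overwrite) {
    stop(sprintf("refusing to write into non-empty directory %s (set overwrite = TRUE)",
                 out_dir))
  }
  for (sub in c("images", "masks", "edges")) {
    dir.create(file.path(out_dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- generate_phantom(params, seed = seed + i)
    stem <- sprintf("%05d", i)
    write_png8(ph$image, file.path(out_dir, "images", paste0(stem, ".png")))
    write_png8(ph$mask, file.path(out_dir, "masks", paste0(stem, ".png")))
    write_png8(ph$edge_map, file.path(out_dir, "edges", paste0(stem, ".png")))
    entries[[i]] <- list(stem = stem, seed = seed + i, meta = ph$meta["lesions"])
  }
  jsonlite::write_json(list(n = n, params = params, base_seed = seed,
                            entries = entries),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
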