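# High-Frequency Boundary Refinement: a fixed-kernel Sobel edge mask drawn
# from the coarse probability map gates shallow features, which are scaled
# by a learnable alpha and injected into the aligned semantics:
#   Medge          = sigmoid(|grad| of coarse_prob)           (fixed Sobel)
#   f_edge_scaled  = alpha * (CBR3x3(f1) * Medge)
#   prediction     = Conv1x1(CBR3x3(CBR3x3(x2) + f_edge_scaled))
# The Sobel pair is stored as non-trainable buffers; Medge is supervised
# directly against the ground-truth contour (no separate edge head).

sobel_kernels <- function() {
  gx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3L, 3L)  # column-major: d/dx
  list(gx = gx, gy = t(gx))
}

#' High-frequency boundary refinement block
#'
#' @param C channel width of x2 and f1.
#' @param combine gradient combination: "magnitude" (sqrt(gx^2+gy^2+delta))
#'   or "abs" (|gx|+|gy|).
#' @param delta stabilizer inside the square root (differentiable at zero).
#' @param centered if TRUE, the sigmoid is applied to (magnitude - tau) so
#'   flat regions map below 0.5; off by default (the literal convention,
#'   whose edge mask has a 0.5 floor).
#' @param tau centering offset used when `centered` is TRUE.
#' @return HBR block object.
#' @export
new_hbr_block <- function(C, combine = c("magnitude", "abs"), delta = 1e-12,
                          centered = FALSE, tau = 2) {
  combine <- match.arg(combine)
  sk <- sobel_kernels()
  blk <- new_layer(children = list(
    cbr_f1 = layer_cbr(3L, C, C),
    cbr_x2 = layer_cbr(3L, C, C),
    cbr_final = layer_cbr(3L, C, C)
  ))
  blk$conv_out <- layer_conv2d(1L, C, 1L, pad = 0L, bias = TRUE)
  blk$alpha <- layer_scalar(1.0, "hbr.alpha")
  blk$sobel_x <- new_param(array(sk$gx, c(3L, 3L, 1L, 1L)), trainable = FALSE,
                           name = "sobel.x")
  blk$sobel_y <- new_param(array(sk$gy, c(3L, 3L, 1L, 1L)), trainable = FALSE,
                           name = "sobel.y")
  blk$.children <- c(blk$.children, list(blk$conv_out))
  blk$.params <- list(blk$alpha, blk$sobel_x, blk$sobel_y)
  blk$C <- C
  blk$combine <- combine
  blk$delta <- delta
  blk$centered <- centered
  blk$tau <- tau
  for (nm in c("cbr_f1", "cbr_x2", "cbr_final")) {
    assign(nm, blk$.children[[nm]], envir = blk)
  }
  blk
}

#' Sobel edge mask of a coarse probability map
#'
#' Fixed (non-trainable) 3x3 horizontal/vertical Sobel kernels with
#' replicate padding (image borders do not fire as spurious edges), combined
#' as a gradient magnitude and passed through a sigmoid. On the default
#' magnitude convention the mask lives in [0.5, 1) and equals 0.5 exactly on
#' spatially constant maps.
#'
#' @param blk HBR block (holds the kernel buffers and configuration).
#' @param coarse_prob single-channel map (H, W, 1, N), values in [0, 1].
#' @return list(y = Medge, back(gy) -> gradient w.r.t. coarse_prob).
#' @export
sobel_edge_mask <- function(blk, coarse_prob) {
  coarse_prob <- as_feature_map(coarse_prob)
  ox <- conv2d(coarse_prob, blk$sobel_x$value, stride = 1L, pad = 1L,
               pad_mode = "replicate")
  oy <- conv2d(coarse_prob, blk$sobel_y$value, stride = 1L, pad = 1L,
               pad_mode = "replicate")
  if (blk$combine == "magnitude") {
    mag <- sqrt(ox$y^2 + oy$y^2 + blk$delta)
    dmag_dx <- ox$y / mag
    dmag_dy <- oy$y / mag
  } else {
    mag <- abs(ox$y) + abs(oy$y)
    dmag_dx <- sign(ox$y)
    dmag_dy <- sign(oy$y)
  }
  z <- if (blk$centered) mag - blk$tau else mag
  med <- sigmoid(z)
  back <- function(gy) {
    gmag <- gy * med * (1 - med)
    ox$back(gmag * dmag_dx)$gx + oy$back(gmag * dmag_dy)$gx
  }
  list(y = med, back = back)
}

#' Edge-gated scaling of shallow features
#'
#' f_edge_scaled = alpha * (CBR3x3(f1) * Medge), Medge broadcast over
#' channels.
#'
#' @param blk HBR block.
#' @param f1 shallow feature (H, W, C, N).
#' @param Medge edge mask (H, W, 1, N) at f1's resolution.
#' @param training logical.
#' @return list(y, back(gy) -> list(g_f1, g_Medge)); alpha's gradient is
#'   accumulated on the block.
#' @export
edge_scale <- function(blk, f1, Medge, training = TRUE) {
  if (!all(dim(f1)[1:2] == dim(Medge)[1:2])) {
    stop(sprintf("resolution mismatch: f1 is %dx%d, Medge is %dx%d",
                 dim(f1)[1], dim(f1)[2], dim(Medge)[1], dim(Medge)[2]))
  }
  ad <- blk$cbr_f1$fwd(f1, training)
  d <- dim(ad$y)
  MB <- broadcast_spatial(Medge, d)
  gated <- ad$y * MB
  a <- blk$alpha$value
  y <- a * gated
  back <- function(gy) {
    blk$alpha$grad <- blk$alpha$grad + sum(gy * gated)
    gg <- gy * a
    list(g_f1 = ad$back(gg * MB), g_Medge = sum_over_channels(gg * ad$y))
  }
  list(y = y, back = back)
}

#' HBR forward pass
#'
#' @param blk HBR block.
#' @param x2 aligned semantic feature (stride 4, C channels).
#' @param f1 shallow feature (stride 4, C channels).
#' @param coarse_prob coarse probability map (stride 4, single channel).
#' @param training logical.
#' @return list(logits (single-channel, stride-4), Medge,
#'   back(gy_logits, gy_Medge) -> list(g_x2, g_f1, g_coarse_prob)).
#' @export
hbr_forward <- function(blk, x2, f1, coarse_prob, training = TRUE) {
  if (!all(dim(x2)[1:2] == dim(f1)[1:2]) ||
      !all(dim(x2)[1:2] == dim(coarse_prob)[1:2])) {
    stop("resolution mismatch: x2, f1 and coarse_prob must share stride-4 resolution")
  }
  se <- sobel_edge_mask(blk, coarse_prob)
  es <- edge_scale(blk, f1, se$y, training)
  sx <- blk$cbr_x2$fwd(x2, training)
  fused <- sx$y + es$y
  fin <- blk$cbr_final$fwd(fused, training)
  out <- blk$conv_out$fwd(fin$y, training)
  back <- function(gy_logits, gy_Medge = NULL) {
    gfused <- fin$back(out$back(gy_logits))
    ges <- es$back(gfused)
    gMedge <- ges$g_Medge
    if (!is.null(gy_Medge)) gMedge <- gMedge + gy_Medge
    list(g_x2 = sx$back(gfused), g_f1 = ges$g_f1,
         g_coarse_prob = se$back(gMedge))
  }
  list(logits = out$y, Medge = se$y, back = back)
}
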