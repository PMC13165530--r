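# Dual-Gated Semantic Fusion: cross-level fusion recalibrated by an
# ECA-style channel gate and a 7x7 spatial gate, with a residual path:
#   Fin = CBR1(f_hi, upsampled) + CBR1(f_lo)
#   Mc  = sigmoid(Conv1D(GAP(Fin)))          (per-channel gate, length C)
#   Ms  = sigmoid(Conv7x7([avgpool_c; maxpool_c](Fin)))   (spatial gate)
#   x   = CBR3x3(Fin + Fin * Mc * Ms)
# Gate variants: "channel_only" forces Ms = 1, "spatial_only" forces Mc = 1.

DSF_VARIANTS <- c("full", "channel_only", "spatial_only")

#' ECA adaptive kernel size for a channel width
#'
#' Nearest odd integer to log2(C)/2 + 1/2 (gamma = 2, b = 1 rule).
#' @param C channel width.
#' @return odd integer kernel size.
#' @export
eca_kernel_size <- function(C) {
  t <- as.integer(floor(abs(log2(C) / 2 + 0.5)))
  if (t %% 2L == 0L) t + 1L else max(t, 1L)
}

broadcast_channel <- function(v, d) {
  # v: (C, N) -> (H, W, C, N)
  array(rep(as.vector(v), each = d[1] * d[2]), d)
}

broadcast_spatial <- function(m, d) {
  # m: (H, W, 1, N) -> (H, W, C, N)
  aperm(array(rep(as.vector(m), times = d[3]), c(d[1], d[2], d[4], d[3])),
        c(1L, 2L, 4L, 3L))
}

sum_over_space <- function(x) {
  d <- dim(x)
  matrix(colSums(matrix(x, nrow = d[1] * d[2])), nrow = d[3])
}

sum_over_channels <- function(x) {
  d <- dim(x)
  y <- rowSums(matrix(aperm(x, c(1L, 2L, 4L, 3L)), ncol = d[3]))
  array(y, c(d[1], d[2], 1L, d[4]))
}

#' Plain addition fusion block (the ablation baseline)
#'
#' Addition-only fusion: each input through its own 1x1 CBR, the high-level map
#' bilinearly upsampled, then element-wise addition. No gates, no smoothing.
#'
#' @param C common channel width.
#' @return fusion block object.
#' @export
new_fuse_block <- function(C) {
  blk <- new_layer(children = list(
    cbr_hi = layer_cbr(1L, C, C, pad = 0L),
    cbr_lo = layer_cbr(1L, C, C, pad = 0L)
  ))
  blk$C <- C
  blk$kind <- "plain"
  blk$cbr_hi <- blk$.children$cbr_hi
  blk$cbr_lo <- blk$.children$cbr_lo
  blk
}

#' Dual-gated semantic fusion block
#'
#' @param C common channel width.
#' @param k 1-D channel-gate kernel size (odd); default from
#'   [eca_kernel_size()].
#' @return DSF block object.
#' @export
new_dsf_block <- function(C, k = eca_kernel_size(C)) {
  blk <- new_layer(children = list(
    cbr_hi = layer_cbr(1L, C, C, pad = 0L),
    cbr_lo = layer_cbr(1L, C, C, pad = 0L),
    eca = layer_conv1d_channel(k),
    spatial = layer_conv2d(7L, 2L, 1L, pad = 3L, bias = TRUE),
    smooth = layer_cbr(3L, C, C)
  ))
  blk$C <- C
  blk$kind <- "dsf"
  for (nm in names(blk$.children)) assign(nm, blk$.children[[nm]], envir = blk)
  blk
}

#' Initial cross-level fusion (Fin)
#'
#' @param blk fusion or DSF block.
#' @param f_hi high-level map (coarser or equal resolution), C channels.
#' @param f_lo low-level map, C channels.
#' @param training logical.
#' @return list(y = Fin at f_lo resolution, back(gy) -> list(g_hi, g_lo)).
#' @export
initial_fuse <- function(blk, f_hi, f_lo, training = TRUE) {
  if (dim(f_hi)[3] != blk$C || dim(f_lo)[3] != blk$C) {
    stop(sprintf("channel mismatch: fusion block expects %d channels, got %d and %d",
                 blk$C, dim(f_hi)[3], dim(f_lo)[3]))
  }
  if (dim(f_hi)[1] > dim(f_lo)[1]) {
    stop("f_hi must not have a larger side than f_lo")
  }
  hi <- blk$cbr_hi$fwd(f_hi, training)
  up <- resize_bilinear(hi$y, dim(f_lo)[1], dim(f_lo)[2])
  lo <- blk$cbr_lo$fwd(f_lo, training)
  list(y = up$y + lo$y, back = function(gy) {
    list(g_hi = hi$back(up$back(gy)), g_lo = lo$back(gy))
  })
}

#' Channel gate Mc
#'
#' Global average pooling to a length-C descriptor, 1-D convolution across
#' channels (replicate padding, no compression), sigmoid.
#'
#' @param blk DSF block.
#' @param Fin fused feature (H, W, C, N).
#' @return list(y = Mc as a (C, N) matrix in (0,1), back(gMc) -> gFin).
#' @export
channel_gate <- function(blk, Fin, training = TRUE) {
  g <- gap_op(Fin)
  cv <- blk$eca$fwd(g$y, training)
  sg <- sigmoid_op(cv$y)
  list(y = sg$y, back = function(gy) g$back(cv$back(sg$back(gy))))
}

#' Spatial gate Ms
#'
#' Channel-wise average and max pooling, concatenation, one 7x7 convolution
#' (zero padding 3, bias), sigmoid.
#'
#' @param blk DSF block.
#' @param Fin fused feature (H, W, C, N).
#' @return list(y = Ms (H, W, 1, N) in (0,1), back(gMs) -> gFin).
#' @export
spatial_gate <- function(blk, Fin, training = TRUE) {
  av <- ch_mean_op(Fin)
  mx <- ch_max_op(Fin)
  ct <- ch_cat_op(av$y, mx$y)
  cv <- blk$spatial$fwd(ct$y, training)
  sg <- sigmoid_op(cv$y)
  list(y = sg$y, back = function(gy) {
    g <- ct$back(cv$back(sg$back(gy)))
    av$back(g$ga) + mx$back(g$gb)
  })
}

#' Dual-gated semantic fusion forward
#'
#' @param blk DSF block from [new_dsf_block()] (or plain block, in which
#'   case the output is Fin itself).
#' @param f_hi,f_lo input maps, C channels each.
#' @param variant "full", "channel_only" (Ms forced to 1) or "spatial_only"
#'   (Mc forced to 1).
#' @param training logical.
#' @return list(x, Fin, Mc, Ms, pre, back(gy) -> list(g_hi, g_lo)); `pre`
#'   is the pre-smoothing tensor Fin + Fin*Mc*Ms.
#' @export
dsf_forward <- function(blk, f_hi, f_lo, variant = "full", training = TRUE) {
  fin <- initial_fuse(blk, f_hi, f_lo, training)
  if (identical(blk$kind, "plain")) {
    return(list(x = fin$y, Fin = fin$y, Mc = NULL, Ms = NULL, pre = fin$y,
                back = fin$back))
  }
  if (!variant %in% DSF_VARIANTS) {
    stop(sprintf("unknown DSF variant '%s'; expected one of: %s",
                 variant, paste(DSF_VARIANTS, collapse = ", ")))
  }
  d <- dim(fin$y)
  use_c <- variant != "spatial_only"
  use_s <- variant != "channel_only"
  cg <- if (use_c) channel_gate(blk, fin$y, training) else NULL
  sg <- if (use_s) spatial_gate(blk, fin$y, training) else NULL
  McB <- if (use_c) broadcast_channel(cg$y, d) else array(1, d)
  MsB <- if (use_s) broadcast_spatial(sg$y, d) else array(1, d)
  gate <- McB * MsB
  pre <- fin$y + fin$y * gate
  sm <- blk$smooth$fwd(pre, training)
  back <- function(gy) {
    gpre <- sm$back(gy)
    gFin <- gpre + gpre * gate
    if (use_c) {
      gMc <- sum_over_space(gpre * fin$y * MsB)
      gFin <- gFin + cg$back(gMc)
    }
    if (use_s) {
      gMs <- sum_over_channels(gpre * fin$y * McB)
      gFin <- gFin + sg$back(gMs)
    }
    fin$back(gFin)
  }
  list(x = sm$y, Fin = fin$y, Mc = if (use_c) cg$y else NULL,
       Ms = if (use_s) sg$y else NULL, pre = pre, back = back)
}
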