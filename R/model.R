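# Full network assembly: encoder -> channel reduction -> top-down fusion
# cascade (x4 = fuse(f4, f3), x3 = fuse(x4, f2), x2 = fuse(x3, f1)) ->
# coarse head / deep-supervision heads -> HBR. Ablation variants:
#   baseline    plain addition fusion, coarse head only (no aux, no HBR)
#   hbr         plain fusion + HBR
#   dsf         dual-gated fusion, no HBR (prediction = coarse head)
#   full        dual-gated fusion + HBR
#   dsf_channel / dsf_spatial   gate-ablated fusion, no HBR

MODEL_VARIANTS <- c("baseline", "hbr", "dsf", "full", "dsf_channel", "dsf_spatial")

#' Model configuration
#'
#' @param backbone "tiny-cnn" or "pvtv2-b2".
#' @param C reduced channel width of the decoder pyramid.
#' @param variant one of baseline, hbr, dsf, full, dsf_channel, dsf_spatial.
#' @param seed integer seed for deterministic weight initialization.
#' @param coarse_head logical; the coarse head must be present whenever HBR
#'   is enabled (it feeds the Sobel mask).
#' @param backbone_weights optional weights-file path for the backbone.
#' @param edge_combine,edge_centered HBR edge-mask options
#'   (see [new_hbr_block()]).
#' @return config list.
#' @export
model_config <- function(backbone = "tiny-cnn", C = 32L, variant = "full",
                         seed = 1L, coarse_head = TRUE,
                         backbone_weights = NULL,
                         edge_combine = "magnitude", edge_centered = FALSE) {
  if (!variant %in% MODEL_VARIANTS) {
    stop(sprintf("unknown model variant '%s'; expected one of: %s",
                 variant, paste(MODEL_VARIANTS, collapse = ", ")))
  }
  has_hbr <- variant %in% c("hbr", "full")
  if (has_hbr && !coarse_head) {
    stop("inconsistent config: HBR requires the coarse head (it consumes coarse_prob)")
  }
  list(backbone = backbone, C = as.integer(C), variant = variant,
       seed = as.integer(seed), coarse_head = coarse_head,
       backbone_weights = backbone_weights,
       edge_combine = edge_combine, edge_centered = edge_centered)
}

variant_has_hbr <- function(variant) variant %in% c("hbr", "full")
variant_has_dsf <- function(variant) variant %in% c("dsf", "full", "dsf_channel", "dsf_spatial")
variant_gate <- function(variant) {
  switch(variant, dsf_channel = "channel_only", dsf_spatial = "spatial_only", "full")
}

#' Build the segmentation model
#'
#' Construction is deterministic for a fixed config seed.
#'
#' @param config from [model_config()] (a bare list with the same fields
#'   also works).
#' @return model handle (environment) with the full layer graph.
#' @export
build_model <- function(config = model_config()) {
  if (is.null(config$variant)) stop("config must name a variant")
  if (!config$variant %in% MODEL_VARIANTS) {
    stop(sprintf("unknown model variant '%s'", config$variant))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(config$seed)
  C <- config$C
  backbone <- make_backbone(config$backbone, config$backbone_weights)
  reducers <- new_channel_reducers(backbone$widths, C)
  make_fuse <- function() {
    if (variant_has_dsf(config$variant)) new_dsf_block(C) else new_fuse_block(C)
  }
  fuse <- list(make_fuse(), make_fuse(), make_fuse())  # x4, x3, x2 levels
  baseline <- identical(config$variant, "baseline")
  aux4 <- if (!baseline) layer_conv2d(1L, C, 1L, pad = 0L, bias = TRUE) else NULL
  aux3 <- if (!baseline) layer_conv2d(1L, C, 1L, pad = 0L, bias = TRUE) else NULL
  coarse <- list(cbr1 = layer_cbr(3L, C, C), cbr2 = layer_cbr(3L, C, C),
                 out = layer_conv2d(1L, C, 1L, pad = 0L, bias = TRUE))
  hbr <- if (variant_has_hbr(config$variant)) {
    new_hbr_block(C, combine = config$edge_combine,
                  centered = isTRUE(config$edge_centered))
  } else NULL
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  model <- new_layer(children = c(
    list(backbone = backbone),
    reducers,
    fuse,
    coarse,
    if (!baseline) list(aux4, aux3),
    if (!is.null(hbr)) list(hbr)
  ))
  model$config <- config
  model$backbone <- backbone
  model$reducers <- reducers
  model$fuse <- fuse
  model$aux4 <- aux4
  model$aux3 <- aux3
  model$coarse <- coarse
  model$hbr <- hbr
  class(model) <- c("dsfbr_model", class(model))
  model
}

#' Full forward pass
#'
#' Runs the cascade and returns all supervision heads, bilinearly upsampled
#' to the input resolution. The stored coarse probability equals
#' sigmoid(upsampled coarse logits) exactly; HBR consumes the native-
#' resolution sigmoid.
#'
#' @param model from [build_model()].
#' @param x image batch (H, W, 3, N), sides divisible by 32.
#' @param training logical; batch-statistics mode for normalization layers.
#' @return list with prediction, coarse_logits, coarse_prob, aux3, aux4,
#'   edge_pred (all at H x W or NULL when the variant lacks the head),
#'   loss_heads (names of distinct logits heads to supervise), native
#'   resolutions, and back(grads) for training.
#' @export
model_forward <- function(model, x, training = TRUE) {
  x <- as_feature_map(x)
  d <- check_input_side(x)
  H <- d[1]; W <- d[2]
  cfg <- model$config
  gate <- variant_gate(cfg$variant)
  enc <- extract_pyramid(x, model$backbone, training)
  red <- reduce_channels(enc$feats, model$reducers, training)
  f <- red$f
  o4 <- dsf_forward(model$fuse[[1]], f[[4]], f[[3]], gate, training)
  o3 <- dsf_forward(model$fuse[[2]], o4$x, f[[2]], gate, training)
  o2 <- dsf_forward(model$fuse[[3]], o3$x, f[[1]], gate, training)

  c1 <- model$coarse$cbr1$fwd(o2$x, training)
  c2 <- model$coarse$cbr2$fwd(c1$y, training)
  co <- model$coarse$out$fwd(c2$y, training)
  coarse_native <- co$y

  baseline <- identical(cfg$variant, "baseline")
  a4 <- if (!baseline) model$aux4$fwd(o4$x, training) else NULL
  a3 <- if (!baseline) model$aux3$fwd(o3$x, training) else NULL

  has_hbr <- !is.null(model$hbr)
  if (has_hbr) {
    sig_native <- sigmoid_op(coarse_native)
    hb <- hbr_forward(model$hbr, o2$x, f[[1]], sig_native$y, training)
    pred_native <- hb$logits
  } else {
    pred_native <- coarse_native
  }

  up_pred <- resize_bilinear(pred_native, H, W)
  up_coarse <- if (has_hbr || !baseline) resize_bilinear(coarse_native, H, W) else NULL
  up_a4 <- if (!baseline) resize_bilinear(a4$y, H, W) else NULL
  up_a3 <- if (!baseline) resize_bilinear(a3$y, H, W) else NULL
  up_edge <- if (has_hbr) resize_bilinear(hb$Medge, H, W) else NULL

  loss_heads <- if (baseline) "prediction"
                else if (has_hbr) c("prediction", "coarse", "aux3", "aux4")
                else c("prediction", "aux3", "aux4")

  back <- function(g) {
    # g: list with (full-res) gradients named prediction, coarse, aux3,
    # aux4, edge_pred; missing/NULL entries are skipped.
    gpred_native <- if (!is.null(g$prediction)) up_pred$back(g$prediction)
                    else array(0, dim(pred_native))
    gx2 <- NULL; gf1_extra <- NULL; gcoarse_native <- NULL
    if (has_hbr) {
      gMedge_ext <- if (!is.null(g$edge_pred)) up_edge$back(g$edge_pred) else NULL
      hbg <- hb$back(gpred_native, gMedge_ext)
      gx2 <- hbg$g_x2
      gf1_extra <- hbg$g_f1
      gcoarse_native <- sig_native$back(hbg$g_coarse_prob)
      if (!is.null(g$coarse)) {
        gcoarse_native <- gcoarse_native + up_coarse$back(g$coarse)
      }
    } else {
      gcoarse_native <- gpred_native
      if (!is.null(g$coarse) && !is.null(up_coarse)) {
        gcoarse_native <- gcoarse_native + up_coarse$back(g$coarse)
      }
    }
    gx2_c <- c1$back(c2$back(co$back(gcoarse_native)))
    gx2 <- if (is.null(gx2)) gx2_c else gx2 + gx2_c
    g2 <- o2$back(gx2)
    gx3 <- g2$g_hi
    if (!baseline && !is.null(g$aux3)) {
      gx3 <- gx3 + a3$back(up_a3$back(g$aux3))
    }
    g3 <- o3$back(gx3)
    gx4 <- g3$g_hi
    if (!baseline && !is.null(g$aux4)) {
      gx4 <- gx4 + a4$back(up_a4$back(g$aux4))
    }
    g4 <- o4$back(gx4)
    gf1 <- g2$g_lo
    if (!is.null(gf1_extra)) gf1 <- gf1 + gf1_extra
    gstages <- red$back(list(gf1, g3$g_lo, g4$g_lo, g4$g_hi))
    enc$back(gstages)
    invisible(NULL)
  }

  list(
    prediction = up_pred$y,
    coarse_logits = if (!is.null(up_coarse)) up_coarse$y else up_pred$y,
    coarse_prob = if (!is.null(up_coarse)) sigmoid(up_coarse$y) else sigmoid(up_pred$y),
    aux3 = if (!baseline) up_a3$y else NULL,
    aux4 = if (!baseline) up_a4$y else NULL,
    edge_pred = if (has_hbr) up_edge$y else NULL,
    loss_heads = loss_heads,
    native = list(stride4 = dim(pred_native)[1:2], input = c(H, W)),
    x2 = o2$x, x3 = o3$x, x4 = o4$x,
    back = back
  )
}

#' Count trainable parameters
#'
#' Fixed buffers (the Sobel kernels) are non-trainable and excluded.
#'
#' @param model model handle.
#' @return integer count.
#' @export
count_parameters <- function(model) {
  ps <- collect_params(model)
  sum(vapply(ps, function(p) if (p$trainable) length(p$value) else 0L, 0L))
}

collect_bn_layers <- function(obj) {
  out <- list()
  walk <- function(o) {
    if (is.environment(o) && !is.null(o$running_mean)) {
      out[[length(out) + 1L]] <<- o
    }
    if (is.environment(o) && !is.null(o$.children)) for (ch in o$.children) walk(ch)
    if (is.list(o)) for (el in o) walk(el)
  }
  walk(obj)
  out
}

#' Save a model checkpoint
#'
#' Writes config, every parameter tensor (including fixed buffers) and the
#' batch-norm running statistics.
#'
#' @param model model handle; @param path destination file.
#' @export
save_checkpoint <- function(model, path) {
  ps <- collect_params(model)
  bns <- collect_bn_layers(model)
  saveRDS(list(
    config = model$config,
    params = lapply(ps, function(p) p$value),
    bn_means = lapply(bns, function(b) b$running_mean),
    bn_vars = lapply(bns, function(b) b$running_var)
  ), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' Rebuilds the model from the stored config and restores all tensors.
#'
#' @param path checkpoint file from [save_checkpoint()].
#' @return model handle.
#' @export
load_checkpoint <- function(path) {
  st <- readRDS(path)
  model <- build_model(st$config)
  ps <- collect_params(model)
  if (length(ps) != length(st$params)) {
    stop(sprintf("checkpoint/config mismatch: %d stored tensors vs %d in model",
                 length(st$params), length(ps)))
  }
  for (i in seq_along(ps)) {
    if (length(ps[[i]]$value) != length(st$params[[i]])) {
      stop(sprintf("checkpoint tensor %d has %d values, model expects %d",
                   i, length(st$params[[i]]), length(ps[[i]]$value)))
    }
    ps[[i]]$value[] <- st$params[[i]]
  }
  bns <- collect_bn_layers(model)
  for (i in seq_along(bns)) {
    bns[[i]]$running_mean <- st$bn_means[[i]]
    bns[[i]]$running_var <- st$bn_vars[[i]]
  }
  model
}
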