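# Pyramid feature extractors. Two backbones are registered:
#   "pvtv2-b2"  — Pyramid Vision Transformer v2, b2 capacity (embed dims
#                 64/128/320/512, depths 3/4/6/3, heads 1/2/5/8, MLP ratios
#                 8/8/4/4, spatial-reduction ratios 8/4/2/1, qkv bias).
#                 Forward pass is inference-only; when trained, the backbone
#                 stays frozen and only the decoder receives updates.
#   "tiny-cnn"  — a four-stage CPU-scale CNN (widths 16/24/32/48) that is
#                 fully differentiable end to end; exists so the whole graph
#                 trains on one CPU in seconds.
# Both produce stage maps at strides 4/8/16/32 relative to the input.

TINY_CNN_WIDTHS <- c(16L, 24L, 32L, 48L)
PVTV2_B2_WIDTHS <- c(64L, 128L, 320L, 512L)

check_input_side <- function(x) {
  d <- dim(x)
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L) {
    stop(sprintf("input sides must be divisible by 32, got %dx%d", d[1], d[2]))
  }
  invisible(d)
}

#' Create a backbone by registry id
#'
#' @param id one of "pvtv2-b2", "tiny-cnn".
#' @param weights optional path to a saved weights file (RDS of named arrays)
#'   to load into the backbone, e.g. pretrained weights.
#' @return backbone object with fields id, widths, fwd().
#' @export
make_backbone <- function(id, weights = NULL) {
  bb <- switch(id,
    "tiny-cnn" = tiny_cnn_backbone(),
    "pvtv2-b2" = pvtv2_b2_backbone(),
    stop(sprintf("unknown backbone id '%s'; registered: tiny-cnn, pvtv2-b2", id))
  )
  if (!is.null(weights)) load_weights_into(bb, weights)
  bb
}

tiny_cnn_backbone <- function() {
  w <- TINY_CNN_WIDTHS
  stem <- layer_cbr(7L, 3L, w[1], stride = 4L, pad = 3L)
  blocks <- list()
  for (i in 2:4) {
    blocks[[i - 1L]] <- list(
      down = layer_cbr(3L, w[i - 1L], w[i], stride = 2L),
      refine = layer_cbr(3L, w[i], w[i])
    )
  }
  bb <- new_layer(children = c(list(stem = stem), blocks))
  bb$id <- "tiny-cnn"
  bb$widths <- w
  bb$fwd <- function(x, training = TRUE) {
    check_input_side(x)
    o1 <- stem$fwd(x, training)
    feats <- list(o1$y)
    backs <- list(list(o1))
    cur <- o1$y
    for (i in 1:3) {
      a <- blocks[[i]]$down$fwd(cur, training)
      b <- blocks[[i]]$refine$fwd(a$y, training)
      cur <- b$y
      feats[[i + 1L]] <- cur
      backs[[i + 1L]] <- list(a, b)
    }
    back <- function(gfeats) {
      # gfeats: list of 4 gradients (NULL allowed), deepest consumed first
      g <- NULL
      for (i in 4:1) {
        gi <- gfeats[[i]]
        if (!is.null(g)) gi <- if (is.null(gi)) g else gi + g
        if (is.null(gi)) next
        if (i == 1L) {
          g <- backs[[1L]][[1L]]$back(gi)
        } else {
          g <- backs[[i]][[1L]]$back(backs[[i]][[2L]]$back(gi))
        }
      }
      g
    }
    list(feats = feats, back = back)
  }
  bb
}

# ---- PVTv2-b2 ----

pvt_attention <- function(dim, num_heads, sr_ratio) {
  at <- new_layer()
  at$q <- layer_linear(dim, dim)
  at$kv <- layer_linear(dim, 2L * dim)
  at$proj <- layer_linear(dim, dim)
  at$num_heads <- num_heads
  at$sr_ratio <- sr_ratio
  children <- list(at$q, at$kv, at$proj)
  if (sr_ratio > 1L) {
    at$sr <- layer_conv2d(sr_ratio, dim, dim, stride = sr_ratio, pad = 0L, bias = TRUE)
    at$norm <- layer_layernorm(dim)
    children <- c(children, list(at$sr, at$norm))
  }
  at$.children <- children
  at$apply <- function(x, H, W) {
    # x: (T, dim) tokens of one sample
    nh <- at$num_heads
    dh <- dim %/% nh
    q <- at$q$apply(x)
    if (at$sr_ratio > 1L) {
      # tokens are row-major (W fastest); rebuild the (H, W, dim, 1) map
      xm <- aperm(array(t(x), c(dim, W, H)), c(3L, 2L, 1L))
      dim(xm) <- c(H, W, dim, 1L)
      xs <- conv2d(xm, at$sr$.params$w$value, at$sr$.params$b$value,
                   stride = at$sr_ratio, pad = 0L)$y
      H2 <- dim(xs)[1]; W2 <- dim(xs)[2]
      x2 <- matrix(aperm(xs[, , , 1L, drop = FALSE], c(3L, 2L, 1L, 4L)), nrow = dim)
      x2 <- at$norm$apply(t(x2))
    } else {
      x2 <- x
    }
    kv <- at$kv$apply(x2)
    kk <- kv[, seq_len(dim), drop = FALSE]
    vv <- kv[, dim + seq_len(dim), drop = FALSE]
    out <- matrix(0, nrow(x), dim)
    for (h in seq_len(nh)) {
      idx <- (h - 1L) * dh + seq_len(dh)
      s <- q[, idx, drop = FALSE] %*% t(kk[, idx, drop = FALSE]) / sqrt(dh)
      s <- exp(s - apply(s, 1L, max))
      s <- s / rowSums(s)
      out[, idx] <- s %*% vv[, idx, drop = FALSE]
    }
    at$proj$apply(out)
  }
  at
}

pvt_mlp <- function(dim, hidden) {
  ml <- new_layer()
  ml$fc1 <- layer_linear(dim, hidden)
  ml$dw_w <- new_param(he_init(c(3L, 3L, hidden), 9), name = "dwconv.w")
  ml$dw_b <- new_param(numeric(hidden), name = "dwconv.b")
  ml$fc2 <- layer_linear(hidden, dim)
  ml$.children <- list(ml$fc1, ml$fc2)
  ml$.params <- list(ml$dw_w, ml$dw_b)
  ml$apply <- function(x, H, W) {
    h1 <- ml$fc1$apply(x)
    hid <- ncol(h1)
    xm <- aperm(array(t(h1), c(hid, W, H)), c(3L, 2L, 1L))
    dim(xm) <- c(H, W, hid, 1L)
    xm <- conv2d_depthwise(xm, ml$dw_w$value, ml$dw_b$value)
    h1 <- t(matrix(aperm(xm[, , , 1L, drop = FALSE], c(3L, 2L, 1L, 4L)), nrow = hid))
    ml$fc2$apply(gelu(h1))
  }
  ml
}

pvt_block <- function(dim, num_heads, mlp_ratio, sr_ratio) {
  bl <- new_layer()
  bl$norm1 <- layer_layernorm(dim)
  bl$attn <- pvt_attention(dim, num_heads, sr_ratio)
  bl$norm2 <- layer_layernorm(dim)
  bl$mlp <- pvt_mlp(dim, dim * mlp_ratio)
  bl$.children <- list(bl$norm1, bl$attn, bl$norm2, bl$mlp)
  bl$apply <- function(x, H, W) {
    x <- x + bl$attn$apply(bl$norm1$apply(x), H, W)
    x + bl$mlp$apply(bl$norm2$apply(x), H, W)
  }
  bl
}

pvtv2_b2_backbone <- function() {
  dims <- PVTV2_B2_WIDTHS
  depths <- c(3L, 4L, 6L, 3L)
  heads <- c(1L, 2L, 5L, 8L)
  mlp_ratios <- c(8L, 8L, 4L, 4L)
  sr_ratios <- c(8L, 4L, 2L, 1L)
  patch_k <- c(7L, 3L, 3L, 3L)
  patch_s <- c(4L, 2L, 2L, 2L)
  in_ch <- c(3L, dims[1:3])
  stages <- list()
  for (i in 1:4) {
    st <- new_layer()
    st$embed <- layer_conv2d(patch_k[i], in_ch[i], dims[i], stride = patch_s[i],
                             pad = patch_k[i] %/% 2L, bias = TRUE)
    st$embed_norm <- layer_layernorm(dims[i])
    st$blocks <- lapply(seq_len(depths[i]), function(j)
      pvt_block(dims[i], heads[i], mlp_ratios[i], sr_ratios[i]))
    st$norm <- layer_layernorm(dims[i])
    st$.children <- c(list(st$embed, st$embed_norm, st$norm), st$blocks)
    stages[[i]] <- st
  }
  bb <- new_layer(children = stages)
  bb$id <- "pvtv2-b2"
  bb$widths <- dims
  bb$stages <- stages
  bb$fwd <- function(x, training = FALSE) {
    check_input_side(x)
    N <- dim(x)[4]
    feats <- vector("list", 4L)
    cur <- x
    for (i in 1:4) {
      st <- stages[[i]]
      emb <- conv2d(cur, st$embed$.params$w$value, st$embed$.params$b$value,
                    stride = patch_s[i], pad = patch_k[i] %/% 2L)$y
      H <- dim(emb)[1]; W <- dim(emb)[2]; C <- dim(emb)[3]
      out <- array(0, c(H, W, C, N))
      for (n in seq_len(N)) {
        # tokens row-major: (H*W, C) with W fastest
        tok <- t(matrix(aperm(emb[, , , n, drop = FALSE], c(3L, 2L, 1L, 4L)), nrow = C))
        tok <- st$embed_norm$apply(tok)
        for (bl in st$blocks) tok <- bl$apply(tok, H, W)
        tok <- st$norm$apply(tok)
        out[, , , n] <- aperm(array(t(tok), c(C, W, H)), c(3L, 2L, 1L))
      }
      feats[[i]] <- out
      cur <- out
    }
    back <- function(gfeats) NULL  # backbone frozen: no gradient into encoder
    list(feats = feats, back = back)
  }
  bb
}

#' Extract the four-stage feature pyramid from an image batch
#'
#' @param image RGB batch (H, W, 3, N), sides divisible by 32.
#' @param backbone backbone object from [make_backbone()].
#' @param training logical; use batch statistics in normalization layers.
#' @return list with `feats` (stage maps at strides 4/8/16/32) and `back`.
#' @export
extract_pyramid <- function(image, backbone, training = FALSE) {
  image <- as_feature_map(image)
  backbone$fwd(image, training)
}

#' Build the 1x1 CBR channel-reduction stage
#'
#' One 1x1 convolution + batch norm + ReLU per encoder stage, mapping the
#' backbone widths to a common width C.
#'
#' @param in_widths integer vector of 4 stage widths.
#' @param C common reduced width (>= 1).
#' @return list of 4 CBR layer objects.
#' @export
new_channel_reducers <- function(in_widths, C) {
  if (C < 1L) stop("C must be a positive integer")
  lapply(in_widths, function(wi) layer_cbr(1L, wi, C, pad = 0L))
}

#' Reduce stage features to a unified pyramid of width C
#'
#' @param stages list of 4 stage maps from [extract_pyramid()].
#' @param reducers from [new_channel_reducers()].
#' @param training logical.
#' @return list with `f` (the pyramid f1..f4, all width C) and `back`.
#' @export
reduce_channels <- function(stages, reducers, training = FALSE) {
  ops <- lapply(1:4, function(i) reducers[[i]]$fwd(stages[[i]], training))
  list(
    f = lapply(ops, `[[`, "y"),
    back = function(gf) lapply(1:4, function(i)
      if (is.null(gf[[i]])) NULL else ops[[i]]$back(gf[[i]]))
  )
}

load_weights_into <- function(obj, path) {
  st <- readRDS(path)
  ps <- collect_params(obj)
  if (length(st) != length(ps)) {
    stop(sprintf("weights file has %d tensors, backbone expects %d",
                 length(st), length(ps)))
  }
  for (i in seq_along(ps)) {
    if (length(st[[i]]) != length(ps[[i]]$value)) {
      stop(sprintf("weight %d size mismatch: file %d vs model %d",
                   i, length(st[[i]]), length(ps[[i]]$value)))
    }
    ps[[i]]$value[] <- st[[i]]
  }
  invisible(obj)
}
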