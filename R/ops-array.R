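# Low-level array operations for feature maps stored as (H, W, C, N) arrays.
# Every differentiable op returns list(y = <output>, back = function(gy) ...)
# where back() returns the input gradient(s); parameter gradients are
# accumulated by the layer wrappers in layers.R.

#' Coerce an image-like array to the (H, W, C, N) feature-map layout
#'
#' 2-D inputs become single-channel single-sample maps, 3-D inputs are taken
#' as (H, W, C) single samples.
#'
#' @param x numeric array of 2, 3, or 4 dimensions.
#' @return 4-D numeric array with dimensions (H, W, C, N).
#' @export
as_feature_map <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array, got a vector")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected 2-4 dimensions, got ", length(d))
  x
}

pad2d <- function(x, p, mode = c("zero", "replicate")) {
  mode <- match.arg(mode)
  if (p == 0L) return(x)
  d <- dim(x)
  H <- d[1]; W <- d[2]
  ri <- c(rep(1L, p), seq_len(H), rep(H, p))
  ci <- c(rep(1L, p), seq_len(W), rep(W, p))
  if (mode == "replicate") return(x[ri, ci, , , drop = FALSE])
  xp <- array(0, c(H + 2L * p, W + 2L * p, d[3], d[4]))
  xp[(p + 1L):(p + H), (p + 1L):(p + W), , ] <- x
  xp
}

# adjoint of pad2d: fold padded-region gradients back onto the interior
unpad_grad <- function(gp, p, mode) {
  if (p == 0L) return(gp)
  d <- dim(gp)
  H <- d[1] - 2L * p; W <- d[2] - 2L * p
  if (mode == "zero") return(gp[(p + 1L):(p + H), (p + 1L):(p + W), , , drop = FALSE])
  # replicate: pad rows/cols were copies of the border, so add their grads back
  gr <- gp[(p + 1L):(p + H), , , , drop = FALSE]
  gr[1L, , , ] <- as.vector(gr[1L, , , ]) +
    as.vector(colSums(gp[seq_len(p), , , , drop = FALSE], dims = 1L))
  gr[H, , , ] <- as.vector(gr[H, , , ]) +
    as.vector(colSums(gp[(p + H + 1L):d[1], , , , drop = FALSE], dims = 1L))
  g <- gr[, (p + 1L):(p + W), , , drop = FALSE]
  left <- gr[, seq_len(p), , , drop = FALSE]
  right <- gr[, (p + W + 1L):d[2], , , drop = FALSE]
  g[, 1L, , ] <- as.vector(g[, 1L, , ]) +
    as.vector(colSums(aperm(left, c(2L, 1L, 3L, 4L)), dims = 1L))
  g[, W, , ] <- as.vector(g[, W, , ]) +
    as.vector(colSums(aperm(right, c(2L, 1L, 3L, 4L)), dims = 1L))
  g
}

#' 2-D convolution (cross-correlation) with gradient closure
#'
#' im2col + BLAS matmul. Weights have dimensions (k, k, Cin, Cout).
#'
#' @param x input map (H, W, Cin, N).
#' @param w kernel array (k, k, Cin, Cout).
#' @param b optional bias vector of length Cout.
#' @param stride integer stride.
#' @param pad integer padding on all sides.
#' @param pad_mode "zero" or "replicate".
#' @return list(y, back); back(gy) returns list(gx, gw, gb).
#' @export
conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, pad_mode = "zero") {
  d <- dim(x)
  kd <- dim(w)
  k <- kd[1]
  if (kd[2] != k) stop("only square kernels supported")
  Cin <- kd[3]; Cout <- kd[4]
  if (d[3] != Cin) {
    stop(sprintf("channel mismatch: input has %d channels, kernel expects %d", d[3], Cin))
  }
  N <- d[4]
  if (k == 1L && stride == 1L && pad == 0L) {
    H <- d[1]; W <- d[2]
    Wm <- matrix(w, nrow = Cin, ncol = Cout)
    xm <- matrix(aperm(x, c(3L, 1L, 2L, 4L)), nrow = Cin)
    ym <- crossprod(Wm, xm)
    if (!is.null(b)) ym <- ym + as.vector(b)
    y <- aperm(array(ym, c(Cout, H, W, N)), c(2L, 3L, 1L, 4L))
    back <- function(gy) {
      gym <- matrix(aperm(gy, c(3L, 1L, 2L, 4L)), nrow = Cout)
      gw <- array(tcrossprod(xm, gym), dim = kd)
      gb <- if (is.null(b)) NULL else rowSums(gym)
      gxm <- Wm %*% gym
      gx <- aperm(array(gxm, c(Cin, H, W, N)), c(2L, 3L, 1L, 4L))
      list(gx = gx, gw = gw, gb = gb)
    }
    return(list(y = y, back = back))
  }
  # channel-first tap decomposition: one small GEMM per kernel tap avoids
  # the k^2-times-larger im2col buffer (allocation-bound in plain R)
  xp <- pad2d(x, pad, pad_mode)
  Hp <- dim(xp)[1]; Wp <- dim(xp)[2]
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  ii <- seq.int(1L, by = stride, length.out = Ho)
  jj <- seq.int(1L, by = stride, length.out = Wo)
  xcf <- aperm(xp, c(3L, 1L, 2L, 4L))                 # (Cin, Hp, Wp, N)
  Wcf <- aperm(w, c(3L, 1L, 2L, 4L))                  # (Cin, k, k, Cout)
  slices <- vector("list", k * k)
  ym <- 0
  for (kx in seq_len(k)) for (ky in seq_len(k)) {
    sl <- matrix(xcf[, ii + ky - 1L, jj + kx - 1L, , drop = FALSE], nrow = Cin)
    slices[[(kx - 1L) * k + ky]] <- sl
    ym <- ym + crossprod(matrix(Wcf[, ky, kx, ], nrow = Cin), sl)
  }
  if (!is.null(b)) ym <- ym + as.vector(b)
  y <- aperm(array(ym, c(Cout, Ho, Wo, N)), c(2L, 3L, 1L, 4L))
  back <- function(gy) {
    gym <- matrix(aperm(gy, c(3L, 1L, 2L, 4L)), nrow = Cout)
    gw <- array(0, kd)
    gxcf <- array(0, c(Cin, Hp, Wp, N))
    for (kx in seq_len(k)) for (ky in seq_len(k)) {
      s <- (kx - 1L) * k + ky
      gw[ky, kx, , ] <- tcrossprod(slices[[s]], gym)
      gsl <- matrix(Wcf[, ky, kx, ], nrow = Cin) %*% gym
      ri <- ii + ky - 1L; ci <- jj + kx - 1L
      gxcf[, ri, ci, ] <- as.vector(gxcf[, ri, ci, ]) + as.vector(gsl)
    }
    gxp <- aperm(gxcf, c(2L, 3L, 1L, 4L))
    list(gx = unpad_grad(gxp, pad, pad_mode), gw = gw,
         gb = if (is.null(b)) NULL else rowSums(gym))
  }
  list(y = y, back = back)
}

# depthwise 3x3 convolution (per-channel kernel), forward only (PVTv2 MLP)
conv2d_depthwise <- function(x, w, b = NULL, pad = 1L) {
  d <- dim(x)
  k <- dim(w)[1]
  C <- d[3]
  xp <- pad2d(x, pad, "zero")
  Ho <- d[1]; Wo <- d[2]
  y <- array(0, d)
  for (kx in seq_len(k)) for (ky in seq_len(k)) {
    wk <- w[ky, kx, ]                       # length C
    sl <- xp[ky:(ky + Ho - 1L), kx:(kx + Wo - 1L), , , drop = FALSE]
    y <- y + sl * rep(wk, each = Ho * Wo)
  }
  if (!is.null(b)) y <- y + rep(b, each = Ho * Wo)
  y
}

relu_op <- function(x) {
  mask <- x > 0
  list(y = x * mask, back = function(gy) gy * mask)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

sigmoid_op <- function(x) {
  y <- sigmoid(x)
  list(y = y, back = function(gy) gy * y * (1 - y))
}

# interpolation weight matrix (n_out x n_in), align_corners = FALSE
bilinear_matrix <- function(n_in, n_out) {
  if (n_in == n_out) return(diag(n_out))
  scale <- n_in / n_out
  src <- (seq_len(n_out) - 0.5) * scale - 0.5
  i0 <- floor(src)
  w1 <- src - i0
  i0c <- pmin(pmax(i0, 0), n_in - 1) + 1
  i1c <- pmin(pmax(i0 + 1, 0), n_in - 1) + 1
  M <- matrix(0, n_out, n_in)
  for (r in seq_len(n_out)) {
    M[r, i0c[r]] <- M[r, i0c[r]] + (1 - w1[r])
    M[r, i1c[r]] <- M[r, i1c[r]] + w1[r]
  }
  M
}

apply_rows <- function(x, M) {
  d <- dim(x)
  y <- M %*% matrix(x, nrow = d[1])
  array(y, c(nrow(M), d[2], d[3], d[4]))
}

apply_cols <- function(x, M) {
  d <- dim(x)
  xt <- aperm(x, c(2L, 1L, 3L, 4L))
  yt <- M %*% matrix(xt, nrow = d[2])
  aperm(array(yt, c(nrow(M), d[1], d[3], d[4])), c(2L, 1L, 3L, 4L))
}

#' Bilinear resize with gradient closure
#'
#' Separable bilinear interpolation (align_corners = FALSE, the convention
#' used for every upsampling step in the decoder).
#'
#' @param x input map (H, W, C, N).
#' @param out_h,out_w target spatial size.
#' @return list(y, back).
#' @export
resize_bilinear <- function(x, out_h, out_w) {
  d <- dim(x)
  RH <- bilinear_matrix(d[1], out_h)
  RW <- bilinear_matrix(d[2], out_w)
  y <- apply_cols(apply_rows(x, RH), RW)
  back <- function(gy) apply_rows(apply_cols(gy, t(RW)), t(RH))
  list(y = y, back = back)
}

#' Nearest-neighbour resize (used for masks so labels stay binary)
#' @param x input map (H, W, C, N).
#' @param out_h,out_w target spatial size.
#' @return resized array.
#' @export
resize_nearest <- function(x, out_h, out_w) {
  d <- dim(x)
  ri <- pmin(pmax(floor((seq_len(out_h) - 0.5) * d[1] / out_h) + 1, 1), d[1])
  ci <- pmin(pmax(floor((seq_len(out_w) - 0.5) * d[2] / out_w) + 1, 1), d[2])
  x[ri, ci, , , drop = FALSE]
}

# global average pooling over space: (H,W,C,N) -> (C,N) matrix
gap_op <- function(x) {
  d <- dim(x)
  y <- matrix(colMeans(matrix(x, nrow = d[1] * d[2])), nrow = d[3])
  back <- function(gy) {
    # gy is (C,N); spread evenly over space
    array(rep(as.vector(gy), each = d[1] * d[2]) / (d[1] * d[2]), d)
  }
  list(y = y, back = back)
}

# mean over channel axis: (H,W,C,N) -> (H,W,1,N)
ch_mean_op <- function(x) {
  d <- dim(x)
  xm <- aperm(x, c(1L, 2L, 4L, 3L))
  y <- array(rowMeans(matrix(xm, ncol = d[3])), c(d[1], d[2], 1L, d[4]))
  back <- function(gy) {
    g <- array(rep(as.vector(gy) / d[3], times = d[3]), c(d[1], d[2], d[4], d[3]))
    aperm(g, c(1L, 2L, 4L, 3L))
  }
  list(y = y, back = back)
}

# max over channel axis with argmax routing: (H,W,C,N) -> (H,W,1,N)
ch_max_op <- function(x) {
  d <- dim(x)
  mx <- x[, , 1L, , drop = FALSE]
  idx <- array(1L, c(d[1], d[2], 1L, d[4]))
  if (d[3] > 1L) for (cc in 2L:d[3]) {
    sl <- x[, , cc, , drop = FALSE]
    upd <- sl > mx
    mx[upd] <- sl[upd]
    idx[upd] <- cc
  }
  back <- function(gy) {
    g <- array(0, d)
    # linear indices of winners
    hw <- d[1] * d[2]
    base <- rep(seq_len(hw), times = d[4])
    n_off <- rep((seq_len(d[4]) - 1L) * hw * d[3], each = hw)
    lin <- base + (as.vector(idx) - 1L) * hw + n_off
    g[lin] <- as.vector(gy)
    g
  }
  list(y = mx, back = back)
}

# concat two maps along channel axis
ch_cat_op <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a
  y[, , da[3] + seq_len(db[3]), ] <- b
  back <- function(gy) {
    list(ga = gy[, , seq_len(da[3]), , drop = FALSE],
         gb = gy[, , da[3] + seq_len(db[3]), , drop = FALSE])
  }
  list(y = y, back = back)
}

# 1-D convolution across the channel axis of a (C, N) descriptor,
# replicate padding, no bias (ECA-style channel interaction)
conv1d_channel <- function(d, w) {
  k <- length(w)
  h <- (k - 1L) %/% 2L
  C <- nrow(d); N <- ncol(d)
  ri <- pmin(pmax(seq_len(C + 2L * h) - h, 1L), C)
  dp <- d[ri, , drop = FALSE]
  y <- matrix(0, C, N)
  for (j in seq_len(k)) y <- y + w[j] * dp[j:(j + C - 1L), , drop = FALSE]
  back <- function(gy) {
    gw <- vapply(seq_len(k), function(j) sum(gy * dp[j:(j + C - 1L), , drop = FALSE]), 0)
    gdp <- matrix(0, C + 2L * h, N)
    for (j in seq_len(k)) {
      gdp[j:(j + C - 1L), ] <- gdp[j:(j + C - 1L), ] + w[j] * gy
    }
    gd <- matrix(0, C, N)
    for (r in seq_len(C + 2L * h)) gd[ri[r], ] <- gd[ri[r], ] + gdp[r, ]
    list(gd = gd, gw = gw)
  }
  list(y = y, back = back)
}

# windowed box mean over each 2-D slice, normalized by the true window
# overlap (count_include_pad = FALSE semantics); x is (H,W,1,N) or (H,W)
box_mean <- function(x, win) {
  x <- as_feature_map(x)
  d <- dim(x)
  h <- (win - 1L) %/% 2L
  H <- d[1]; W <- d[2]
  rcnt <- pmin(seq_len(H) + h, H) - pmax(seq_len(H) - h, 1L) + 1L
  ccnt <- pmin(seq_len(W) + h, W) - pmax(seq_len(W) - h, 1L) + 1L
  cnt <- outer(rcnt, ccnt)
  out <- array(0, d)
  lo_r <- pmax(seq_len(H) - h, 1L); hi_r <- pmin(seq_len(H) + h, H)
  lo_c <- pmax(seq_len(W) - h, 1L); hi_c <- pmin(seq_len(W) + h, W)
  for (n in seq_len(d[4])) for (cc in seq_len(d[3])) {
    m <- x[, , cc, n]
    cs <- apply(m, 2L, cumsum)
    cs <- rbind(0, cs)
    rs <- cs[hi_r + 1L, , drop = FALSE] - cs[lo_r, , drop = FALSE]
    cs2 <- t(apply(rs, 1L, cumsum))
    cs2 <- cbind(0, cs2)
    bs <- cs2[, hi_c + 1L, drop = FALSE] - cs2[, lo_c, drop = FALSE]
    out[, , cc, n] <- bs / cnt
  }
  out
}

# separable Gaussian blur on (H,W) matrices (phantom construction, Fw metric)
gaussian_kernel1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

blur2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(seq_len(H + 2L * r) - r, 1L), H)
  mp <- m[ri, , drop = FALSE]
  m1 <- matrix(0, H, W)
  for (j in seq_along(k)) m1 <- m1 + k[j] * mp[j:(j + H - 1L), , drop = FALSE]
  ci <- pmin(pmax(seq_len(W + 2L * r) - r, 1L), W)
  mp <- m1[, ci, drop = FALSE]
  m2 <- matrix(0, H, W)
  for (j in seq_along(k)) m2 <- m2 + k[j] * mp[, j:(j + W - 1L), drop = FALSE]
  m2
}

# 3x3 binary morphology with replicate padding on a (H,W) 0/1 matrix
shift_stack <- function(m) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(seq_len(H + 2L) - 1L, 1L), H)
  ci <- pmin(pmax(seq_len(W + 2L) - 1L, 1L), W)
  mp <- m[ri, ci, drop = FALSE]
  lapply(1:9, function(s) {
    ky <- (s - 1L) %% 3L; kx <- (s - 1L) %/% 3L
    mp[(1L + ky):(H + ky), (1L + kx):(W + kx), drop = FALSE]
  })
}

dilate3 <- function(m) Reduce(pmax, shift_stack(m))
erode3 <- function(m) Reduce(pmin, shift_stack(m))
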