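# Independent oracles used across the suite. These are deliberately written
# as plain double loops / direct formulas, independent of the package's
# vectorized implementations.

# direct convolution oracle (cross-correlation), any stride/pad/pad mode
oracle_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L,
                          pad_mode = "zero") {
  d <- dim(x); k <- dim(w)[1]; Cout <- dim(w)[4]
  H <- d[1]; W <- d[2]
  pidx <- function(i, n) min(max(i, 1L), n)
  get_px <- function(i, j, ci, n) {
    if (i >= 1 && i <= H && j >= 1 && j <= W) return(x[i, j, ci, n])
    if (pad_mode == "zero") return(0)
    x[pidx(i, H), pidx(j, W), ci, n]
  }
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  y <- array(0, c(Ho, Wo, Cout, d[4]))
  for (n in seq_len(d[4])) for (co in seq_len(Cout)) {
    for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
      acc <- if (is.null(b)) 0 else b[co]
      for (ky in seq_len(k)) for (kx in seq_len(k)) for (ci in seq_len(d[3])) {
        acc <- acc + get_px((i - 1L) * stride + ky - pad, (j - 1L) * stride + kx - pad,
                            ci, n) * w[ky, kx, ci, co]
      }
      y[i, j, co, n] <- acc
    }
  }
  y
}

# Sobel magnitude mask oracle: double-loop convolution, replicate padding
oracle_sobel_mask <- function(m, delta = 1e-12) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  ky <- t(kx)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    gx <- 0; gy <- 0
    for (a in -1:1) for (b in -1:1) {
      v <- m[min(max(i + a, 1), H), min(max(j + b, 1), W)]
      gx <- gx + v * kx[a + 2, b + 2]
      gy <- gy + v * ky[a + 2, b + 2]
    }
    out[i, j] <- 1 / (1 + exp(-sqrt(gx^2 + gy^2 + delta)))
  }
  out
}

# pixel-counting Dice/IoU oracles on binary matrices
oracle_dice <- function(P, G) {
  if (sum(G) == 0) return(if (sum(P) == 0) 1 else 0)
  2 * sum(P == 1 & G == 1) / (sum(P) + sum(G))
}
oracle_iou <- function(P, G) {
  if (sum(G) == 0) return(if (sum(P) == 0) 1 else 0)
  sum(P == 1 & G == 1) / sum(P == 1 | G == 1)
}

# brute-force nearest-foreground distance (squared) + index, O(n * m)
oracle_edt <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  sites <- which(mask)
  si <- (sites - 1) %% H + 1
  sj <- (sites - 1) %/% H + 1
  d2 <- matrix(Inf, H, W)
  idx <- matrix(0L, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    dd <- (si - i)^2 + (sj - j)^2
    kk <- which.min(dd)
    d2[i, j] <- dd[kk]
    idx[i, j] <- sites[kk]
  }
  list(d2 = d2, idx = idx)
}

# weighted F-measure oracle: direct transcription with the brute-force EDT
oracle_wfb <- function(FG, GT) {
  GT <- GT > 0.5
  eps <- .Machine$double.eps
  if (!any(GT)) return(if (all(FG < 0.5)) 1 else 0)
  E <- abs(FG - GT)
  ed <- oracle_edt(GT)
  D <- sqrt(ed$d2)
  Et <- E
  Et[!GT] <- E[ed$idx[!GT]]
  r <- 3L
  xs <- seq(-r, r)
  K <- outer(exp(-xs^2 / 50), exp(-xs^2 / 50))
  K <- K / sum(K)
  H <- nrow(GT); W <- ncol(GT)
  EA <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (a in -r:r) for (b in -r:r) {
      ii <- i + a; jj <- j + b
      v <- if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) Et[ii, jj] else 0
      acc <- acc + v * K[a + r + 1, b + r + 1]
    }
    EA[i, j] <- acc
  }
  MIN_E_EA <- E
  sel <- GT & (EA < E)
  MIN_E_EA[sel] <- EA[sel]
  B <- matrix(1, H, W)
  B[!GT] <- 2 - exp(log(0.5) / 5 * D[!GT])
  Ew <- MIN_E_EA * B
  TPw <- sum(GT) - sum(Ew[GT])
  FPw <- sum(Ew[!GT])
  R <- 1 - mean(Ew[GT])
  P <- TPw / (eps + TPw + FPw)
  min(max(2 * P * R / (eps + P + R), 0), 1)
}

# S-measure reference: direct transcription of the original definition
# (object term + 4-quadrant region SSIM at the mask centroid, alpha = 0.5)
oracle_smeasure <- function(FG, GT, alpha = 0.5) {
  GT <- GT > 0.5
  eps <- .Machine$double.eps
  y <- mean(GT)
  if (y == 0) return(min(max(1 - mean(FG), 0), 1))
  if (y == 1) return(min(max(mean(FG), 0), 1))
  obj <- function(x, region) {
    v <- x[region]
    2 * mean(v) / (mean(v)^2 + 1 + stats::sd(v) + eps)
  }
  fg <- FG; fg[!GT] <- 0
  bg <- 1 - FG; bg[GT] <- 0
  So <- y * obj(fg, GT) + (1 - y) * obj(bg, !GT)
  H <- nrow(GT); W <- ncol(GT)
  rc <- which(GT, arr.ind = TRUE)
  Y <- min(max(round(mean(rc[, 1])), 1), H)
  X <- min(max(round(mean(rc[, 2])), 1), W)
  ssim1 <- function(p, g) {
    n <- length(p)
    x <- mean(p); yy <- mean(g)
    sx <- if (n > 1) sum((p - x)^2) / (n - 1) else 0
    sy <- if (n > 1) sum((g - yy)^2) / (n - 1) else 0
    sxy <- if (n > 1) sum((p - x) * (g - yy)) / (n - 1) else 0
    a <- 4 * x * yy * sxy
    b <- (x^2 + yy^2) * (sx + sy)
    if (a != 0) a / (b + eps) else if (b == 0) 1 else 0
  }
  w <- c(X * Y, (W - X) * Y, X * (H - Y), (W - X) * (H - Y)) / (H * W)
  blocks <- list(list(1:Y, 1:X),
                 if (X < W) list(1:Y, (X + 1):W) else NULL,
                 if (Y < H) list((Y + 1):H, 1:X) else NULL,
                 if (Y < H && X < W) list((Y + 1):H, (X + 1):W) else NULL)
  Sr <- 0
  for (i in 1:4) {
    if (is.null(blocks[[i]])) next
    ri <- blocks[[i]][[1]]; ci <- blocks[[i]][[2]]
    Sr <- Sr + w[i] * ssim1(as.vector(FG[ri, ci]), as.vector(GT[ri, ci] + 0))
  }
  min(max(alpha * So + (1 - alpha) * Sr, 0), 1)
}

# E-measure reference on the continuous map, clamped to [0,1]
oracle_emeasure <- function(FG, GT) {
  GT <- GT > 0.5
  eps <- .Machine$double.eps
  dFM <- FG - mean(FG)
  enhanced <- if (!any(GT)) {
    1 - dFM
  } else if (all(GT)) {
    dFM
  } else {
    dGT <- GT - mean(GT)
    al <- 2 * dGT * dFM / (dGT^2 + dFM^2 + eps)
    (al + 1)^2 / 4
  }
  min(max(sum(enhanced) / (length(GT) - 1 + eps), 0), 1)
}

# polynomial rolling hash over 8-bit-quantized pixel data (determinism
# fingerprints); exact integer arithmetic in doubles (modulus < 2^26)
pixel_hash <- function(x) {
  bytes <- as.numeric(round(pmin(pmax(x, 0), 1) * 255))
  h <- 17
  md <- 67108859
  for (b in bytes) h <- (h * 31 + b) %% md
  sprintf("%d", h)
}

# shared tiny fixtures
make_test_mask <- function(side = 16L, seed = 1L) {
  set.seed(seed)
  m <- matrix(0, side, side)
  r0 <- sample(2:(side - 6), 1)
  c0 <- sample(2:(side - 6), 1)
  m[r0:(r0 + 4), c0:(c0 + 4)] <- 1
  m
}

rand_feature_map <- function(H, W, C, N, seed = 1L, min = -1, max = 1) {
  set.seed(seed)
  array(stats::runif(H * W * C * N, min, max), c(H, W, C, N))
}

# force a CBR block to the identity in inference mode:
# 1x1 (or centred kxk) identity kernel, BN neutralized
neutralize_cbr <- function(cbr, C) {
  w <- cbr$conv$.params$w
  k <- dim(w$value)[1]
  w$value[] <- 0
  mid <- (k + 1L) %/% 2L
  for (cc in seq_len(C)) w$value[mid, mid, cc, cc] <- 1
  cbr$bn$.params$gamma$value[] <- 1
  cbr$bn$.params$beta$value[] <- 0
  cbr$bn$running_mean[] <- 0
  cbr$bn$running_var[] <- 1 - cbr$bn$eps
  invisible(cbr)
}
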