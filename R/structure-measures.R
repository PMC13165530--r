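# Camouflaged-object evaluation measures on continuous prediction maps:
#   weighted F-measure (dependency-weighted precision/recall, beta^2 = 1),
#   S-measure (object + region structural similarity, balance alpha = 0.5),
#   E-measure (enhanced alignment, computed on the continuous map and
#   averaged; clamped to [0,1] so perfect agreement scores exactly 1).

# ---- exact Euclidean distance transform with nearest-site indices ----
# two-pass lower-envelope-of-parabolas algorithm; sites are TRUE pixels.

dt1d <- function(f) {
  n <- length(f)
  d <- numeric(n)
  arg <- integer(n)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -Inf
  z[2L] <- Inf
  if (n > 1L) for (q in 2L:n) {
    s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
    arg[q] <- v[k]
  }
  list(d = d, arg = arg)
}

# returns squared distance to the nearest TRUE pixel and its linear index
edt_with_index <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  LARGE <- 1e15
  f <- ifelse(mask, 0, LARGE)
  g <- matrix(0, H, W)
  rowarg <- matrix(0L, H, W)
  for (j in seq_len(W)) {
    r <- dt1d(f[, j])
    g[, j] <- r$d
    rowarg[, j] <- r$arg
  }
  d2 <- matrix(0, H, W)
  idx <- matrix(0L, H, W)
  for (i in seq_len(H)) {
    r <- dt1d(g[i, ])
    d2[i, ] <- r$d
    jbest <- r$arg
    ibest <- rowarg[i + (jbest - 1L) * H]
    idx[i, ] <- ibest + (jbest - 1L) * H
  }
  list(d2 = d2, idx = idx)
}

filter2_zero <- function(m, K) {
  kr <- (nrow(K) - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  mp <- matrix(0, H + 2L * kr, W + 2L * kr)
  mp[kr + seq_len(H), kr + seq_len(W)] <- m
  out <- matrix(0, H, W)
  for (a in seq_len(nrow(K))) for (b in seq_len(ncol(K))) {
    out <- out + K[a, b] * mp[(a - 1L) + seq_len(H), (b - 1L) + seq_len(W)]
  }
  out
}

gaussian_kernel2d <- function(size = 7L, sigma = 5) {
  r <- (size - 1L) / 2
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  K <- outer(k, k)
  K / sum(K)
}

weighted_fbeta <- function(FG, GT, beta2 = 1) {
  GT <- GT > 0.5
  eps <- .Machine$double.eps
  if (!any(GT)) return(if (all(FG < 0.5)) 1 else 0)
  E <- abs(FG - GT)
  ed <- edt_with_index(GT)
  D <- sqrt(ed$d2)
  Et <- E
  Et[!GT] <- E[ed$idx[!GT]]
  EA <- filter2_zero(Et, gaussian_kernel2d(7L, 5))
  MIN_E_EA <- E
  sel <- GT & (EA < E)
  MIN_E_EA[sel] <- EA[sel]
  B <- matrix(1, nrow(GT), ncol(GT))
  B[!GT] <- 2 - exp(log(0.5) / 5 * D[!GT])
  Ew <- MIN_E_EA * B
  TPw <- sum(GT) - sum(Ew[GT])
  FPw <- sum(Ew[!GT])
  R <- 1 - mean(Ew[GT])
  P <- TPw / (eps + TPw + FPw)
  Q <- (1 + beta2) * P * R / (eps + R + beta2 * P)
  min(max(Q, 0), 1)
}

ssim_region <- function(pred, gt) {
  N <- length(pred)
  x <- mean(pred); y <- mean(gt)
  if (N <= 1L) {
    sx <- 0; sy <- 0; sxy <- 0
  } else {
    sx <- sum((pred - x)^2) / (N - 1)
    sy <- sum((gt - y)^2) / (N - 1)
    sxy <- sum((pred - x) * (gt - y)) / (N - 1)
  }
  aleph <- 4 * x * y * sxy
  beth <- (x^2 + y^2) * (sx + sy)
  if (aleph != 0) aleph / (beth + .Machine$double.eps)
  else if (beth == 0) 1
  else 0
}

s_object_term <- function(x, region) {
  v <- x[region]
  if (length(v) == 0L) return(0)
  mu <- mean(v)
  sdv <- if (length(v) > 1L) stats::sd(v) else 0
  2 * mu / (mu^2 + 1 + sdv + .Machine$double.eps)
}

s_object <- function(FG, GT) {
  fg <- FG; fg[!GT] <- 0
  bg <- 1 - FG; bg[GT] <- 0
  u <- mean(GT)
  u * s_object_term(fg, GT) + (1 - u) * s_object_term(bg, !GT)
}

s_region <- function(FG, GT) {
  H <- nrow(GT); W <- ncol(GT)
  area <- sum(GT)
  rows <- which(GT, arr.ind = TRUE)
  Y <- round(mean(rows[, 1L]))
  X <- round(mean(rows[, 2L]))
  Y <- min(max(Y, 1L), H); X <- min(max(X, 1L), W)
  w1 <- (X * Y) / (H * W)
  w2 <- ((W - X) * Y) / (H * W)
  w3 <- (X * (H - Y)) / (H * W)
  w4 <- 1 - w1 - w2 - w3
  q <- function(ri, ci) ssim_region(as.vector(FG[ri, ci, drop = FALSE]),
                                    as.vector(GT[ri, ci, drop = FALSE] + 0))
  r1 <- seq_len(Y); r2 <- if (Y < H) (Y + 1L):H else integer(0)
  c1 <- seq_len(X); c2 <- if (X < W) (X + 1L):W else integer(0)
  s <- w1 * q(r1, c1)
  if (length(c2)) s <- s + w2 * q(r1, c2)
  if (length(r2)) s <- s + w3 * q(r2, c1)
  if (length(r2) && length(c2)) s <- s + w4 * q(r2, c2)
  s
}

s_measure <- function(FG, GT, alpha = 0.5) {
  GT <- GT > 0.5
  y <- mean(GT)
  if (y == 0) return(min(max(1 - mean(FG), 0), 1))
  if (y == 1) return(min(max(mean(FG), 0), 1))
  Q <- alpha * s_object(FG, GT) + (1 - alpha) * s_region(FG, GT)
  min(max(Q, 0), 1)
}

e_measure <- function(FG, GT) {
  GT <- GT > 0.5
  eps <- .Machine$double.eps
  H <- nrow(GT); W <- ncol(GT)
  dFM <- FG - mean(FG)
  if (!any(GT)) {
    enhanced <- 1 - dFM
  } else if (all(GT)) {
    enhanced <- dFM
  } else {
    dGT <- GT - mean(GT)
    align <- 2 * dGT * dFM / (dGT^2 + dFM^2 + eps)
    enhanced <- (align + 1)^2 / 4
  }
  min(max(sum(enhanced) / (H * W - 1 + eps), 0), 1)
}

#' Structure-quality measures of a prediction against a mask
#'
#' Weighted F-measure (beta^2 = 1), S-measure (alpha = 0.5) and E-measure
#' (enhanced alignment on the continuous map, mean variant), each clamped
#' to [0, 1]. The prediction is consumed as a continuous map, not
#' thresholded.
#'
#' @param pred probability map (matrix in [0,1]).
#' @param gt binary mask (matrix).
#' @return named numeric vector c(wfb, smeasure, emeasure).
#' @export
structure_measures <- function(pred, gt) {
  pred <- as_mask_matrix(pred)
  gt <- as_mask_matrix(gt)
  if (!identical(dim(pred), dim(gt))) stop("pred and gt must share shape")
  c(wfb = weighted_fbeta(pred, gt),
    smeasure = s_measure(pred, gt),
    emeasure = e_measure(pred, gt))
}
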