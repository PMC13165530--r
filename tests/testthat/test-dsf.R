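# Dual-gated semantic fusion: gate algebra, ranges, variants, gradients.

test_that("initial fusion has the shape contract and constant-map algebra", {
  set.seed(10)
  blk <- new_dsf_block(32L)
  f_hi <- rand_feature_map(11, 11, 32, 2, seed = 1, min = 0, max = 1)
  f_lo <- rand_feature_map(22, 22, 32, 2, seed = 2, min = 0, max = 1)
  fin <- initial_fuse(blk, f_hi, f_lo, training = TRUE)
  expect_equal(dim(fin$y), c(22L, 22L, 32L, 2L))
  # identity-configured CBRs on constant inputs: Fin = c1 + c2 exactly
  # (bilinear upsampling of a constant is that constant)
  blk2 <- new_dsf_block(4L)
  neutralize_cbr(blk2$cbr_hi, 4L)
  neutralize_cbr(blk2$cbr_lo, 4L)
  c1 <- array(0.3, c(6, 6, 4, 1)); c2 <- array(1.2, c(12, 12, 4, 1))
  fin2 <- initial_fuse(blk2, c1, c2, training = FALSE)
  expect_equal(fin2$y, array(1.5, c(12, 12, 4, 1)), tolerance = 1e-7)
  # equal-resolution degenerate case: plain elementwise sum path
  fin3 <- initial_fuse(blk2, c2, c2, training = FALSE)
  expect_equal(fin3$y, array(2.4, c(12, 12, 4, 1)), tolerance = 1e-7)
  # channel mismatch is a dimension error
  expect_error(initial_fuse(blk, rand_feature_map(11, 11, 16, 2), f_lo),
               "channel mismatch")
})

test_that("gates are sigmoid-valued: zero weights give exactly 0.5", {
  blk <- new_dsf_block(8L)
  blk$eca$.params$w$value[] <- 0
  blk$spatial$.params$w$value[] <- 0
  blk$spatial$.params$b$value[] <- 0
  z <- array(0, c(10, 10, 8, 2))
  expect_equal(channel_gate(blk, z)$y, matrix(0.5, 8, 2))
  expect_equal(spatial_gate(blk, z)$y, array(0.5, c(10, 10, 1, 2)))
})

test_that("channel gate: uniform descriptors give equal entries, doubling raises the pooled mean", {
  set.seed(11)
  blk <- new_dsf_block(8L)
  # channel-constant input -> uniform GAP descriptor -> all Mc equal
  # (replicate padding keeps the 1-D convolution symmetric at the ends)
  fin <- array(rep(0.7, 10 * 10 * 8), c(10, 10, 8, 1))
  mc <- channel_gate(blk, fin)$y
  expect_equal(max(mc) - min(mc), 0, tolerance = 1e-12)
  # doubling one channel strictly increases its pooled descriptor
  x <- rand_feature_map(6, 6, 8, 1, seed = 12, min = 0.1, max = 1)
  g1 <- dsfbr:::gap_op(x)$y
  x2 <- x; x2[, , 3, ] <- 2 * x2[, , 3, ]
  g2 <- dsfbr:::gap_op(x2)$y
  expect_gt(g2[3, 1], g1[3, 1])
  expect_equal(g2[-3, 1], g1[-3, 1])
})

test_that("spatial gate output is at Fin's resolution and interior-constant on constant maps", {
  set.seed(13)
  blk <- new_dsf_block(8L)
  fin <- array(0.4, c(12, 14, 8, 1))
  ms <- spatial_gate(blk, fin)$y
  expect_equal(dim(ms), c(12L, 14L, 1L, 1L))
  interior <- ms[4:9, 4:11, 1, 1]
  expect_equal(max(interior) - min(interior), 0, tolerance = 1e-12)
})

test_that("gate range and residual sandwich hold on random nonnegative inputs", {
  for (seed in 1:5) {
    set.seed(seed + 100)
    blk <- new_dsf_block(8L)
    f_hi <- rand_feature_map(5, 5, 8, 2, seed = seed, min = 0, max = 2)
    f_lo <- rand_feature_map(10, 10, 8, 2, seed = seed + 50, min = 0, max = 2)
    out <- dsf_forward(blk, f_hi, f_lo, "full", training = TRUE)
    expect_true(all(out$Mc > 0 & out$Mc < 1))
    expect_true(all(out$Ms > 0 & out$Ms < 1))
    # Fin >= 0 (sum of two post-ReLU maps), and Fin <= pre <= 2*Fin
    expect_true(all(out$Fin >= 0))
    expect_true(all(out$pre >= out$Fin))
    expect_true(all(out$pre <= 2 * out$Fin + 1e-12))
  }
})

test_that("forced gates reproduce the residual gating algebra exactly", {
  set.seed(14)
  blk <- new_dsf_block(4L)
  f_hi <- rand_feature_map(4, 4, 4, 1, seed = 9, min = 0, max = 1)
  f_lo <- rand_feature_map(8, 8, 4, 1, seed = 10, min = 0, max = 1)
  # channel_only forces Ms = 1; with zero eca weights Mc = 0.5 everywhere,
  # so pre = 1.5 * Fin
  blk$eca$.params$w$value[] <- 0
  o <- dsf_forward(blk, f_hi, f_lo, "channel_only", training = TRUE)
  expect_equal(o$pre, 1.5 * o$Fin, tolerance = 1e-12)
  # spatial_only with zero spatial kernel: Ms = 0.5, pre = 1.5 * Fin
  blk$spatial$.params$w$value[] <- 0
  blk$spatial$.params$b$value[] <- 0
  o2 <- dsf_forward(blk, f_hi, f_lo, "spatial_only", training = TRUE)
  expect_equal(o2$pre, 1.5 * o2$Fin, tolerance = 1e-12)
  # saturated gates: +/- large bias drives Ms to 1 or 0, giving 2*Fin / Fin
  blk$spatial$.params$b$value[] <- 50
  o3 <- dsf_forward(blk, f_hi, f_lo, "spatial_only", training = TRUE)
  expect_equal(o3$pre, 2 * o3$Fin, tolerance = 1e-8)
  blk$spatial$.params$b$value[] <- -50
  o4 <- dsf_forward(blk, f_hi, f_lo, "spatial_only", training = TRUE)
  expect_equal(o4$pre, o4$Fin, tolerance = 1e-8)
  expect_error(dsf_forward(blk, f_hi, f_lo, "both_gates"), "unknown DSF variant")
})

test_that("gradient flows to both fusion inputs", {
  set.seed(15)
  blk <- new_dsf_block(6L)
  f_hi <- rand_feature_map(4, 4, 6, 2, seed = 16, min = 0, max = 1)
  f_lo <- rand_feature_map(8, 8, 6, 2, seed = 17, min = 0, max = 1)
  out <- dsf_forward(blk, f_hi, f_lo, "full", training = TRUE)
  g <- out$back(array(1, dim(out$x)))
  expect_true(is.finite(sum(abs(g$g_hi))) && sum(abs(g$g_hi)) > 0)
  expect_true(is.finite(sum(abs(g$g_lo))) && sum(abs(g$g_lo)) > 0)
})

test_that("dsf gradients match finite differences through the gates", {
  set.seed(16)
  blk <- new_dsf_block(4L)
  f_hi <- rand_feature_map(3, 3, 4, 1, seed = 18, min = 0, max = 1)
  f_lo <- rand_feature_map(6, 6, 4, 1, seed = 19, min = 0, max = 1)
  r <- rand_feature_map(6, 6, 4, 1, seed = 20)
  loss <- function(fh, fl) sum(dsf_forward(blk, fh, fl, "full", training = TRUE)$x * r)
  out <- dsf_forward(blk, f_hi, f_lo, "full", training = TRUE)
  g <- out$back(r)
  eps <- 1e-6
  for (i in sample(length(f_hi), 3)) {
    fp <- f_hi; fm <- f_hi; fp[i] <- fp[i] + eps; fm[i] <- fm[i] - eps
    expect_equal(g$g_hi[i], (loss(fp, f_lo) - loss(fm, f_lo)) / (2 * eps), tolerance = 1e-4)
  }
  for (i in sample(length(f_lo), 3)) {
    fp <- f_lo; fm <- f_lo; fp[i] <- fp[i] + eps; fm[i] <- fm[i] - eps
    expect_equal(g$g_lo[i], (loss(f_hi, fp) - loss(f_hi, fm)) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("eca kernel rule gives k = 3 at C = 32", {
  expect_equal(eca_kernel_size(32L), 3L)
  expect_true(eca_kernel_size(64L) %% 2L == 1L)
})
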