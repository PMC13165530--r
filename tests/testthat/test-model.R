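# Network assembly: variants, determinism, parameter accounting, checkpoints.

test_that("build_model is deterministic for a fixed seed", {
  m1 <- build_model(model_config(backbone = "tiny-cnn", C = 16, variant = "full", seed = 9))
  m2 <- build_model(model_config(backbone = "tiny-cnn", C = 16, variant = "full", seed = 9))
  p1 <- collect_params(m1); p2 <- collect_params(m2)
  expect_equal(length(p1), length(p2))
  for (i in seq_along(p1)) expect_identical(p1[[i]]$value, p2[[i]]$value)
  m3 <- build_model(model_config(backbone = "tiny-cnn", C = 16, variant = "full", seed = 10))
  p3 <- collect_params(m3)
  expect_false(identical(p1[[1]]$value, p3[[1]]$value))
})

test_that("variants expose exactly their heads", {
  set.seed(1)
  x <- rand_feature_map(64, 64, 3, 2, seed = 2, min = 0, max = 1)
  out_full <- model_forward(build_model(model_config(variant = "full", C = 8, seed = 1)), x)
  expect_equal(dim(out_full$prediction), c(64L, 64L, 1L, 2L))
  expect_false(is.null(out_full$aux3) || is.null(out_full$aux4) || is.null(out_full$edge_pred))
  expect_true(all(out_full$coarse_prob > 0 & out_full$coarse_prob < 1))
  expect_gte(min(out_full$edge_pred), 0.5)
  out_base <- model_forward(build_model(model_config(variant = "baseline", C = 8, seed = 1)), x)
  expect_null(out_base$aux3); expect_null(out_base$aux4); expect_null(out_base$edge_pred)
  expect_equal(out_base$loss_heads, "prediction")
  out_dsf <- model_forward(build_model(model_config(variant = "dsf", C = 8, seed = 1)), x)
  expect_null(out_dsf$edge_pred)
  expect_setequal(out_dsf$loss_heads, c("prediction", "aux3", "aux4"))
  expect_error(model_config(variant = "resnet"), "unknown model variant")
  expect_error(model_config(variant = "full", coarse_head = FALSE), "inconsistent config")
})

test_that("parameter counts match hand-derived closed forms", {
  # a bare 1x1 conv 32 -> 1 with bias
  ly <- layer_conv2d(1L, 32L, 1L, pad = 0L, bias = TRUE)
  expect_equal(sum(vapply(collect_params(ly), function(p) length(p$value), 0L)), 33L)
  # one DSF block at C = 32:
  # 2 * (32*32 + 64) for the two 1x1 CBRs, 3 for the 1-D gate kernel,
  # 2*49 + 1 for the spatial gate, 9*32*32 + 64 for the 3x3 CBR
  blk <- new_dsf_block(32L)
  want <- 2 * (32 * 32 + 64) + 3 + (2 * 49 + 1) + (9 * 32 * 32 + 64)
  expect_equal(sum(vapply(collect_params(blk), function(p) length(p$value), 0L)),
               want)
  expect_equal(want, 11558L)
})

test_that("ablation lattice: parameter count strictly increases toward the full model", {
  counts <- vapply(c("baseline", "hbr", "dsf", "full"), function(v)
    count_parameters(build_model(model_config(backbone = "tiny-cnn", C = 16,
                                              variant = v, seed = 1))), 0L)
  expect_lt(counts[["baseline"]], counts[["hbr"]])
  expect_lt(counts[["baseline"]], counts[["dsf"]])
  expect_lt(counts[["hbr"]], counts[["full"]])
  expect_lt(counts[["dsf"]], counts[["full"]])
})

test_that("count_parameters excludes the fixed Sobel buffers", {
  m <- build_model(model_config(backbone = "tiny-cnn", C = 8, variant = "full", seed = 1))
  n_all <- sum(vapply(collect_params(m), function(p) length(p$value), 0L))
  expect_equal(n_all - count_parameters(m), 18L)   # two 3x3 kernels
})

test_that("forward is deterministic in inference mode", {
  m <- build_model(model_config(backbone = "tiny-cnn", C = 8, variant = "full", seed = 4))
  x <- rand_feature_map(64, 64, 3, 2, seed = 5, min = 0, max = 1)
  o1 <- model_forward(m, x, training = FALSE)
  o2 <- model_forward(m, x, training = FALSE)
  expect_identical(o1$prediction, o2$prediction)
  expect_identical(o1$edge_pred, o2$edge_pred)
})

test_that("nearly all trainable parameters receive gradient on a random batch", {
  set.seed(6)
  m <- build_model(model_config(backbone = "tiny-cnn", C = 32, variant = "full", seed = 11))
  params <- collect_params(m)
  x <- rand_feature_map(128, 128, 3, 4, seed = 7, min = 0, max = 1)
  G <- array(0, c(128, 128, 1, 4)); G[30:100, 40:90, 1, ] <- 1
  out <- model_forward(m, x, training = TRUE)
  lb <- total_loss(out, G)
  zero_grads(params)
  out$back(lb$grads)
  tot <- 0; nz <- 0
  for (p in params) if (p$trainable) {
    tot <- tot + length(p$grad); nz <- nz + sum(p$grad != 0)
  }
  expect_gt(nz / tot, 0.99)
  # every trainable tensor is on a gradient pathway
  touched <- vapply(params, function(p) !p$trainable || any(p$grad != 0), TRUE)
  expect_true(all(touched))
})

test_that("checkpoint round-trip is bit-identical in evaluation", {
  td <- withr::local_tempdir()
  m <- build_model(model_config(backbone = "tiny-cnn", C = 8, variant = "full", seed = 12))
  x <- rand_feature_map(64, 64, 3, 1, seed = 13, min = 0, max = 1)
  before <- model_forward(m, x, training = FALSE)$prediction
  ck <- file.path(td, "m.ckpt")
  save_checkpoint(m, ck)
  m2 <- load_checkpoint(ck)
  after <- model_forward(m2, x, training = FALSE)$prediction
  expect_identical(before, after)
})

test_that("checkpoint loading reports mismatched shapes", {
  td <- withr::local_tempdir()
  m <- build_model(model_config(backbone = "tiny-cnn", C = 8, variant = "full", seed = 14))
  ck <- file.path(td, "m.ckpt")
  save_checkpoint(m, ck)
  st <- readRDS(ck)
  st$config$C <- 16L
  saveRDS(st, ck)
  expect_error(load_checkpoint(ck), "mismatch|expects")
})

test_that("full pvtv2-b2 forward yields all five outputs at input resolution", {
  m <- build_model(model_config(backbone = "pvtv2-b2", C = 32, variant = "full", seed = 1))
  x <- rand_feature_map(64, 64, 3, 1, seed = 15, min = 0, max = 1)
  out <- model_forward(m, x, training = FALSE)
  for (nm in c("prediction", "coarse_prob", "aux3", "aux4", "edge_pred")) {
    expect_equal(dim(out[[nm]]), c(64L, 64L, 1L, 1L), info = nm)
  }
})
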