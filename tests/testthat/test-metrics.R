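# Metric suite: counting oracles, Dice-IoU identity, structure measures.

test_that("mDice/mIoU match pixel-counting oracles on 200 random mask pairs", {
  set.seed(70)
  preds <- list(); gts <- list()
  for (i in 1:200) {
    preds[[i]] <- (matrix(runif(256), 16, 16) > runif(1, 0.3, 0.7)) + 0
    gts[[i]] <- (matrix(runif(256), 16, 16) > runif(1, 0.3, 0.7)) + 0
  }
  md <- mean_dice(preds, gts)
  mi <- mean_iou(preds, gts)
  od <- vapply(1:200, function(i) oracle_dice(preds[[i]], gts[[i]]), 0)
  oi <- vapply(1:200, function(i) oracle_iou(preds[[i]], gts[[i]]), 0)
  expect_equal(md$per_image, od)
  expect_equal(mi$per_image, oi)
  expect_equal(md$mean, mean(od))
  # Dice = 2*IoU/(1+IoU) on every binary pair
  expect_equal(md$per_image, 2 * mi$per_image / (1 + mi$per_image), tolerance = 1e-12)
  expect_true(all(md$per_image >= 0 & md$per_image <= 1))
  expect_true(all(mi$per_image >= 0 & mi$per_image <= 1))
})

test_that("exact toys: identity, half overlap, empty-agreement convention", {
  G <- matrix(0, 8, 8); G[1:2, 1:2] <- 1
  P <- matrix(0, 8, 8); P[1:2, 2:3] <- 1
  expect_equal(mean_dice(list(G), list(G))$mean, 1)
  expect_equal(mean_dice(list(P), list(G))$mean, 0.5)      # |P|=|G|=4, inter 2
  expect_equal(mean_iou(list(P), list(G))$mean, 1 / 3)     # inter 2, union 6
  z <- matrix(0, 8, 8)
  expect_equal(mean_dice(list(z), list(z))$mean, 1)        # both empty
  expect_equal(mean_dice(list(P), list(z))$mean, 0)        # spurious prediction
  expect_error(mean_dice(list(P), list(G, G)), "validation error")
  expect_error(mean_dice(list(matrix(0, 4, 4)), list(G)), "validation error")
})

test_that("adding correctly predicted pixels never decreases Dice or IoU", {
  set.seed(71)
  for (rep in 1:20) {
    G <- (matrix(runif(256), 16, 16) > 0.5) + 0
    if (sum(G) == 0) next
    P <- G * (matrix(runif(256), 16, 16) > 0.5)      # subset of G
    missing <- which(G == 1 & P == 0)
    if (length(missing) == 0) next
    P2 <- P
    P2[sample(missing, 1)] <- 1
    expect_gte(oracle_dice(P2, G), oracle_dice(P, G))
    expect_gte(oracle_iou(P2, G), oracle_iou(P, G))
    expect_equal(mean_dice(list(P2), list(G))$mean, oracle_dice(P2, G))
  }
})

test_that("structure measures are 1 at perfect agreement and small on inversion", {
  set.seed(72)
  for (seed in 1:4) {
    G <- make_test_mask(16, seed)
    sm <- structure_measures(G, G)
    expect_equal(unname(sm["wfb"]), 1, tolerance = 1e-6)
    expect_equal(unname(sm["smeasure"]), 1, tolerance = 1e-6)
    expect_equal(unname(sm["emeasure"]), 1, tolerance = 1e-6)
    inv <- structure_measures(1 - G, G)
    expect_true(all(inv <= 0.25))
    expect_true(all(sm >= 0 & sm <= 1))
  }
})

test_that("weighted F-measure matches the brute-force oracle on continuous toys", {
  set.seed(73)
  for (seed in 1:5) {
    set.seed(seed + 80)
    G <- make_test_mask(16, seed + 10)
    FG <- pmin(pmax(matrix(runif(256), 16, 16) * 0.8 +
                      0.2 * G + rnorm(256, sd = 0.05), 0), 1)
    expect_equal(unname(structure_measures(FG, G)["wfb"]), oracle_wfb(FG, G),
                 tolerance = 1e-4)
  }
  # constant half prediction against half-foreground mask
  G <- matrix(0, 16, 16); G[, 1:8] <- 1
  FG <- matrix(0.5, 16, 16)
  expect_equal(unname(structure_measures(FG, G)["wfb"]), oracle_wfb(FG, G),
               tolerance = 1e-4)
})

test_that("distance transform matches the brute-force oracle", {
  set.seed(74)
  for (rep in 1:5) {
    m <- matrix(runif(15 * 13) > 0.85, 15, 13)
    if (!any(m)) m[4, 4] <- TRUE
    got <- dsfbr:::edt_with_index(m)
    want <- oracle_edt(m)
    expect_equal(got$d2, want$d2)
    # nearest indices may differ on ties, but distances through them agree
    H <- nrow(m)
    di <- function(idx) {
      si <- (idx - 1) %% H + 1; sj <- (idx - 1) %/% H + 1
      ii <- matrix(rep(seq_len(H), ncol(m)), H)
      jj <- matrix(rep(seq_len(ncol(m)), each = H), H)
      (si - ii)^2 + (sj - jj)^2
    }
    expect_equal(di(got$idx), want$d2)
  }
})

test_that("s-measure and e-measure behave on known degenerate cases", {
  G <- matrix(0, 12, 12)
  # empty ground truth: high score only for an empty prediction
  expect_equal(dsfbr:::s_measure(matrix(0, 12, 12), G), 1)
  expect_lt(dsfbr:::s_measure(matrix(1, 12, 12), G), 0.05)
  expect_equal(dsfbr:::e_measure(matrix(0, 12, 12), G), 1, tolerance = 1e-2)
  # full ground truth
  Gf <- matrix(1, 12, 12)
  expect_equal(dsfbr:::s_measure(matrix(1, 12, 12), Gf), 1)
  # constant 0.5 prediction scores strictly between the extremes
  G2 <- matrix(0, 12, 12); G2[4:9, 4:9] <- 1
  s <- dsfbr:::s_measure(matrix(0.5, 12, 12), G2)
  expect_true(s > 0.2 && s < 0.9)
})

test_that("evaluate_dataset pairs by stem, excludes strays, writes reports", {
  td <- withr::local_tempdir()
  pd <- file.path(td, "preds"); gd <- file.path(td, "gts")
  dir.create(pd); dir.create(gd)
  G1 <- make_test_mask(16, 1); G2 <- make_test_mask(16, 2)
  write_png8(G1, file.path(pd, "a.png")); write_png8(G1, file.path(gd, "a.png"))
  write_png8(G2, file.path(pd, "b.png")); write_png8(G2, file.path(gd, "b.png"))
  write_png8(G2, file.path(pd, "stray.png"))
  out_json <- file.path(td, "report.json")
  expect_warning(rep1 <- evaluate_dataset(pd, gd, list(out_json = out_json,
                                                       out_csv = file.path(td, "r.csv"))),
                 "unpaired")
  expect_equal(rep1$n, 2)
  expect_equal(rep1$means$mDice, 1)
  expect_equal(rep1$means$mIoU, 1)
  expect_true(file.exists(out_json) && file.exists(file.path(td, "r.csv")))
  js <- jsonlite::read_json(out_json)
  expect_equal(js$n, 2)
  # deterministic across repeated runs
  expect_warning(rep2 <- evaluate_dataset(pd, gd, list()), "unpaired")
  expect_identical(rep1$per_image$dice, rep2$per_image$dice)
  expect_error(evaluate_dataset(file.path(td, "nope"), gd, list()),
               "validation error")
})
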