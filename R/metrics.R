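# Region-overlap metrics (mDice, mIoU) and dataset aggregation. Maps are
# (H, W) matrices here; predictions are probability maps in [0,1], ground
# truths binary. Empty-ground-truth convention: score 1 if the prediction
# is also empty after thresholding, else 0 (needed for synthetic edge
# cases; benchmark ground truths are never empty).

as_mask_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  if (length(d) == 4L && d[3] == 1L && d[4] == 1L) return(x[, , 1L, 1L])
  if (length(d) == 3L && d[3] == 1L) return(x[, , 1L])
  stop("expected a single-channel 2-D map")
}

dice_pair <- function(P, G) {
  sp <- sum(P); sg <- sum(G)
  if (sg == 0) return(if (sp == 0) 1 else 0)
  2 * sum(P * G) / (sp + sg)
}

iou_pair <- function(P, G) {
  sg <- sum(G)
  inter <- sum(P * G)
  union <- sum(P) + sg - inter
  if (sg == 0) return(if (sum(P) == 0) 1 else 0)
  inter / union
}

check_pair_lists <- function(preds, gts) {
  if (length(preds) != length(gts)) {
    stop(sprintf("validation error: %d predictions vs %d ground truths",
                 length(preds), length(gts)))
  }
  if (length(preds) == 0L) stop("validation error: empty input lists")
  for (i in seq_along(preds)) {
    if (!identical(dim(as_mask_matrix(preds[[i]])), dim(as_mask_matrix(gts[[i]])))) {
      stop(sprintf("validation error: pair %d shapes differ", i))
    }
  }
}

#' Mean Dice coefficient over a list of prediction/mask pairs
#'
#' @param preds list of probability maps (matrices in [0,1]).
#' @param gts list of binary masks.
#' @param threshold binarization threshold for the predictions.
#' @return list(per_image, mean).
#' @export
mean_dice <- function(preds, gts, threshold = 0.5) {
  check_pair_lists(preds, gts)
  per <- vapply(seq_along(preds), function(i) {
    P <- as_mask_matrix(preds[[i]]) >= threshold
    dice_pair(P + 0, as_mask_matrix(gts[[i]]))
  }, 0)
  list(per_image = per, mean = mean(per))
}

#' Mean IoU over a list of prediction/mask pairs
#' @inheritParams mean_dice
#' @return list(per_image, mean).
#' @export
mean_iou <- function(preds, gts, threshold = 0.5) {
  check_pair_lists(preds, gts)
  per <- vapply(seq_along(preds), function(i) {
    P <- as_mask_matrix(preds[[i]]) >= threshold
    iou_pair(P + 0, as_mask_matrix(gts[[i]]))
  }, 0)
  list(per_image = per, mean = mean(per))
}

#' Evaluate a directory of predictions against ground-truth masks
#'
#' Pairs files by stem, resizes each prediction bilinearly to its ground
#' truth's resolution, computes mDice, mIoU, weighted F-measure, S-measure
#' and E-measure per image, and aggregates by arithmetic mean. Unpaired
#' files are listed in the report and excluded with a warning.
#'
#' @param pred_dir directory of prediction PNGs (probability maps).
#' @param gt_dir directory of ground-truth mask PNGs.
#' @param config list: threshold (default 0.5), out_json / out_csv report
#'   paths (optional).
#' @return MetricReport: list(per_image data.frame, means, n, unpaired,
#'   emeasure_mode = "mean-of-continuous-map").
#' @export
evaluate_dataset <- function(pred_dir, gt_dir, config = list()) {
  threshold <- config$threshold %||% 0.5
  pf <- list.files(pred_dir, pattern = "\\.png$", full.names = TRUE)
  gf <- list.files(gt_dir, pattern = "\\.png$", full.names = TRUE)
  if (length(pf) == 0L || length(gf) == 0L) {
    stop("validation error: empty prediction or ground-truth directory")
  }
  ps <- sub("\\.png$", "", basename(pf))
  gs <- sub("\\.png$", "", basename(gf))
  common <- intersect(ps, gs)
  unpaired <- c(setdiff(ps, gs), setdiff(gs, ps))
  if (length(unpaired) > 0L) {
    warning(sprintf("excluding %d unpaired file(s): %s", length(unpaired),
                    paste(utils::head(unpaired, 5L), collapse = ", ")))
  }
  if (length(common) == 0L) stop("validation error: no paired files")
  common <- sort(common)
  rows <- lapply(common, function(st) {
    P <- read_probability_png(file.path(pred_dir, paste0(st, ".png")))
    G <- read_mask_png(file.path(gt_dir, paste0(st, ".png")))
    if (!identical(dim(P), dim(G))) {
      P <- resize_bilinear(as_feature_map(P), nrow(G), ncol(G))$y[, , 1L, 1L]
    }
    sm <- structure_measures(P, G)
    data.frame(stem = st,
               dice = dice_pair((P >= threshold) + 0, G),
               iou = iou_pair((P >= threshold) + 0, G),
               wfb = sm[["wfb"]], smeasure = sm[["smeasure"]],
               emeasure = sm[["emeasure"]])
  })
  per <- do.call(rbind, rows)
  means <- c(mDice = mean(per$dice), mIoU = mean(per$iou),
             wFb = mean(per$wfb), Salpha = mean(per$smeasure),
             Ephi = mean(per$emeasure))
  report <- list(per_image = per, means = as.list(means), n = nrow(per),
                 unpaired = unpaired, threshold = threshold,
                 emeasure_mode = "mean-of-continuous-map")
  if (!is.null(config$out_json)) {
    jsonlite::write_json(list(means = report$means, n = report$n,
                              unpaired = unpaired,
                              emeasure_mode = report$emeasure_mode,
                              per_image = per),
                         config$out_json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(config$out_csv)) {
    utils::write.csv(per, config$out_csv, row.names = FALSE)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
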