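# Ablation harness: train each architectural variant on the same phantom
# split across seeds, report mean +/- sd mDice/mIoU per variant.

#' Run the component/gating ablation
#'
#' @param base_config TrainConfig; its `variant` field is overridden per
#'   row.
#' @param variants subset of baseline, hbr, dsf, full, dsf_channel,
#'   dsf_spatial.
#' @param seeds integer vector of training seeds.
#' @param train_dir,val_dir dataset directories (same split for every run).
#' @param verbose print progress.
#' @return list(table data.frame (one row per variant, mean/sd mDice and
#'   mIoU), runs (per-run results)).
#' @export
run_ablation <- function(base_config, variants, seeds, train_dir, val_dir,
                         verbose = FALSE) {
  bad <- setdiff(variants, MODEL_VARIANTS)
  if (length(bad)) stop(sprintf("unknown variant(s): %s", paste(bad, collapse = ", ")))
  runs <- list()
  for (v in variants) for (s in seeds) {
    cfg <- base_config
    cfg$variant <- v
    cfg$seed <- as.integer(s)
    if (verbose) message(sprintf("ablation: variant=%s seed=%d", v, s))
    tr <- train_model(cfg, train_dir, val_dir, verbose = FALSE)
    ev <- evaluate_model(tr$model, val_dir, side = cfg$side)
    runs[[length(runs) + 1L]] <- list(variant = v, seed = s,
                                      mdice = ev$means$mDice,
                                      miou = ev$means$mIoU)
  }
  rd <- do.call(rbind, lapply(runs, function(r)
    data.frame(variant = r$variant, seed = r$seed,
               mdice = r$mdice, miou = r$miou)))
  tab <- do.call(rbind, lapply(variants, function(v) {
    sub <- rd[rd$variant == v, ]
    data.frame(variant = v, n_seeds = nrow(sub),
               mdice_mean = mean(sub$mdice),
               mdice_sd = if (nrow(sub) > 1L) stats::sd(sub$mdice) else 0,
               miou_mean = mean(sub$miou),
               miou_sd = if (nrow(sub) > 1L) stats::sd(sub$miou) else 0)
  }))
  list(table = tab, runs = rd)
}
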