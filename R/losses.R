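# Hybrid objective: structure loss (weighted BCE + weighted soft IoU) on
# every semantic head, Dice loss on the sparse edge branch, summed with unit
# weights. Pixel weights omega = 1 + 5*|meanpool31(G) - G| emphasize pixels
# whose label disagrees with their neighbourhood (boundary/hard pixels).
# All BCE terms are computed from logits in the numerically stable form.

check_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("dimension error: %s must share shape (%s vs %s)", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  }
}

#' Derive the binary edge target from a ground-truth mask
#'
#' Morphological gradient: 3x3 square dilation minus erosion with replicate
#' padding, yielding a 1-2 px contour band. An empty mask yields an empty
#' edge map; a full-frame mask has no interior contour (replicate padding
#' means the frame border does not fire).
#'
#' @param G binary mask, values in {0, 1}; (H, W) matrix or (H, W, 1, N).
#' @return binary edge map with G's shape.
#' @export
make_edge_target <- function(G) {
  was_matrix <- is.matrix(G)
  G <- as_feature_map(G)
  if (!all(G %in% c(0, 1))) stop("validation error: mask must be binary {0,1}")
  d <- dim(G)
  out <- array(0, d)
  for (n in seq_len(d[4])) for (cc in seq_len(d[3])) {
    m <- G[, , cc, n]
    out[, , cc, n] <- dilate3(m) - erode3(m)
  }
  if (was_matrix) out <- out[, , 1L, 1L]
  out
}

# omega weights per pixel: 1 + 5*|meanpool31(G) - G|
structure_weights <- function(G, win = 31L) {
  1 + 5 * abs(box_mean(G, win) - G)
}

wbce_impl <- function(logits, G, win = 31L, om = NULL) {
  logits <- as_feature_map(logits); G <- as_feature_map(G)
  check_same_shape(logits, G, "logits and mask")
  d <- dim(logits)
  N <- d[4]
  if (is.null(om)) om <- structure_weights(G, win)
  bce <- pmax(logits, 0) - logits * G + log1p(exp(-abs(logits)))
  hw <- d[1] * d[2] * d[3]
  om_m <- matrix(om, nrow = hw)
  s_om <- colSums(om_m)                      # per image
  vals <- colSums(matrix(om * bce, nrow = hw)) / s_om
  p <- sigmoid(logits)
  gl <- om * (p - G) / rep(s_om, each = hw) / N
  list(value = mean(vals), grad = gl)
}

wiou_impl <- function(logits, G, win = 31L, eps = 1e-6, om = NULL) {
  logits <- as_feature_map(logits); G <- as_feature_map(G)
  check_same_shape(logits, G, "logits and mask")
  d <- dim(logits)
  N <- d[4]
  hw <- d[1] * d[2] * d[3]
  if (is.null(om)) om <- structure_weights(G, win)
  p <- sigmoid(logits)
  inter <- colSums(matrix(om * p * G, nrow = hw))
  union <- colSums(matrix(om * (p + G - p * G), nrow = hw))
  vals <- 1 - (inter + eps) / (union + eps)
  iu <- rep(inter + eps, each = hw)
  uu <- rep(union + eps, each = hw)
  dLdp <- -(om * G * uu - iu * om * (1 - G)) / uu^2
  gl <- dLdp * p * (1 - p) / N
  list(value = mean(vals), grad = gl)
}

#' Weighted binary cross-entropy loss (hard-pixel weighting)
#' @param logits prediction logits; @param G binary mask (same shape).
#' @return scalar loss.
#' @export
weighted_bce <- function(logits, G) wbce_impl(logits, G)$value

#' Weighted soft-IoU loss
#' @param logits prediction logits; @param G binary mask (same shape).
#' @return scalar loss in [0, 1].
#' @export
weighted_iou_loss <- function(logits, G) wiou_impl(logits, G)$value

structure_loss_impl <- function(logits, G, om = NULL) {
  if (is.null(om)) om <- structure_weights(as_feature_map(G))
  a <- wbce_impl(logits, G, om = om)
  b <- wiou_impl(logits, G, om = om)
  list(value = a$value + b$value, grad = a$grad + b$grad)
}

#' Structure loss: weighted BCE + weighted IoU, direct sum
#' @param logits prediction logits; @param G binary mask.
#' @return scalar loss.
#' @export
structure_loss <- function(logits, G) structure_loss_impl(logits, G)$value

dice_impl <- function(E, Gedge, eps = 1e-5) {
  E <- as_feature_map(E); Gedge <- as_feature_map(Gedge)
  check_same_shape(E, Gedge, "edge prediction and edge target")
  d <- dim(E)
  N <- d[4]
  hw <- d[1] * d[2] * d[3]
  num <- 2 * colSums(matrix(E * Gedge, nrow = hw)) + eps
  den <- colSums(matrix(E, nrow = hw)) + colSums(matrix(Gedge, nrow = hw)) + eps
  vals <- 1 - num / den
  gn <- rep(num, each = hw); gd <- rep(den, each = hw)
  gE <- -(2 * Gedge * gd - gn) / gd^2 / N
  list(value = mean(vals), grad = gE)
}

#' Dice loss for the sparse edge branch
#'
#' 1 - (2*sum(E*Gedge) + eps) / (sum(E) + sum(Gedge) + eps), eps = 1e-5.
#' @param E predicted edge map in [0, 1]; @param Gedge binary contour.
#' @param eps smoothing factor.
#' @return scalar loss in [0, 1).
#' @export
dice_edge_loss <- function(E, Gedge, eps = 1e-5) dice_impl(E, Gedge, eps)$value

#' Total deep-supervised loss bundle
#'
#' Sums the structure loss over every semantic head the variant produces
#' (prediction, coarse, aux3, aux4) plus the edge Dice term when the edge
#' branch exists; unit weights throughout. Heads absent from a variant are
#' recorded as absent, not zero.
#'
#' @param outputs from [model_forward()].
#' @param G binary ground-truth mask at input resolution (H, W, 1, N).
#' @param Gedge binary edge target; defaults to [make_edge_target()] of G.
#' @return list(total, components (named numeric), grads (for training)).
#' @export
total_loss <- function(outputs, G, Gedge = NULL) {
  G <- as_feature_map(G)
  if (is.null(Gedge)) Gedge <- make_edge_target(G)
  Gedge <- as_feature_map(Gedge)
  comps <- c()
  grads <- list()
  heads <- outputs$loss_heads
  head_map <- list(prediction = outputs$prediction,
                   coarse = outputs$coarse_logits,
                   aux3 = outputs$aux3, aux4 = outputs$aux4)
  om <- structure_weights(G)   # depends only on G: shared across heads
  for (h in heads) {
    sl <- structure_loss_impl(head_map[[h]], G, om = om)
    comps[paste0("Lstruct_", h)] <- sl$value
    grads[[h]] <- sl$grad
  }
  if (!is.null(outputs$edge_pred)) {
    dl <- dice_impl(outputs$edge_pred, Gedge)
    comps["Ldice_edge"] <- dl$value
    grads[["edge_pred"]] <- dl$grad
  }
  list(total = sum(comps), components = comps, grads = grads)
}
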