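#' Loss weights for multi-task training
#'
#' The four loss terms (image-wide variable MSE, weighted localization BCE,
#' masked amplitude MSE, masked phase MSE) are combined as
#' `L = alpha1 L1 + alpha2 L2 + alpha3 L3 + alpha4 L4`. The positive-class
#' weight `omega` of the localization BCE counteracts the extreme class
#' imbalance of a single positive pixel in an 80 x 80 frame: with
#' `omega = 1` the optimum is an all-zero probability map.
#'
#' @param alpha Non-negative weights of the four terms.
#' @param omega Positive weight of the positive (scatterer) pixel class.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(alpha = c(1, 1, 10, 10), omega = default_omega()) {
  alpha <- as.numeric(alpha)
  stopifnot(length(alpha) == 4, all(is.finite(alpha)), all(alpha >= 0),
            any(alpha > 0), is.finite(omega), omega > 0)
  structure(list(alpha = alpha, omega = omega), class = "loss_weights")
}

#' Default positive-class weight
#'
#' One positive pixel per frame gives a positive:negative ratio of
#' `1 : (H*W - 1)`; weighting the positive class by `H*W / n_scatterers`
#' roughly equalizes the two classes' total contribution.
#'
#' @param height,width Frame size (px).
#' @param n_scatterers Expected positives per frame.
#' @return A scalar weight.
#' @export
default_omega <- function(height = 80, width = 80, n_scatterers = 1) {
  height * width / n_scatterers
}

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Image-wide variable regression loss (MSE)
#'
#' Mean over batch and components of the squared differences between
#' predicted and true normalized variable vectors.
#'
#' @param pred,true Numeric vectors or `B x k` matrices.
#' @return A non-negative scalar, zero iff `pred == true`.
#' @export
loss_imagewide <- function(pred, true) {
  pred <- rbind(pred); true <- rbind(true)
  if (!identical(dim(pred), dim(true))) stop("shape mismatch", call. = FALSE)
  mean((pred - true)^2)
}

#' Weighted binary cross-entropy with logits for sparse localization
#'
#' Per-pixel loss `-[omega y log(sigma(x)) + (1 - y) log(1 - sigma(x))]`,
#' averaged over all pixels and the batch, computed in the numerically
#' stable logit form (no overflow for logits up to +/- 1e3). `y` must be
#' binary.
#'
#' @param logit Numeric array of location logits.
#' @param target Binary array of the same shape.
#' @param omega Positive-class weight.
#' @return A non-negative scalar.
#' @export
loss_localization <- function(logit, target, omega = default_omega()) {
  if (!identical(dim(logit) %||% length(logit),
                 dim(target) %||% length(target))) {
    stop("shape mismatch", call. = FALSE)
  }
  if (!all(target %in% c(0, 1))) {
    stop("localization targets must be binary", call. = FALSE)
  }
  mean(omega * target * softplus(-logit) + (1 - target) * softplus(logit))
}

#' Masked mean-squared error for amplitude/phase maps
#'
#' `(1/N) * sum_batch sum_pixels mask * (pred - true)^2`: only the pixels on
#' the ground-truth scatterer locations contribute, so off-mask predictions
#' are unconstrained.
#'
#' @param pred,true Numeric matrices or `H x W x B` arrays.
#' @param mask Binary array of the same shape (the ground-truth probability
#'   map).
#' @param n Batch size `N`; defaults to the third array dimension (1 for a
#'   matrix).
#' @return A non-negative scalar.
#' @export
loss_masked <- function(pred, true, mask, n = NULL) {
  if (length(pred) != length(true) || length(pred) != length(mask)) {
    stop("shape mismatch between maps and mask", call. = FALSE)
  }
  if (!all(mask %in% c(0, 1))) stop("mask must be binary", call. = FALSE)
  if (is.null(n)) n <- if (length(dim(pred)) == 3) dim(pred)[3] else 1
  sum(mask * (pred - true)^2) / n
}

#' Weighted total loss
#'
#' @param l1,l2,l3,l4 Component losses.
#' @param weights A [loss_weights()].
#' @return `alpha1 l1 + alpha2 l2 + alpha3 l3 + alpha4 l4`.
#' @export
total_loss <- function(l1, l2, l3, l4, weights = loss_weights()) {
  sum(weights$alpha * c(l1, l2, l3, l4))
}

#' Rebalance loss weights from observed per-term averages
#'
#' Rescales each `alpha_i` so the weighted per-term averages agree (set to
#' the geometric mean of the observed weighted terms), mirroring the
#' iterative tuning in which weights are adjusted over calibration epochs
#' until the average losses are similar. Terms with zero average are left
#' unchanged.
#'
#' @param weights Current [loss_weights()].
#' @param avg_losses Observed average unweighted component losses
#'   (length 4).
#' @return A new [loss_weights()].
#' @export
balance_loss_weights <- function(weights, avg_losses) {
  stopifnot(length(avg_losses) == 4, all(avg_losses >= 0))
  contrib <- weights$alpha * avg_losses
  pos <- contrib > 0
  if (!any(pos)) return(weights)
  target <- exp(mean(log(contrib[pos])))
  alpha <- weights$alpha
  alpha[pos] <- target / avg_losses[pos]
  loss_weights(alpha = alpha, omega = weights$omega)
}
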