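#' Training configuration
#'
#' Adam with a single-cycle cosine-annealing learning-rate schedule (peak
#' `learning_rate` decaying to `lr_floor_frac * learning_rate`), seeded
#' shuffling and augmentation, and best-model tracking: the best model is
#' the last checkpoint after which no validation-loss improvement occurred.
#'
#' @param epochs Number of epochs (>= 1).
#' @param batch_size Mini-batch size N (>= 1).
#' @param learning_rate Peak Adam learning rate.
#' @param lr_floor_frac Cosine-annealing floor as a fraction of the peak.
#' @param beta1,beta2,epsilon Adam moment decay rates and stabilizer.
#' @param seed Seed for shuffling and on-the-fly augmentation.
#' @param weights A [loss_weights()].
#' @param augment Re-draw Gaussian blur + white noise for every training
#'   image each epoch (on-the-fly augmentation, using the generator ranges
#'   stored in the training dataset).
#' @param balance Rebalance `alpha` with [balance_loss_weights()] after the
#'   first epoch (calibration epoch).
#' @param verbose Print one line per epoch.
#' @return An object of class `training_config`.
#' @export
training_config <- function(epochs = 30, batch_size = 16,
                            learning_rate = 1e-3, lr_floor_frac = 1e-2,
                            beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                            seed = 1, weights = loss_weights(),
                            augment = TRUE, balance = FALSE,
                            verbose = FALSE) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            lr_floor_frac >= 0, lr_floor_frac <= 1)
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, lr_floor_frac = lr_floor_frac,
         beta1 = beta1, beta2 = beta2, epsilon = epsilon,
         seed = as.integer(seed), weights = weights,
         augment = isTRUE(augment), balance = isTRUE(balance),
         verbose = isTRUE(verbose)),
    class = "training_config"
  )
}

# cosine-annealed learning rate for epoch e of E (single cycle)
cosine_lr <- function(e, epochs, peak, floor_frac) {
  lo <- peak * floor_frac
  frac <- if (epochs > 1) (e - 1) / (epochs - 1) else 0
  lo + 0.5 * (peak - lo) * (1 + cos(pi * frac))
}

# assemble a batch: images (optionally re-augmented) and dense target cubes
# built from the sparse per-sample target pixels
make_batch <- function(ds, idx, augment) {
  H <- ds$height; W <- ds$width; B <- length(idx)
  x <- array(0, c(H, W, B))
  prob <- array(0, c(H, W, B))
  amp <- array(0, c(H, W, B))
  phs <- array(0, c(H, W, B))
  vars <- matrix(0, B, 6)
  for (j in seq_len(B)) {
    s <- ds$samples[[idx[j]]]
    img <- s$image
    if (augment) img <- augment_sampled(img, ds$ranges)$image
    x[, , j] <- img
    px <- s$pixels
    if (nrow(px) > 0) {
      ii <- cbind(px$y + 1L, px$x + 1L, j)
      prob[ii] <- 1
      amp[ii] <- px$amplitude
      phs[ii] <- px$phase
    }
    vars[j, ] <- s$variables
  }
  list(x = x, prob = prob, amp = amp, phase = phs, vars = vars)
}

# mean component losses over a dataset (no gradients, no augmentation)
dataset_losses <- function(params, ds, weights, batch_size = 32) {
  n <- length(ds$samples)
  acc <- c(L1 = 0, L2 = 0, L3 = 0, L4 = 0, total = 0)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    b <- make_batch(ds, idx, augment = FALSE)
    l <- cpp_ynet_loss(params, b$x, b$prob, b$amp, b$phase, b$vars,
                       weights$alpha, weights$omega, FALSE)
    acc <- acc + unlist(l[c("L1", "L2", "L3", "L4", "total")]) * length(idx)
  }
  acc / n
}

#' Train a Y-Net on a synthetic iPM dataset
#'
#' Minimizes the weighted four-term loss with Adam under a cosine-annealing
#' schedule, recording all four train and validation loss components per
#' epoch. Fully deterministic for a fixed `config$seed` on one platform.
#' Training aborts with an error naming the epoch if the loss becomes
#' non-finite.
#'
#' @param model A [build_ynet()] model.
#' @param train_ds Training [generate_dataset()] (typically generated with
#'   `augment = FALSE` and augmented on the fly here).
#' @param val_ds Optional validation dataset (typically generated with a
#'   fixed augmentation draw).
#' @param config A [training_config()].
#' @return An object of class `ynet_fit`: `model` (best weights), `final`
#'   (last-epoch weights), `history` (tibble), `best_epoch`, `config`,
#'   `weights` (possibly rebalanced).
#' @export
train_ynet <- function(model, train_ds, val_ds = NULL,
                       config = training_config()) {
  stopifnot(inherits(model, "ynet"), inherits(train_ds, "ipm_dataset"))
  n <- length(train_ds$samples)
  if (n == 0) stop("empty training dataset", call. = FALSE)
  params <- model$params
  weights <- config$weights
  mstate <- lapply(params, function(p) p * 0)
  vstate <- lapply(params, function(p) p * 0)
  t <- 0
  set.seed(config$seed)
  hist_rows <- vector("list", config$epochs)
  best <- list(loss = Inf, params = params, epoch = 0L)

  for (e in seq_len(config$epochs)) {
    lr <- cosine_lr(e, config$epochs, config$learning_rate,
                    config$lr_floor_frac)
    idx <- sample.int(n)
    tr_acc <- c(L1 = 0, L2 = 0, L3 = 0, L4 = 0, total = 0)
    for (start in seq(1, n, by = config$batch_size)) {
      bi <- idx[start:min(start + config$batch_size - 1, n)]
      b <- make_batch(train_ds, bi, augment = config$augment)
      res <- cpp_ynet_loss(params, b$x, b$prob, b$amp, b$phase, b$vars,
                           weights$alpha, weights$omega, TRUE)
      if (!is.finite(res$total)) {
        stop("training diverged (non-finite loss) at epoch ", e, call. = FALSE)
      }
      tr_acc <- tr_acc +
        unlist(res[c("L1", "L2", "L3", "L4", "total")]) * length(bi)
      g <- res$grads
      t <- t + 1
      bc1 <- 1 - config$beta1^t
      bc2 <- 1 - config$beta2^t
      for (nm in names(params)) {
        gi <- g[[nm]]
        mstate[[nm]] <- config$beta1 * mstate[[nm]] + (1 - config$beta1) * gi
        vstate[[nm]] <- config$beta2 * vstate[[nm]] + (1 - config$beta2) * gi^2
        params[[nm]] <- params[[nm]] -
          lr * (mstate[[nm]] / bc1) / (sqrt(vstate[[nm]] / bc2) + config$epsilon)
      }
    }
    tr <- tr_acc / n
    row <- tibble::tibble(
      epoch = e, lr = lr,
      train_L1 = tr[["L1"]], train_L2 = tr[["L2"]],
      train_L3 = tr[["L3"]], train_L4 = tr[["L4"]],
      train_total = tr[["total"]]
    )
    monitor <- tr[["total"]]
    if (!is.null(val_ds)) {
      vl <- dataset_losses(params, val_ds, weights)
      row$val_L1 <- vl[["L1"]]; row$val_L2 <- vl[["L2"]]
      row$val_L3 <- vl[["L3"]]; row$val_L4 <- vl[["L4"]]
      row$val_total <- vl[["total"]]
      monitor <- vl[["total"]]
    }
    if (monitor < best$loss) {
      best <- list(loss = monitor, params = params, epoch = e)
    }
    hist_rows[[e]] <- row
    if (config$verbose) {
      message(sprintf("epoch %3d  lr %.2e  train %.5f%s", e, lr,
                      tr[["total"]],
                      if (!is.null(val_ds))
                        sprintf("  val %.5f", row$val_total) else ""))
    }
    if (e == 1 && config$balance) {
      weights <- balance_loss_weights(weights,
                                      tr[c("L1", "L2", "L3", "L4")])
    }
  }

  best_model <- model
  best_model$params <- best$params
  final_model <- model
  final_model$params <- params
  structure(
    list(model = best_model, final = final_model,
         history = dplyr::bind_rows(hist_rows),
         best_epoch = best$epoch, config = config, weights = weights),
    class = "ynet_fit"
  )
}

#' @export
print.ynet_fit <- function(x, ...) {
  cat(sprintf("<ynet_fit> %d epochs, best epoch %d", nrow(x$history),
              x$best_epoch))
  if ("val_total" %in% names(x$history)) {
    cat(sprintf(" (val loss %.5f)", x$history$val_total[x$best_epoch]))
  }
  cat("\n")
  invisible(x)
}
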