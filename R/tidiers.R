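#' Tidy the training history of a fitted Y-Net
#'
#' One row per epoch, loss term and split, in long format suitable for
#' plotting or summarizing with dplyr.
#'
#' @param x A `ynet_fit`.
#' @param ... Unused.
#' @return A tibble with columns `epoch`, `lr`, `split` (train/val), `term`
#'   (L1, L2, L3, L4, total) and `loss`.
#' @method tidy ynet_fit
#' @export
tidy.ynet_fit <- function(x, ...) {
  h <- x$history
  terms <- c("L1", "L2", "L3", "L4", "total")
  rows <- list()
  for (split in c("train", "val")) {
    cols <- paste0(split, "_", terms)
    if (!all(cols %in% names(h))) next
    for (k in seq_along(terms)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        epoch = h$epoch, lr = h$lr, split = split, term = terms[k],
        loss = h[[cols[k]]]
      )
    }
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$epoch, .data$split, .data$term)
}

#' One-row summary of a fitted Y-Net
#'
#' @param x A `ynet_fit`.
#' @param ... Unused.
#' @return A one-row tibble: epochs trained, best epoch, final and best
#'   total losses, parameter count.
#' @method glance ynet_fit
#' @export
glance.ynet_fit <- function(x, ...) {
  h <- x$history
  has_val <- "val_total" %in% names(h)
  tibble::tibble(
    epochs = nrow(h),
    best_epoch = x$best_epoch,
    train_total = h$train_total[nrow(h)],
    val_total = if (has_val) h$val_total[nrow(h)] else NA_real_,
    best_loss = if (has_val) h$val_total[x$best_epoch]
                else h$train_total[x$best_epoch],
    n_parameters = n_parameters(x$model)
  )
}

#' Tidy per-truth localization results of an evaluation
#'
#' @param x A `ynet_eval` from [evaluate_ynet()].
#' @param ... Unused.
#' @return The per-truth results tibble (sample, truth and matched
#'   prediction coordinates, distance in nm, `within_limit`).
#' @method tidy ynet_eval
#' @export
tidy.ynet_eval <- function(x, ...) {
  x$results
}

#' One-row summary of an evaluation
#'
#' @param x A `ynet_eval`.
#' @param ... Unused.
#' @return A one-row tibble with accuracy, radius, error metrics.
#' @method glance ynet_eval
#' @export
glance.ynet_eval <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy,
    radius_nm = x$radius_nm,
    cutoff = x$cutoff,
    false_positive_rate = x$false_positive_rate,
    amp_rmse = x$amp_rmse,
    phase_rmse = x$phase_rmse
  )
}
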