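#' Localize scatterers on a probability map
#'
#' Thresholds the map at `cutoff`, then applies greedy non-maximum
#' suppression: candidates are visited in descending probability (row-major
#' pixel order breaking ties), and any candidate closer than
#' `min_separation` pixels to an already accepted peak is suppressed.
#' Deterministic; an empty result is valid.
#'
#' @param prob_map Numeric matrix of probabilities in (0, 1).
#' @param cutoff Detection threshold in (0, 1).
#' @param min_separation Suppression radius in pixels.
#' @return A tibble with 0-based pixel coordinates `x`, `y` and `prob`,
#'   ordered by decreasing probability.
#' @export
localize <- function(prob_map, cutoff = 0.5, min_separation = 2) {
  stopifnot(cutoff > 0, cutoff < 1)
  hits <- which(prob_map > cutoff)
  if (length(hits) == 0) {
    return(tibble::tibble(x = integer(), y = integer(), prob = numeric()))
  }
  H <- nrow(prob_map)
  y <- (hits - 1) %% H
  x <- (hits - 1) %/% H
  p <- prob_map[hits]
  ord <- order(-p, y, x)
  keep_x <- integer(0); keep_y <- integer(0); keep_p <- numeric(0)
  for (i in ord) {
    if (length(keep_x) == 0 ||
        all((keep_x - x[i])^2 + (keep_y - y[i])^2 >= min_separation^2)) {
      keep_x <- c(keep_x, x[i]); keep_y <- c(keep_y, y[i])
      keep_p <- c(keep_p, p[i])
    }
  }
  tibble::tibble(x = as.integer(keep_x), y = as.integer(keep_y), prob = keep_p)
}

#' Match predicted and true scatterer locations
#'
#' Greedy one-to-one matching: the globally closest (prediction, truth) pair
#' is matched first, both points are consumed, and the process repeats. A
#' truth is counted correct iff its matched prediction lies within `radius`.
#' Distances are center-to-center in physical nanometres
#' (`pixel_size * pixel distance`).
#'
#' @param predictions Tibble with `x`, `y` (pixel coords) of detections for
#'   one image.
#' @param truths Tibble with `x`, `y` of true locations for the same image.
#' @param radius Correctness radius in nm.
#' @param pixel_size Physical pixel size (nm/px) of this image.
#' @return A list: `results` (one row per truth: matched coords, distance
#'   in nm, `within_limit`), `false_positives` (unmatched predictions),
#'   `false_negatives` (unmatched truths).
#' @export
match_localizations <- function(predictions, truths, radius, pixel_size) {
  nt <- nrow(truths); np <- nrow(predictions)
  res <- tibble::tibble(
    truth_x = truths$x, truth_y = truths$y,
    pred_x = NA_real_, pred_y = NA_real_,
    distance = NA_real_, within_limit = FALSE
  )
  if (nt > 0 && np > 0) {
    d <- outer(seq_len(np), seq_len(nt), function(i, j) {
      pixel_size * sqrt((predictions$x[i] - truths$x[j])^2 +
                          (predictions$y[i] - truths$y[j])^2)
    })
    d <- matrix(d, np, nt)
    for (m in seq_len(min(np, nt))) {
      k <- arrayInd(which.min(d), dim(d))
      i <- k[1]; j <- k[2]
      if (!is.finite(d[i, j])) break
      res$pred_x[j] <- predictions$x[i]
      res$pred_y[j] <- predictions$y[i]
      res$distance[j] <- d[i, j]
      res$within_limit[j] <- d[i, j] <= radius
      d[i, ] <- Inf; d[, j] <- Inf
    }
  }
  list(
    results = res,
    false_positives = np - sum(!is.na(res$distance)),
    false_negatives = sum(is.na(res$distance))
  )
}

#' Localization accuracy within a matching radius
#'
#' Fraction of true scatterers whose greedily matched prediction lies within
#' `radius` (nm). Operates on parallel lists of per-image predictions and
#' truths.
#'
#' @param predictions List of per-image detection tibbles (`x`, `y`).
#' @param truths List of per-image truth tibbles (`x`, `y`).
#' @param radius Correctness radius in nm.
#' @param pixel_sizes Per-image physical pixel sizes (nm/px); recycled if
#'   scalar.
#' @return A list: `accuracy` in `[0, 1]`, `results` (per-truth tibble with
#'   a `sample` column), `false_positive_rate` (mean unmatched predictions
#'   per image).
#' @export
localization_accuracy <- function(predictions, truths, radius, pixel_sizes) {
  stopifnot(length(predictions) == length(truths))
  pixel_sizes <- rep_len(pixel_sizes, length(truths))
  rows <- vector("list", length(truths))
  fp <- 0
  for (i in seq_along(truths)) {
    m <- match_localizations(predictions[[i]], truths[[i]], radius,
                             pixel_sizes[i])
    rows[[i]] <- dplyr::mutate(m$results, sample = i, .before = 1)
    fp <- fp + m$false_positives
  }
  results <- dplyr::bind_rows(rows)
  list(
    accuracy = if (nrow(results) > 0) mean(results$within_limit) else NA_real_,
    results = results,
    false_positive_rate = fp / length(truths)
  )
}

#' Evaluate a trained Y-Net on a dataset
#'
#' Runs the forward pass over every sample, localizes scatterers on the
#' probability maps (cutoff + non-maximum suppression), matches them to the
#' encoded ground-truth pixels, and reports: localization accuracy within
#' the diffraction radius, amplitude and phase RMSE at matched pixels,
#' per-variable regression RMSE in physical units, and the false-positive
#' rate per image.
#'
#' @param model A `ynet` or `ynet_fit`.
#' @param ds An [generate_dataset()] dataset.
#' @param cutoff Probability cutoff for [localize()].
#' @param min_separation Suppression radius (px); default: the diffraction
#'   radius converted with each sample's true pixel size.
#' @param batch_size Forward-pass batch size.
#' @return An object of class `ynet_eval`: list with `accuracy`,
#'   `false_positive_rate`, `amp_rmse`, `phase_rmse`, `variable_rmse`
#'   (tibble, physical units), `results` (per-truth tibble), `radius_nm`.
#' @export
evaluate_ynet <- function(model, ds, cutoff = 0.5, min_separation = NULL,
                          batch_size = 32) {
  model <- as_ynet(model)
  n <- length(ds$samples)
  radius <- diffraction_radius(ds$samples[[1]]$config)
  preds <- vector("list", n)
  truths <- vector("list", n)
  ps <- numeric(n)
  amp_err2 <- numeric(0)
  phase_err2 <- numeric(0)
  var_err <- matrix(0, 0, 6)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    b <- make_batch(ds, idx, augment = FALSE)
    out <- ynet_forward(model, b$x)
    for (j in seq_along(idx)) {
      i <- idx[j]
      s <- ds$samples[[i]]
      ps[i] <- s$config$pixel_size
      sep <- if (is.null(min_separation)) radius / ps[i] else min_separation
      det <- localize(out$prob[, , j], cutoff, sep)
      preds[[i]] <- det
      truths[[i]] <- s$pixels
      m <- match_localizations(det, s$pixels, radius, ps[i])
      ok <- !is.na(m$results$distance)
      if (any(ok)) {
        ii <- cbind(round(m$results$pred_y[ok]) + 1L,
                    round(m$results$pred_x[ok]) + 1L)
        amp_err2 <- c(amp_err2,
                      (out$amp[, , j][ii] - s$pixels$amplitude[ok])^2)
        phase_err2 <- c(phase_err2,
                        wrap_phase(out$phase[, , j][ii] -
                                     s$pixels$phase[ok])^2)
      }
      var_err <- rbind(var_err, out$vars[j, ] - s$variables)
    }
  }
  acc <- localization_accuracy(preds, truths, radius, ps)
  widths <- vapply(variable_names(), function(nm) diff(ds$ranges[[nm]]),
                   numeric(1))
  var_rmse <- sqrt(colMeans(var_err^2)) * widths
  structure(
    list(
      accuracy = acc$accuracy,
      false_positive_rate = acc$false_positive_rate,
      amp_rmse = if (length(amp_err2)) sqrt(mean(amp_err2)) else NA_real_,
      phase_rmse = if (length(phase_err2)) sqrt(mean(phase_err2)) else NA_real_,
      variable_rmse = tibble::tibble(variable = variable_names(),
                                     rmse = var_rmse,
                                     normalized_rmse = sqrt(colMeans(var_err^2))),
      results = acc$results,
      radius_nm = radius,
      cutoff = cutoff
    ),
    class = "ynet_eval"
  )
}

#' @export
print.ynet_eval <- function(x, ...) {
  cat(sprintf(
    "<ynet_eval> accuracy %.3f within %.1f nm | FP/image %.3f | amp RMSE %s | phase RMSE %s\n",
    x$accuracy, x$radius_nm, x$false_positive_rate,
    formatC(x$amp_rmse, digits = 4, format = "g"),
    formatC(x$phase_rmse, digits = 4, format = "g")
  ))
  invisible(x)
}
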