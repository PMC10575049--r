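#' Decode a network output into a scene
#'
#' Inverts the target encoding: scatterer locations come from the cutoff +
#' non-maximum-suppression localization of the probability map, their
#' amplitude and phase are read off the amplitude/phase channels at those
#' pixels (phase wrapped to [-pi, pi)), and the optical configuration is
#' de-normalized from the 6-vector regression output (clipped to [0, 1]
#' first) through the inverse of the generator's min-max map. No detections
#' yield a valid empty scene.
#'
#' @param output A `ynet_output` from [ynet_forward()].
#' @param ranges The [sampling_ranges()] used in training.
#' @param cutoff Probability cutoff.
#' @param min_separation Suppression radius (px); default: diffraction
#'   radius at the decoded pixel size.
#' @param base_config Template config for material constants.
#' @param index Which sample of the batch to decode.
#' @return A list with `config` ([optical_config()]) and `scene`
#'   ([scatterers()] tibble).
#' @export
output_to_scene <- function(output, ranges, cutoff = 0.5,
                            min_separation = NULL,
                            base_config = optical_config(), index = 1) {
  cfg <- denormalize_variables(output$vars[index, ], ranges, base_config)
  if (is.null(min_separation)) {
    min_separation <- diffraction_radius(cfg) / cfg$pixel_size
  }
  det <- localize(output$prob[, , index], cutoff, min_separation)
  amp_map <- output$amp[, , index]
  phase_map <- output$phase[, , index]
  scene <- if (nrow(det) == 0) {
    scatterers()
  } else {
    ii <- cbind(det$y + 1L, det$x + 1L)
    scatterers(
      x = det$x, y = det$y,
      amplitude = pmax(amp_map[ii], 0),
      phase = wrap_phase(phase_map[ii])
    )
  }
  list(config = cfg, scene = scene)
}

#' Noise-free reconstruction from a network output
#'
#' Re-renders the decoded scene with the physics simulator on the training
#' normalization scale: the reconstruction depends only on the decoded
#' parameters, never on the input pixels. When the input image is supplied,
#' pixelwise Pearson correlation and the RMS difference normalized by the
#' input RMS are reported (both `NA` for an empty scene or constant input).
#'
#' @inheritParams output_to_scene
#' @param mode Render mode; the generator default `"linearized"` matches the
#'   training data.
#' @param input Optional input image (normalized) for similarity metrics.
#' @return An object of class `ipm_reconstruction`: list with `image`,
#'   `config`, `scene`, `correlation`, `nrms`, `input`.
#' @export
reconstruct <- function(output, ranges, cutoff = 0.5, min_separation = NULL,
                        mode = "linearized", input = NULL,
                        base_config = optical_config(), index = 1) {
  dims <- dim(output$prob)
  sc <- output_to_scene(output, ranges, cutoff, min_separation, base_config,
                        index)
  img <- render_scene(sc$config, sc$scene, dims[1], dims[2], mode) /
    ranges$intensity_scale
  correlation <- nrms <- NA_real_
  if (!is.null(input) && nrow(sc$scene) > 0) {
    if (stats::sd(input) > 0 && stats::sd(img) > 0) {
      correlation <- stats::cor(as.vector(img), as.vector(input))
    }
    rms_in <- sqrt(mean(input^2))
    if (rms_in > 0) nrms <- sqrt(mean((img - input)^2)) / rms_in
  }
  structure(
    list(image = img, config = sc$config, scene = sc$scene,
         correlation = correlation, nrms = nrms, input = input),
    class = "ipm_reconstruction"
  )
}

#' @export
print.ipm_reconstruction <- function(x, ...) {
  cat(sprintf("<ipm_reconstruction> %d scatterer(s)", nrow(x$scene)))
  if (!is.na(x$correlation)) {
    cat(sprintf(" | correlation %.3f, nRMS %.3f", x$correlation, x$nrms))
  }
  cat("\n")
  invisible(x)
}

# reflective (mirror) padding to the next multiple of 2^depth
pad_reflect <- function(img, multiple) {
  H <- nrow(img); W <- ncol(img)
  H2 <- ceiling(H / multiple) * multiple
  W2 <- ceiling(W / multiple) * multiple
  if (H2 > 2 * H || W2 > 2 * W) {
    stop("image too small to pad by reflection to a multiple of ", multiple,
         call. = FALSE)
  }
  out <- matrix(0, H2, W2)
  ry <- c(seq_len(H), rev(seq_len(H)))[seq_len(H2)]
  rx <- c(seq_len(W), rev(seq_len(W)))[seq_len(W2)]
  out[] <- img[ry, rx]
  out
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    "tif" = , "tiff" = tiff::readTIFF(path, all = FALSE),
    "png" = png::readPNG(path),
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  if (length(dim(img)) == 3) {
    if (dim(img)[3] > 1) {
      stop("expected a single-channel image, got ", dim(img)[3], " channels",
           call. = FALSE)
    }
    img <- img[, , 1]
  }
  img
}

#' Analyze an experimental iPM crop
#'
#' Reads a single-channel TIFF/PNG (or takes a matrix), min-max rescales it
#' to the training normalization range [-1, 1] (the rescaling rule is
#' recorded in the report), pads it by reflection to a size divisible by
#' `2^depth`, runs the forward pass, crops the outputs back, and
#' reconstructs a noise-free image from the decoded scene. Qualitative use:
#' experimental crops carry no ground truth.
#'
#' @param image File path or numeric matrix.
#' @param model A trained `ynet` or `ynet_fit`.
#' @param ranges The training [sampling_ranges()].
#' @param cutoff Probability cutoff.
#' @param base_config Template config for material constants.
#' @return An `ipm_reconstruction` with an extra `rescale` element
#'   (`list(min, max)` of the raw input).
#' @export
analyze_experimental <- function(image, model, ranges = sampling_ranges(),
                                 cutoff = 0.5,
                                 base_config = optical_config()) {
  raw <- if (is.character(image)) read_image_file(image) else as.matrix(image)
  lo <- min(raw); hi <- max(raw)
  scaled <- if (hi > lo) 2 * (raw - lo) / (hi - lo) - 1 else raw * 0
  model <- as_ynet(model)
  mult <- 2^model$spec$depth
  H <- nrow(scaled); W <- ncol(scaled)
  padded <- pad_reflect(scaled, mult)
  out <- ynet_forward(model, padded)
  crop <- function(a) a[seq_len(H), seq_len(W), , drop = FALSE]
  out$logit <- crop(out$logit); out$amp <- crop(out$amp)
  out$phase <- crop(out$phase); out$prob <- crop(out$prob)
  rec <- reconstruct(out, ranges, cutoff, mode = "linearized",
                     input = scaled, base_config = base_config)
  rec$rescale <- list(min = lo, max = hi)
  rec
}

#' Detect scatterers across a large field of view ("crop and go")
#'
#' Splits a frame into overlapping square crops of the network's native
#' size, localizes scatterers in each crop, maps detections back to global
#' coordinates and merges them by non-maximum suppression. This extends the
#' single-frame model to wide fields containing many objects.
#'
#' @param image Numeric matrix (any size at least the crop size).
#' @param model A trained `ynet` or `ynet_fit`.
#' @param crop_size Native frame size (px).
#' @param stride Crop stride (px); overlap is `crop_size - stride`.
#' @param cutoff Probability cutoff.
#' @param min_separation Merge radius in px.
#' @return A tibble of global detections (`x`, `y`, `prob`).
#' @export
crop_and_go <- function(image, model, crop_size = 80, stride = 40,
                        cutoff = 0.5, min_separation = 3) {
  H <- nrow(image); W <- ncol(image)
  stopifnot(H >= crop_size, W >= crop_size)
  starts <- function(total) {
    s <- seq(0, max(total - crop_size, 0), by = stride)
    unique(c(s, total - crop_size))
  }
  model <- as_ynet(model)
  dets <- list()
  for (oy in starts(H)) {
    for (ox in starts(W)) {
      crop <- image[oy + seq_len(crop_size), ox + seq_len(crop_size)]
      out <- ynet_forward(model, crop)
      d <- localize(out$prob[, , 1], cutoff, min_separation)
      if (nrow(d) > 0) {
        d$x <- d$x + ox; d$y <- d$y + oy
        dets[[length(dets) + 1]] <- d
      }
    }
  }
  if (length(dets) == 0) {
    return(tibble::tibble(x = integer(), y = integer(), prob = numeric()))
  }
  all_d <- dplyr::bind_rows(dets)
  # merge duplicated detections from overlapping crops: greedy NMS again
  ord <- order(-all_d$prob, all_d$y, all_d$x)
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0 ||
        all((all_d$x[keep] - all_d$x[i])^2 +
              (all_d$y[keep] - all_d$y[i])^2 >= min_separation^2)) {
      keep <- c(keep, i)
    }
  }
  all_d[keep, ]
}
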