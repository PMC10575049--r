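#' Sampling ranges for the synthetic iPM data generator
#'
#' Declares the closed intervals from which the generator draws the six
#' image-wide optical variables, the scatterer properties, and the
#' augmentation strengths. These defaults ARE the study conditions of the
#' generator: they bracket the printed experimental constants of the
#' microscope (93 nm pixels, 50 nm gold film, 633 nm HeNe, SPR dip angle for
#' gold/air behind a 1.515 coupling medium) and keep the object wave weak
#' enough (`max |E_O| <= 0.1 |E_R|`) that the linearized image model holds.
#'
#' @param pixel_size Interval (nm/px).
#' @param propagation_angle Interval (rad).
#' @param incident_angle Interval (rad); default SPR dip angle +/- 2 degrees.
#' @param bfp_offset Interval (nm). Positive offsets attenuate the object
#'   wave as `exp(kappa_z z)`; the default upper bound 600 nm keeps the
#'   weakest scatterer detectable (attenuation >= 0.16).
#' @param film_thickness Interval (nm).
#' @param phase_offset Interval (rad).
#' @param amplitude Scatterer amplitude interval (dimensionless).
#' @param n_scatterers Integer interval for the per-image scatterer count
#'   (default exactly 1: isolated patterns, as the loss design assumes).
#' @param margin Interior margin (px) within which scatterer centres are
#'   drawn so fringes fit in-frame.
#' @param blur_sigma Gaussian blur sigma interval (px).
#' @param noise_sigma Additive white-noise sigma interval (normalized
#'   intensity units).
#' @param intensity_scale Fixed global normalization divisor for rendered
#'   images. The linearized image is bounded by `2 * max(amplitude)`, so the
#'   default `2 * amplitude[2]` maps every clean image into [-1, 1] while
#'   keeping the scatterer amplitude learnable (a per-image max would erase
#'   it).
#' @return An object of class `sampling_ranges` (a named list).
#' @export
sampling_ranges <- function(pixel_size = c(85, 100),
                            propagation_angle = c(-15, 15) * pi / 180,
                            incident_angle = spr_angle() + c(-2, 2) * pi / 180,
                            bfp_offset = c(0, 600),
                            film_thickness = c(45, 55),
                            phase_offset = c(-pi, pi),
                            amplitude = c(0.01, 0.1),
                            n_scatterers = c(1, 1),
                            margin = 8,
                            blur_sigma = c(0.5, 1.5),
                            noise_sigma = c(0.01, 0.05),
                            intensity_scale = 2 * amplitude[2]) {
  rg <- structure(
    list(
      pixel_size = as.numeric(pixel_size),
      propagation_angle = as.numeric(propagation_angle),
      incident_angle = as.numeric(incident_angle),
      bfp_offset = as.numeric(bfp_offset),
      film_thickness = as.numeric(film_thickness),
      phase_offset = as.numeric(phase_offset),
      amplitude = as.numeric(amplitude),
      n_scatterers = as.integer(round(n_scatterers)),
      margin = as.numeric(margin),
      blur_sigma = as.numeric(blur_sigma),
      noise_sigma = as.numeric(noise_sigma),
      intensity_scale = as.numeric(intensity_scale)
    ),
    class = "sampling_ranges"
  )
  for (nm in c(names(rg)[!names(rg) %in% c("margin", "intensity_scale")])) {
    iv <- rg[[nm]]
    if (length(iv) != 2 || any(!is.finite(iv)) || iv[2] < iv[1]) {
      stop("invalid interval for ", nm, call. = FALSE)
    }
  }
  stopifnot(rg$amplitude[1] >= 0, rg$intensity_scale > 0,
            all(rg$blur_sigma >= 0), all(rg$noise_sigma >= 0),
            rg$n_scatterers[1] >= 0)
  rg
}

#' Names and canonical order of the six image-wide variables
#' @return Character vector of length 6.
#' @export
variable_names <- function() {
  c("pixel_size", "propagation_angle", "incident_angle",
    "bfp_offset", "film_thickness", "phase_offset")
}

#' Min-max normalize the six image-wide variables of a config
#'
#' Maps each variable to [0, 1] using its sampling interval, in the fixed
#' order `pixel_size, propagation_angle, incident_angle, bfp_offset,
#' film_thickness, phase_offset`. A degenerate (fixed) interval maps to 0.5.
#' The map is invertible per component via [denormalize_variables()].
#'
#' @param config An [optical_config()].
#' @param ranges A [sampling_ranges()].
#' @return A named numeric vector of length 6 in [0, 1].
#' @export
normalize_variables <- function(config, ranges) {
  vapply(variable_names(), function(nm) {
    iv <- ranges[[nm]]
    w <- iv[2] - iv[1]
    if (w == 0) 0.5 else (config[[nm]] - iv[1]) / w
  }, numeric(1))
}

#' Invert the variable normalization into an optical configuration
#'
#' @param v Numeric vector of length 6 in [0, 1] (clipped to [0, 1] first).
#' @param ranges A [sampling_ranges()].
#' @param base_config Template [optical_config()] supplying wavelength,
#'   materials and numerical aperture.
#' @return An [optical_config()].
#' @export
denormalize_variables <- function(v, ranges, base_config = optical_config()) {
  stopifnot(length(v) == 6)
  v <- pmin(pmax(as.numeric(v), 0), 1)
  vals <- purrr::map2_dbl(variable_names(), v, function(nm, vi) {
    iv <- ranges[[nm]]
    iv[1] + vi * (iv[2] - iv[1])
  })
  names(vals) <- variable_names()
  optical_config(
    wavelength = base_config$wavelength,
    incident_angle = vals[["incident_angle"]],
    propagation_angle = vals[["propagation_angle"]],
    pixel_size = vals[["pixel_size"]],
    bfp_offset = vals[["bfp_offset"]],
    film_thickness = vals[["film_thickness"]],
    phase_offset = vals[["phase_offset"]],
    metal_permittivity = base_config$metal_permittivity,
    dielectric_index = base_config$dielectric_index,
    numerical_aperture = base_config$numerical_aperture
  )
}

#' Draw a random optical configuration
#'
#' Each of the six image-wide variables is drawn independently and uniformly
#' from its interval in `ranges`; material constants come from
#' `base_config`. Uses R's global RNG stream (seed with `set.seed()` for
#' reproducibility).
#'
#' @inheritParams denormalize_variables
#' @return An [optical_config()].
#' @export
sample_config <- function(ranges, base_config = optical_config()) {
  draws <- vapply(variable_names(), function(nm) {
    iv <- ranges[[nm]]
    if (iv[2] > iv[1]) stats::runif(1, iv[1], iv[2]) else iv[1]
  }, numeric(1))
  optical_config(
    wavelength = base_config$wavelength,
    incident_angle = draws[["incident_angle"]],
    propagation_angle = draws[["propagation_angle"]],
    pixel_size = draws[["pixel_size"]],
    bfp_offset = draws[["bfp_offset"]],
    film_thickness = draws[["film_thickness"]],
    phase_offset = draws[["phase_offset"]],
    metal_permittivity = base_config$metal_permittivity,
    dielectric_index = base_config$dielectric_index,
    numerical_aperture = base_config$numerical_aperture
  )
}

#' Draw a random scene of scatterers
#'
#' Scatterer count is uniform over the integer interval in `ranges`;
#' locations are uniform over the interior of the frame (a `margin`-pixel
#' border is excluded so the fringe pattern centre stays in-frame); phases
#' are uniform on [-pi, pi); amplitudes uniform over their interval.
#'
#' @param ranges A [sampling_ranges()].
#' @param height,width Frame size in pixels.
#' @return A [scatterers()] tibble.
#' @export
sample_scatterers <- function(ranges, height, width) {
  m <- ranges$margin
  if (m >= height / 2 || m >= width / 2) {
    stop("margin must be smaller than half the frame", call. = FALSE)
  }
  lo <- ranges$n_scatterers[1]
  hi <- ranges$n_scatterers[2]
  count <- if (hi > lo) lo + floor(stats::runif(1) * (hi - lo + 1)) else lo
  count <- min(count, hi)
  scatterers(
    x = stats::runif(count, m, width - m),
    y = stats::runif(count, m, height - m),
    amplitude = stats::runif(count, ranges$amplitude[1], ranges$amplitude[2]),
    phase = stats::runif(count, -pi, pi)
  )
}

#' Encode a scene into supervised target maps
#'
#' Each scatterer's continuous location is rounded to the nearest pixel
#' (half-up). The probability map gets a 1 at that pixel, the amplitude and
#' phase maps carry the scatterer's amplitude and phase there, and all three
#' maps are zero elsewhere. The six image-wide variables are min-max
#' normalized to [0, 1]. Two scatterers rounding to the same pixel raise a
#' collision condition (`ipmnet_collision`), on which the generator redraws
#' the sample.
#'
#' @param scene A [scatterers()] tibble.
#' @param height,width Frame size (px).
#' @param ranges A [sampling_ranges()].
#' @param config The [optical_config()] the scene was rendered with.
#' @return A list with `prob`, `amp`, `phase` (H x W matrices), `variables`
#'   (length-6 vector in [0, 1]) and `pixels` (tibble of the rounded
#'   locations).
#' @export
encode_targets <- function(scene, height, width, ranges, config) {
  px <- pmin(floor(scene$x + 0.5), width - 1)
  py <- pmin(floor(scene$y + 0.5), height - 1)
  if (anyDuplicated(cbind(px, py))) {
    stop(structure(
      class = c("ipmnet_collision", "error", "condition"),
      list(message = "two scatterers round to the same pixel", call = NULL)
    ))
  }
  prob <- amp <- phs <- matrix(0, height, width)
  idx <- cbind(py + 1L, px + 1L)
  prob[idx] <- 1
  amp[idx] <- scene$amplitude
  phs[idx] <- scene$phase
  list(
    prob = prob, amp = amp, phase = phs,
    variables = normalize_variables(config, ranges),
    pixels = tibble::tibble(x = px, y = py,
                            amplitude = scene$amplitude, phase = scene$phase)
  )
}

# banded circulant matrix implementing 1-D Gaussian convolution with
# circular boundary; rows sum to 1 exactly, so the blur conserves the image
# mean to machine precision
gaussian_circulant <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- min(ceiling(4 * sigma), n - 1)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  M <- matrix(0, n, n)
  for (o in -r:r) {
    idx <- ((0:(n - 1)) + o) %% n
    pos <- cbind(1:n, idx + 1)
    M[pos] <- M[pos] + k[o + r + 1]
  }
  M
}

#' Augment an image with Gaussian blur and white noise
#'
#' Applies a separable Gaussian blur (circular boundary, exactly
#' mean-conserving) with the given sigma, then adds i.i.d. zero-mean
#' Gaussian noise. `sigma = 0` for either step is an exact no-op for that
#' step. Draws come from R's global RNG stream.
#'
#' @param image Numeric matrix.
#' @param blur_sigma Blur standard deviation in pixels (scalar, >= 0).
#' @param noise_sigma Noise standard deviation in intensity units (>= 0).
#' @return The augmented matrix.
#' @export
augment_image <- function(image, blur_sigma = 0, noise_sigma = 0) {
  stopifnot(blur_sigma >= 0, noise_sigma >= 0)
  out <- image
  if (blur_sigma > 0) {
    out <- gaussian_circulant(nrow(out), blur_sigma) %*% out %*%
      gaussian_circulant(ncol(out), blur_sigma)
  }
  if (noise_sigma > 0) {
    out <- out + matrix(stats::rnorm(length(out), sd = noise_sigma),
                        nrow(out), ncol(out))
  }
  attr(out, "pixel_size") <- attr(image, "pixel_size")
  out
}

# draw augmentation strengths from their ranges and apply
augment_sampled <- function(image, ranges) {
  bs <- stats::runif(1, ranges$blur_sigma[1], ranges$blur_sigma[2])
  ns <- stats::runif(1, ranges$noise_sigma[1], ranges$noise_sigma[2])
  list(image = augment_image(image, bs, ns), blur_sigma = bs, noise_sigma = ns)
}

#' Generate a synthetic iPM dataset
#'
#' Draws `n` independent samples: a random optical configuration, a random
#' scene, the rendered interference image normalized by the fixed
#' `intensity_scale`, the single-pixel target maps, and the normalized
#' variable vector. With `augment = TRUE` each image additionally receives a
#' fixed draw of Gaussian blur and white noise (use `augment = FALSE` for
#' training sets that are augmented on the fly each epoch). Fully
#' deterministic given `seed`.
#'
#' @param n Number of samples.
#' @param ranges A [sampling_ranges()].
#' @param seed Integer seed.
#' @param height,width Frame size (default 80 x 80, the localization frame).
#' @param mode Render mode, see [ipm_intensity()]; the generator default is
#'   `"linearized"`, matching the background-subtracted image model.
#' @param augment Apply a fixed augmentation draw to each image.
#' @param base_config Template config for materials.
#' @param out_dir Optional directory: writes per-sample TIFF (image + three
#'   target pages) and sidecar JSON plus a `manifest.json`.
#' @param max_retries Redraws allowed on pixel collisions.
#' @return An object of class `ipm_dataset`: list with `samples` (list of
#'   per-sample lists), `manifest` (tibble), `ranges`, `seed`, `height`,
#'   `width`, `mode`.
#' @examples
#' ds <- generate_dataset(3, sampling_ranges(), seed = 1)
#' ds$manifest
#' @export
generate_dataset <- function(n, ranges = sampling_ranges(), seed = 1,
                             height = 80, width = 80,
                             mode = "linearized", augment = TRUE,
                             base_config = optical_config(),
                             out_dir = NULL, max_retries = 20) {
  stopifnot(n >= 1)
  set.seed(seed)
  samples <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    for (attempt in seq_len(max_retries)) {
      cfg <- sample_config(ranges, base_config)
      scene <- sample_scatterers(ranges, height, width)
      tg <- tryCatch(encode_targets(scene, height, width, ranges, cfg),
                     ipmnet_collision = function(e) NULL)
      if (!is.null(tg)) break
      if (attempt == max_retries) stop("collision retries exhausted", call. = FALSE)
    }
    img <- render_scene(cfg, scene, height, width, mode) / ranges$intensity_scale
    # augmentation draws are consumed whether or not they are applied, so a
    # toggled `augment` flag leaves every scene and config unchanged
    bs <- stats::runif(1, ranges$blur_sigma[1], ranges$blur_sigma[2])
    ns <- stats::runif(1, ranges$noise_sigma[1], ranges$noise_sigma[2])
    noise <- matrix(stats::rnorm(height * width), height, width)
    if (augment) {
      img <- augment_image(img, bs, 0) + ns * noise
    } else {
      bs <- ns <- 0
    }
    samples[[i]] <- list(
      image = img, prob = tg$prob, amp = tg$amp, phase = tg$phase,
      variables = tg$variables, pixels = tg$pixels,
      config = cfg, scene = scene
    )
    rows[[i]] <- tibble::tibble(
      sample = i, n_scatterers = nrow(scene),
      blur_sigma = bs, noise_sigma = ns,
      !!!stats::setNames(as.list(tg$variables), variable_names())
    )
  }
  ds <- structure(
    list(samples = samples, manifest = dplyr::bind_rows(rows),
         ranges = ranges, seed = seed, height = height, width = width,
         mode = mode, augmented = augment),
    class = "ipm_dataset"
  )
  if (!is.null(out_dir)) write_dataset(ds, out_dir)
  ds
}

#' @export
print.ipm_dataset <- function(x, ...) {
  cat(sprintf("<ipm_dataset> %d samples, %dx%d px, mode=%s, seed=%d%s\n",
              length(x$samples), x$height, x$width, x$mode, x$seed,
              if (x$augmented) ", augmented" else ""))
  invisible(x)
}

# TIFF stores (image, prob, amp, phase) as pages mapped into [0,1] by
# value/4 + 1/2 (recorded in the sidecar); JSON stores the exact targets.
write_dataset <- function(ds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(ds$samples))
  for (i in seq_along(ds$samples)) {
    s <- ds$samples[[i]]
    stem <- sprintf("sample_%05d", i)
    pages <- lapply(list(s$image, s$prob, s$amp, s$phase),
                    function(m) pmin(pmax(unclass(m) / 4 + 0.5, 0), 1))
    tiff::writeTIFF(pages, file.path(out_dir, paste0(stem, ".tif")),
                    bits.per.sample = 32L)
    side <- list(
      transform = list(scale = 4, offset = -0.5),
      variables = as.list(s$variables),
      pixels = s$pixels,
      scene = s$scene,
      config = config_to_list(s$config)
    )
    jsonlite::write_json(side, file.path(out_dir, paste0(stem, ".json")),
                         auto_unbox = TRUE, digits = NA)
    files[i] <- paste0(stem, ".tif")
  }
  jsonlite::write_json(
    list(n = length(ds$samples), seed = ds$seed, height = ds$height,
         width = ds$width, mode = ds$mode, augmented = ds$augmented,
         ranges = unclass(ds$ranges), files = files),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}

config_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$metal_permittivity <- c(Re(cfg$metal_permittivity), Im(cfg$metal_permittivity))
  out
}

list_to_config <- function(lst) {
  em <- lst$metal_permittivity
  do.call(optical_config, c(
    lst[setdiff(names(lst), "metal_permittivity")],
    list(metal_permittivity = complex(real = em[1], imaginary = em[2]))
  ))
}
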