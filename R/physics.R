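#' Scatterer table constructor
#'
#' A scene is a tibble with one row per point scatterer: continuous pixel
#' coordinates `x` (column) and `y` (row), both 0-based in the image frame,
#' a dimensionless scattering amplitude `amplitude >= 0` (kept well below 1
#' so the cross-term linearization of the interference image is valid) and a
#' scattering `phase` in radians, wrapped to [-pi, pi).
#'
#' @param x,y Continuous pixel coordinates (0-based; `0 <= x < W`,
#'   `0 <= y < H` for the target grid).
#' @param amplitude Non-negative scattering amplitude(s).
#' @param phase Scattering phase(s) in radians (wrapped).
#' @return A tibble with columns `x`, `y`, `amplitude`, `phase`.
#' @examples
#' scatterers(40.2, 39.8, amplitude = 0.05, phase = 1)
#' @export
scatterers <- function(x = numeric(), y = numeric(),
                       amplitude = numeric(), phase = numeric()) {
  df <- tibble::tibble(
    x = as.numeric(x), y = as.numeric(y),
    amplitude = as.numeric(amplitude), phase = wrap_phase(as.numeric(phase))
  )
  stopifnot(all(df$amplitude >= 0))
  df
}

#' Wrap angles to [-pi, pi)
#' @param p Angles in radians.
#' @return Wrapped angles.
#' @export
wrap_phase <- function(p) {
  ((p + pi) %% (2 * pi)) - pi
}

# physical coordinate grids (nm), pixel-centered, 0-based, row = y, col = x
physical_grid <- function(config, height, width) {
  ps <- config$pixel_size
  list(
    x = matrix(rep((0:(width - 1)) * ps, each = height), nrow = height),
    y = matrix(rep((0:(height - 1)) * ps, times = width), nrow = height)
  )
}

as_complex_field <- function(values, pixel_size) {
  structure(values, pixel_size = pixel_size, class = c("complex_field", class(values)))
}

#' Reference (reflected) plane wave
#'
#' The background of an iPM image: the wave reflected off the metal film,
#' modeled as a unit-amplitude plane wave in the dielectric,
#' `E_R(x, y) = exp(-i k_d (y' cos(theta) + x' sin(theta)) + i psi)`,
#' where `k_d = n k0` is the (real) dielectric wavenumber, `theta` the
#' incident angle, `(x', y')` the physical coordinates rotated in-plane by
#' the propagation angle, and `psi` the total reference phase (the explicit
#' phase offset plus the film-thickness optical-path contribution). Having a
#' real wavenumber, it has unit modulus at every pixel.
#'
#' @param config An [optical_config()].
#' @param height,width Image dimensions in pixels.
#' @return An `height x width` complex matrix of class `complex_field` with a
#'   `pixel_size` attribute.
#' @export
reflected_field <- function(config, height, width) {
  stopifnot(height >= 1, width >= 1)
  wn <- derive_wavenumbers(config)
  g <- physical_grid(config, height, width)
  as_complex_field(
    reflected_wave_at(config, wn, g$x, g$y),
    config$pixel_size
  )
}

# scalar/elementwise evaluation of the reference wave at physical (x, y) nm
reflected_wave_at <- function(config, wn, x, y) {
  phi <- config$propagation_angle
  u <- x * cos(phi) - y * sin(phi)
  v <- x * sin(phi) + y * cos(phi)
  th <- config$incident_angle
  exp(1i * (-wn$k_d * (v * cos(th) + u * sin(th)) + reference_phase(config, wn$k0)))
}

#' Object wave of a single scatterer
#'
#' The leakage-radiation wave scattered by one point object: a decaying
#' circular wave centred on the scatterer,
#' `E_O(r) = alpha e^{i p} E_R(r') exp(-2 k'' |r - r'|) exp(-i k' |r - r'|)
#' exp(kappa_z z)`, with `k' + i k''` the complex surface-plasmon propagation
#' constant, `|r - r'|` the in-plane physical distance from the scatterer at
#' `r'`, and `kappa_z <= 0` the defocus attenuation rate applied to the
#' back-focal-plane offset `z`. The expression is finite at `r = r'` (no
#' 1/r singularity), where it equals `alpha e^{i p} E_R(r') exp(kappa_z z)`.
#'
#' @param config An [optical_config()].
#' @param scatterer A one-row [scatterers()] tibble (or list with `x`, `y`,
#'   `amplitude`, `phase`).
#' @param height,width Image dimensions in pixels.
#' @return An `height x width` complex matrix of class `complex_field`.
#' @export
object_field <- function(config, scatterer, height, width) {
  stopifnot(height >= 1, width >= 1)
  if (scatterer$x < 0 || scatterer$x >= width ||
      scatterer$y < 0 || scatterer$y >= height) {
    stop("scatterer lies outside the image grid", call. = FALSE)
  }
  wn <- derive_wavenumbers(config)
  g <- physical_grid(config, height, width)
  ps <- config$pixel_size
  xr <- scatterer$x * ps
  yr <- scatterer$y * ps
  d <- sqrt((g$x - xr)^2 + (g$y - yr)^2)
  er_at <- reflected_wave_at(config, wn, xr, yr)
  vals <- scatterer$amplitude * exp(1i * scatterer$phase) * er_at *
    exp(-2 * wn$k_dprime * d) *
    exp(-1i * wn$k_prime * d) *
    exp(wn$kappa_z * config$bfp_offset)
  as_complex_field(vals, ps)
}

#' Interference intensity of an iPM image
#'
#' Combines reference and object waves into the background-subtracted image.
#' `mode = "full"` computes `|E_R + E_O|^2 - |E_R|^2` (the measured
#' spatial-difference image); `mode = "linearized"` drops the `|E_O|^2`
#' self-term, keeping only the cross terms
#' `E_R conj(E_O) + conj(E_R) E_O = 2 Re(conj(E_R) E_O)`, valid when the
#' object wave is much weaker than the reference. Their pointwise difference
#' is exactly `|E_O|^2`.
#'
#' @param er,eo Complex fields of identical dimensions.
#' @param mode `"full"` or `"linearized"`.
#' @return A real matrix of the same dimensions.
#' @export
ipm_intensity <- function(er, eo, mode = c("full", "linearized")) {
  mode <- match.arg(mode)
  if (!identical(dim(er), dim(eo))) {
    stop("reference and object fields must have identical dimensions", call. = FALSE)
  }
  out <- if (mode == "full") {
    Mod(er + eo)^2 - Mod(er)^2
  } else {
    2 * Re(Conj(er) * eo)
  }
  structure(out, pixel_size = attr(er, "pixel_size"))
}

#' Render an iPM scene
#'
#' Superposes the object waves of all scatterers in a scene and forms the
#' interference image against the reference wave. An empty scene renders as
#' an all-zero image. Deterministic for fixed inputs.
#'
#' @param config An [optical_config()].
#' @param scene A [scatterers()] tibble (zero or more rows).
#' @param height,width Image dimensions in pixels.
#' @param mode Intensity mode, see [ipm_intensity()].
#' @return A real `height x width` matrix with a `pixel_size` attribute.
#' @examples
#' img <- render_scene(optical_config(), scatterers(40, 40, 0.05, 0), 80, 80)
#' @export
render_scene <- function(config, scene, height, width,
                         mode = c("full", "linearized")) {
  mode <- match.arg(mode)
  er <- reflected_field(config, height, width)
  eo <- as_complex_field(
    matrix(0 + 0i, height, width), config$pixel_size
  )
  if (nrow(scene) > 0) {
    for (i in seq_len(nrow(scene))) {
      eo <- eo + object_field(config, scene[i, ], height, width)
    }
  }
  ipm_intensity(er, as_complex_field(eo, config$pixel_size), mode)
}
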