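#' Optical configuration for iPM image formation
#'
#' Bundles every image-wide physical variable of the interferometric
#' plasmonic microscope: the six variables the network regresses
#' (`pixel_size`, `propagation_angle`, `incident_angle`, `bfp_offset`,
#' `film_thickness`, `phase_offset`) plus the material constants from which
#' the wavenumbers derive.
#'
#' All lengths are in nanometres, all angles in radians. The complex metal
#' permittivity must satisfy the surface-plasmon existence condition
#' `Re(metal_permittivity) < -dielectric_index^2`; configurations violating
#' it are rejected because no bound surface plasmon exists there.
#'
#' @param wavelength Free-space wavelength (nm). Default 633 (HeNe line).
#' @param incident_angle Incidence angle of the excitation wave with respect
#'   to the interface normal (rad). Default is the SPR dip angle for the
#'   default materials behind a 1.515-index coupling medium.
#' @param propagation_angle In-plane azimuth of the reference-wave tilt
#'   (rad); rotates the interference fringes. Default 0.
#' @param pixel_size Physical size of one camera pixel after magnification
#'   (nm/px). Default 93.
#' @param bfp_offset Back-focal-plane displacement z (nm); attenuates the
#'   object-wave contribution. Default 0.
#' @param film_thickness Metal film thickness (nm); contributes an additional
#'   reference-wave phase. Default 50.
#' @param phase_offset Reference-wave phase shift from the optical path
#'   (rad). Default 0.
#' @param metal_permittivity Complex relative permittivity of the film.
#'   Default -11.74 + 1.26i (gold at 633 nm).
#' @param dielectric_index Real refractive index of the medium above the film.
#'   Default 1 (dried samples in air).
#' @param numerical_aperture Collection NA of the objective. Default 1.49.
#'
#' @return An object of class `optical_config` (a named list).
#' @examples
#' cfg <- optical_config()
#' derive_wavenumbers(cfg)$k0   # 2*pi/633
#' @export
optical_config <- function(wavelength = 633,
                           incident_angle = spr_angle(),
                           propagation_angle = 0,
                           pixel_size = 93,
                           bfp_offset = 0,
                           film_thickness = 50,
                           phase_offset = 0,
                           metal_permittivity = complex(real = -11.74, imaginary = 1.26),
                           dielectric_index = 1,
                           numerical_aperture = 1.49) {
  cfg <- structure(
    list(
      wavelength = as.numeric(wavelength),
      incident_angle = as.numeric(incident_angle),
      propagation_angle = as.numeric(propagation_angle),
      pixel_size = as.numeric(pixel_size),
      bfp_offset = as.numeric(bfp_offset),
      film_thickness = as.numeric(film_thickness),
      phase_offset = as.numeric(phase_offset),
      metal_permittivity = as.complex(metal_permittivity),
      dielectric_index = as.numeric(dielectric_index),
      numerical_aperture = as.numeric(numerical_aperture)
    ),
    class = "optical_config"
  )
  validate_optical_config(cfg)
  cfg
}

validate_optical_config <- function(cfg) {
  stopifnot(
    cfg$wavelength > 0,
    cfg$pixel_size > 0,
    cfg$dielectric_index >= 1,
    cfg$numerical_aperture > 0,
    is.finite(cfg$incident_angle),
    is.finite(cfg$bfp_offset),
    is.finite(cfg$film_thickness),
    is.finite(cfg$phase_offset)
  )
  if (Re(cfg$metal_permittivity) >= -cfg$dielectric_index^2) {
    stop(
      "no bound surface plasmon: Re(metal_permittivity) must be < -n^2 ",
      "(got ", Re(cfg$metal_permittivity), " vs -", cfg$dielectric_index^2, ")",
      call. = FALSE
    )
  }
  invisible(cfg)
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  wavelength     %g nm   pixel_size %g nm/px   NA %g\n",
              x$wavelength, x$pixel_size, x$numerical_aperture))
  cat(sprintf("  incident angle %.4f rad   propagation angle %.4f rad\n",
              x$incident_angle, x$propagation_angle))
  cat(sprintf("  bfp offset     %g nm   film %g nm   phase offset %.4f rad\n",
              x$bfp_offset, x$film_thickness, x$phase_offset))
  cat(sprintf("  metal eps      %g%+gi   dielectric n %g\n",
              Re(x$metal_permittivity), Im(x$metal_permittivity),
              x$dielectric_index))
  invisible(x)
}

#' Surface plasmon resonance dip angle
#'
#' Angle of incidence (through a coupling medium of index `n_coupling`) at
#' which the in-plane photon momentum matches the real part of the
#' surface-plasmon wavenumber. Used as the centre of the incident-angle
#' sampling range.
#'
#' @param metal_permittivity,dielectric_index Materials as in
#'   [optical_config()].
#' @param wavelength Free-space wavelength (nm).
#' @param n_coupling Index of the coupling prism/objective immersion medium.
#' @return Angle in radians.
#' @export
spr_angle <- function(metal_permittivity = complex(real = -11.74, imaginary = 1.26),
                      dielectric_index = 1,
                      wavelength = 633,
                      n_coupling = 1.515) {
  k0 <- 2 * pi / wavelength
  ksp <- sp_wavenumber(k0, metal_permittivity, dielectric_index)
  asin(Re(ksp) / (k0 * n_coupling))
}

# complex SP propagation constant with the decaying branch
# (Im <= 0 under the e^{-ikr} sign convention)
sp_wavenumber <- function(k0, eps_m, n) {
  ksp <- k0 * sqrt(eps_m * n^2 / (eps_m + n^2))
  if (Im(ksp) > 0) ksp <- Conj(ksp)
  ksp
}

#' Derive wavenumbers from an optical configuration
#'
#' Computes the free-space wavenumber `k0 = 2*pi/wavelength`, the real
#' dielectric wavenumber `k_d = n*k0` of the reference plane wave, and the
#' complex surface-plasmon propagation constant
#' `k_sp = k0 * sqrt(eps_m * n^2 / (eps_m + n^2))`, with the branch chosen so
#' that `Im(k_sp) <= 0` (decaying propagation under the `exp(-i k r)` sign
#' convention). `k_prime = Re(k_sp)` sets the object-wave fringe period and
#' `k_dprime = -Im(k_sp) >= 0` its radial decay rate. `kappa_z` is the
#' (negative) defocus attenuation rate `-sqrt(k_prime^2 - k_d^2)` applied as
#' `exp(kappa_z * z)` for a back-focal-plane offset `z`.
#'
#' @param config An [optical_config()].
#' @return A named list with `k0`, `k_d`, `k_sp`, `k_prime`, `k_dprime`,
#'   `kappa_z` (all in rad/nm; `k_sp` complex).
#' @export
derive_wavenumbers <- function(config) {
  validate_optical_config(config)
  k0 <- 2 * pi / config$wavelength
  kd <- config$dielectric_index * k0
  ksp <- sp_wavenumber(k0, config$metal_permittivity, config$dielectric_index)
  kp <- Re(ksp)
  list(
    k0 = k0,
    k_d = kd,
    k_sp = ksp,
    k_prime = kp,
    k_dprime = -Im(ksp),
    kappa_z = -sqrt(max(kp^2 - kd^2, 0))
  )
}

#' Diffraction-limited resolution radius
#'
#' Abbe criterion `lambda / (2 NA)`: the radius within which a predicted
#' scatterer location counts as correct.
#'
#' @param config An [optical_config()].
#' @return Radius in nm.
#' @examples
#' diffraction_radius(optical_config())  # ~212.4 nm at 633 nm / NA 1.49
#' @export
diffraction_radius <- function(config) {
  config$wavelength / (2 * config$numerical_aperture)
}

# total reference-wave phase: the explicit optical-path offset plus the
# film-thickness contribution (one optical-path phase k0*d; the two variables
# act nearly identically on the image, which is deliberate and matches how
# the microscope behaves)
reference_phase <- function(config, k0 = 2 * pi / config$wavelength) {
  config$phase_offset + k0 * config$film_thickness
}
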