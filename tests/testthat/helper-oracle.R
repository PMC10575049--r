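# Independent scalar brute-force evaluation of the iPM image model:
# plain double loops over pixels and scatterers, no shared code with the
# vectorized renderer beyond the closed-form wavenumber definitions.

bf_wavenumbers <- function(cfg) {
  k0 <- 2 * pi / cfg$wavelength
  ksp <- k0 * sqrt(cfg$metal_permittivity * cfg$dielectric_index^2 /
                     (cfg$metal_permittivity + cfg$dielectric_index^2))
  if (Im(ksp) > 0) ksp <- Conj(ksp)
  list(k0 = k0, kd = cfg$dielectric_index * k0,
       kp = Re(ksp), kpp = -Im(ksp),
       kz = -sqrt(max(Re(ksp)^2 - (cfg$dielectric_index * k0)^2, 0)))
}

bf_reference_at <- function(cfg, wn, xn, yn) {
  phi <- cfg$propagation_angle
  u <- xn * cos(phi) - yn * sin(phi)
  v <- xn * sin(phi) + yn * cos(phi)
  psi <- cfg$phase_offset + wn$k0 * cfg$film_thickness
  exp(1i * (-wn$kd * (v * cos(cfg$incident_angle) +
                        u * sin(cfg$incident_angle)) + psi))
}

bf_render <- function(cfg, scene, height, width, mode = "full") {
  wn <- bf_wavenumbers(cfg)
  ps <- cfg$pixel_size
  img <- matrix(0, height, width)
  for (row in seq_len(height)) {
    for (col in seq_len(width)) {
      xn <- (col - 1) * ps
      yn <- (row - 1) * ps
      er <- bf_reference_at(cfg, wn, xn, yn)
      eo <- 0 + 0i
      if (nrow(scene) > 0) {
        for (s in seq_len(nrow(scene))) {
          d <- sqrt((xn - scene$x[s] * ps)^2 + (yn - scene$y[s] * ps)^2)
          erp <- bf_reference_at(cfg, wn, scene$x[s] * ps, scene$y[s] * ps)
          eo <- eo + scene$amplitude[s] * exp(1i * scene$phase[s]) * erp *
            exp(-2 * wn$kpp * d) * exp(-1i * wn$kp * d) *
            exp(wn$kz * cfg$bfp_offset)
        }
      }
      img[row, col] <- if (mode == "full") {
        Mod(er + eo)^2 - Mod(er)^2
      } else {
        2 * Re(Conj(er) * eo)
      }
    }
  }
  img
}

# a small non-trivial configuration exercising every variable
oracle_config <- function() {
  optical_config(
    incident_angle = 0.76, propagation_angle = 0.12, pixel_size = 91,
    bfp_offset = 250, film_thickness = 48, phase_offset = 0.9
  )
}
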