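#' Detector geometry
#'
#' Flat-detector geometry and pixel masks for a monolithic grid emulating a
#' tiled pixel-array detector. Defaults follow the experimental setup: 565 mm
#' sample-to-detector distance, 2.07 Angstrom wavelength (6 keV), 110 um pixel
#' pitch. The panel-gap mask is a configurable cross of masked rows/columns
#' through the tile boundaries; bad pixels are an arbitrary logical mask.
#'
#' @param n_rows,n_cols Detector size in pixels.
#' @param pixel_pitch Pixel pitch in micrometres.
#' @param distance Sample-to-detector distance in mm.
#' @param wavelength X-ray wavelength in Angstrom.
#' @param beam_center Beam center `(row, col)`; defaults to the center pixel.
#' @param gap_half_width Half-width (pixels) of the cross-shaped panel gap;
#'   0 disables it.
#' @param bad_pixel_fraction Fraction of randomly placed dead pixels (drawn
#'   with `bad_pixel_seed`).
#' @param bad_pixel_seed Seed for the bad-pixel draw.
#' @return An object of class `detector_geometry` with logical masks
#'   `panel_gap_mask` and `bad_pixel_mask` (`TRUE` = excluded).
#' @export
detector_geometry <- function(n_rows = 400, n_cols = n_rows,
                              pixel_pitch = 110, distance = 565,
                              wavelength = 2.07, beam_center = NULL,
                              gap_half_width = 1L,
                              bad_pixel_fraction = 0.002,
                              bad_pixel_seed = 9001L) {
  stopifnot(distance > 0, wavelength > 0, pixel_pitch > 0)
  if (is.null(beam_center))
    beam_center <- c(floor(n_rows / 2) + 1, floor(n_cols / 2) + 1)
  gap <- matrix(FALSE, n_rows, n_cols)
  if (gap_half_width > 0) {
    rr <- round(beam_center[1]) + seq(-gap_half_width, gap_half_width)
    cc <- round(beam_center[2]) + seq(-gap_half_width, gap_half_width)
    gap[rr[rr >= 1 & rr <= n_rows], ] <- TRUE
    gap[, cc[cc >= 1 & cc <= n_cols]] <- TRUE
  }
  bad <- matrix(FALSE, n_rows, n_cols)
  if (bad_pixel_fraction > 0) {
    n_bad <- round(bad_pixel_fraction * n_rows * n_cols)
    old <- .save_rng_state()
    set.seed(bad_pixel_seed)
    bad[sample.int(n_rows * n_cols, n_bad)] <- TRUE
    .restore_rng_state(old)
  }
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pixel_pitch = pixel_pitch, distance = distance,
                 wavelength = wavelength, beam_center = beam_center,
                 panel_gap_mask = gap, bad_pixel_mask = bad),
            class = "detector_geometry")
}

# save/restore the RNG state so that internal seeded draws do not disturb the
# caller's random stream
.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng_state <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
  invisible()
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf(
    "<detector_geometry> %d x %d px @ %g um, distance %g mm, lambda %g A\n",
    x$n_rows, x$n_cols, x$pixel_pitch, x$distance, x$wavelength))
  invisible(x)
}

#' Spatial frequency of a detector pixel
#'
#' Exact (non-small-angle) momentum-transfer calibration of a flat detector:
#' for a pixel at radial distance r from the beam center, the scattering
#' angle is `2 theta = atan(r / distance)` and the spatial frequency is
#' `q = 2 sin(theta) / lambda`, in nm^-1 (reciprocal resolution, `d = 1/q`).
#'
#' @param geometry A `detector_geometry`.
#' @param row,col Pixel coordinates (may be vectors, fractional allowed).
#' @return Spatial frequency in nm^-1.
#' @export
q_of_pixel <- function(geometry, row, col) {
  dr <- (row - geometry$beam_center[1]) * geometry$pixel_pitch * 1e-3  # mm
  dc <- (col - geometry$beam_center[2]) * geometry$pixel_pitch * 1e-3
  r <- sqrt(dr^2 + dc^2)
  two_theta <- atan2(r, geometry$distance)
  lambda_nm <- geometry$wavelength * 0.1
  2 * sin(two_theta / 2) / lambda_nm
}

#' Photon wavelength from energy
#'
#' `lambda = h c / E`; 6 keV corresponds to 2.07 Angstrom.
#'
#' @param energy_keV Photon energy in keV.
#' @return Wavelength in Angstrom.
#' @export
wavelength_from_energy <- function(energy_keV) {
  stopifnot(all(energy_keV > 0))
  12.39841984 / energy_keV
}

#' Photons per pulse from pulse energy
#'
#' Number of photons in a pulse of given total energy: pulse energy divided by
#' the single-photon energy. A 2 mJ pulse at 6 keV carries ~2e12 photons.
#'
#' @param pulse_mJ Pulse energy in millijoule.
#' @param energy_keV Photon energy in keV.
#' @return Photon count.
#' @export
photons_from_pulse_energy <- function(pulse_mJ, energy_keV) {
  stopifnot(all(pulse_mJ > 0), all(energy_keV > 0))
  (pulse_mJ * 1e-3) / (energy_keV * 1.602176634e-16)
}

#' Illuminated sample volume
#'
#' Cylinder swept by the focused beam through the liquid jet:
#' `pi (focus/2)^2 x jet diameter`. The experimental values (200 nm focus,
#' 5 um jet) give ~0.16 um^3.
#'
#' @param focus_nm Beam focus diameter in nm.
#' @param jet_um Jet diameter in micrometres.
#' @return Volume in um^3.
#' @export
illuminated_volume <- function(focus_nm, jet_um) {
  stopifnot(all(focus_nm >= 0), all(jet_um >= 0))
  pi * (focus_nm * 1e-3 / 2)^2 * jet_um
}
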