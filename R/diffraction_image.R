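#' Diffraction image
#'
#' The unit that flows through sorting, averaging, fitting and phase
#' retrieval: a 2D intensity grid (photons per pixel) with a linear spatial
#' frequency calibration, a beam center and a pixel mask. Simulated images
#' live on a grid linear in spatial frequency (the flat-detector distortion
#' is below 0.3% at the q-range of interest); q of a pixel is
#' `q_step * radius` from the beam center, in nm^-1 with `d = 1/q`.
#'
#' @param intensity Numeric matrix of photon counts.
#' @param q_step Spatial-frequency step per pixel, nm^-1.
#' @param beam_center Beam center `(row, col)`; defaults to the center pixel.
#' @param mask Logical matrix, `TRUE` = excluded pixel (panel gap, bad pixel,
#'   beamstop). Masked pixels carry 0 and are excluded from all statistics.
#' @param geometry Optional `detector_geometry` metadata.
#' @param metadata Free-form list (shot id, true jet angle for synthetic
#'   shots, seed, labels).
#' @return An object of class `diffraction_image`.
#' @export
diffraction_image <- function(intensity, q_step, beam_center = NULL,
                              mask = NULL, geometry = NULL,
                              metadata = list()) {
  stopifnot(is.matrix(intensity), q_step > 0)
  if (is.null(beam_center))
    beam_center <- c(floor(nrow(intensity) / 2) + 1,
                     floor(ncol(intensity) / 2) + 1)
  if (is.null(mask)) mask <- matrix(FALSE, nrow(intensity), ncol(intensity))
  stopifnot(identical(dim(mask), dim(intensity)))
  if (any(intensity[!mask] < 0))
    stop("negative intensity on unmasked pixels", call. = FALSE)
  intensity[mask] <- 0
  structure(list(intensity = intensity, q_step = q_step,
                 beam_center = beam_center, mask = mask,
                 geometry = geometry, metadata = metadata),
            class = "diffraction_image")
}

#' @export
print.diffraction_image <- function(x, ...) {
  n_masked <- sum(x$mask)
  cat(sprintf(
    "<diffraction_image> %d x %d px, q step %.4g nm^-1 (q_max %.3g), %d masked px\n",
    nrow(x$intensity), ncol(x$intensity), x$q_step,
    x$q_step * min(dim(x$intensity)) / 2, n_masked))
  if (!is.null(x$metadata$shot_id))
    cat(sprintf("  shot %s\n", x$metadata$shot_id))
  invisible(x)
}

# per-pixel radius (px) and q (nm^-1) from the beam center
pixel_radius <- function(img) {
  dr <- seq_len(nrow(img$intensity)) - img$beam_center[1]
  dc <- seq_len(ncol(img$intensity)) - img$beam_center[2]
  sqrt(outer(dr^2, dc^2, `+`))
}

pixel_q <- function(img) img$q_step * pixel_radius(img)

# polar angle (deg, mod 180) of each pixel about the beam center, measured
# counter-clockwise from the +x (column) axis with y (rows) increasing up
pixel_angle <- function(img) {
  dr <- seq_len(nrow(img$intensity)) - img$beam_center[1]
  dc <- seq_len(ncol(img$intensity)) - img$beam_center[2]
  ang <- atan2(outer(dr, rep(1, length(dc))),
               outer(rep(1, length(dr)), dc)) * 180 / pi
  ang %% 180
}

#' Rotate a diffraction image about its beam center
#'
#' Bilinear interpolation; the mask is propagated by rotating a validity map
#' and re-masking pixels that draw more than `mask_tol` of their weight from
#' masked or out-of-bounds source regions.
#'
#' @param img A `diffraction_image`.
#' @param angle Rotation angle, degrees counter-clockwise.
#' @param mask_tol Maximum tolerated masked-source weight (default 0.05).
#' @return The rotated `diffraction_image`.
#' @export
rotate_image <- function(img, angle, mask_tol = 0.05) {
  valid <- matrix(as.numeric(!img$mask), nrow(img$intensity))
  # kernel's inverse mapping advances feature angles by -angle in the
  # pixel_angle convention; negate so that +angle moves features CCW
  rot <- cpp_rotate_weighted(img$intensity, valid, -angle,
                             img$beam_center[1], img$beam_center[2])
  new_mask <- rot$weight < (1 - mask_tol)
  out <- rot$image
  out[new_mask] <- 0
  out[!new_mask] <- out[!new_mask] / rot$weight[!new_mask]
  out[out < 0] <- 0
  diffraction_image(out, img$q_step, img$beam_center, new_mask,
                    img$geometry, img$metadata)
}

#' Crop the central four panels
#'
#' Emulates restricting sorting statistics to the central four of sixteen
#' detector tiles: keeps the centered half-size region around the beam
#' center.
#'
#' @param img A `diffraction_image`.
#' @return The cropped `diffraction_image`.
#' @export
crop_central_panels <- function(img) {
  n <- nrow(img$intensity); m <- ncol(img$intensity)
  hr <- floor(n / 4); hc <- floor(m / 4)
  rows <- (round(img$beam_center[1]) - hr):(round(img$beam_center[1]) + hr - 1)
  cols <- (round(img$beam_center[2]) - hc):(round(img$beam_center[2]) + hc - 1)
  rows <- rows[rows >= 1 & rows <= n]
  cols <- cols[cols >= 1 & cols <= m]
  diffraction_image(img$intensity[rows, cols], img$q_step,
                    c(img$beam_center[1] - rows[1] + 1,
                      img$beam_center[2] - cols[1] + 1),
                    img$mask[rows, cols], img$geometry, img$metadata)
}
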