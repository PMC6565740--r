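#' Azimuthal integration (pseudo-SAXS profile)
#'
#' Mean unmasked intensity in equal-width momentum-transfer bins about the
#' beam center. Diffraction images are calibrated in spatial frequency
#' (1/d, nm^-1); the profile is reported on the SAXS momentum-transfer scale
#' `q = 4 pi sin(theta) / lambda = 2 pi / d` (nm^-1), the convention in which
#' the first lobe of a cylindrical shell of radius R sits at `q = 3.83 / R`.
#' Bins are half-open `[low, high)` over `[0, q_max)` with the q of a pixel
#' evaluated at its center; empty bins are flagged, not zero-filled.
#'
#' @param image A `diffraction_image`.
#' @param n_bins Number of bins (default 250).
#' @param q_max Upper edge of the binned range (SAXS nm^-1); default the
#'   inscribed-circle radius of the detector.
#' @return An object of class `radial_profile`: data.frame with `q` (bin
#'   centers, SAXS nm^-1), `mean_intensity` (NA for empty bins) and
#'   `pixel_count`.
#' @export
azimuthal_integrate <- function(image, n_bins = 250L, q_max = NULL) {
  q_saxs <- 2 * pi * pixel_q(image)
  good <- !image$mask
  if (is.null(q_max))
    q_max <- 2 * pi * image$q_step *
      (min(dim(image$intensity)) / 2 - 0.5)
  sel <- good & q_saxs < q_max
  if (!any(sel)) stop("no unmasked pixels in the q range", call. = FALSE)
  width <- q_max / n_bins
  bin <- floor(q_saxs[sel] / width) + 1L
  cnt <- tabulate(bin, nbins = n_bins)
  ssum <- rep(0, n_bins)
  t <- tapply(image$intensity[sel], bin, sum)
  ssum[as.integer(names(t))] <- t
  mean_int <- ifelse(cnt > 0, ssum / pmax(cnt, 1), NA_real_)
  structure(data.frame(q = (seq_len(n_bins) - 0.5) * width,
                       mean_intensity = mean_int, pixel_count = cnt),
            class = c("radial_profile", "data.frame"))
}

#' Locate the J01 peak of a pseudo-SAXS profile
#'
#' First local maximum of the low-q oscillation within the search range,
#' refined by a 3-point parabola: the first lobe of the zero-order Bessel
#' form factor of the (hollow-cylinder) filament, whose location encodes the
#' mean helical radius.
#'
#' @param profile A `radial_profile`.
#' @param search_range q-range (SAXS nm^-1) searched.
#' @param smooth Half-width (bins) of a running-mean filter applied before
#'   peak picking (default 2), suppressing single-bin noise blips; 0
#'   disables.
#' @return The refined peak location q (SAXS nm^-1).
#' @export
find_J01 <- function(profile, search_range = c(0.15, 0.6), smooth = 2L) {
  v_all <- profile$mean_intensity
  if (smooth > 0) {
    k <- 2L * smooth + 1L
    v_all <- as.numeric(stats::filter(v_all, rep(1 / k, k)))
  }
  sel <- which(profile$q >= search_range[1] & profile$q <= search_range[2] &
               is.finite(v_all))
  if (length(sel) < 3) stop("search range not covered by the profile",
                            call. = FALSE)
  v <- v_all[sel]
  n <- length(v)
  loc <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  if (length(loc) == 0)
    stop("no local maximum in the search range", call. = FALSE)
  i <- loc[1]
  ref <- parabolic_peak(v_all, sel[i])
  width <- profile$q[2] - profile$q[1]
  profile$q[1] + (ref - 1) * width
}

#' Mean helical radius from the J01 peak
#'
#' `R = 7.66 / (2 q)` with q the J01 location on the SAXS scale; the
#' experimental peak at 0.297 nm^-1 gives 12.9 nm.
#'
#' @param q J01 peak location, SAXS nm^-1.
#' @return Mean helical radius, nm.
#' @export
helical_radius_from_J01 <- function(q) {
  if (any(q <= 0)) stop("q must be positive", call. = FALSE)
  7.66 / (2 * q)
}

#' Peak-to-peak diameter of a reconstruction
#'
#' Distance between the two highest maxima of the y-averaged density profile
#' along x (the maximum projected density of the filament wall), sub-pixel
#' refined by 3-point parabolas. For a hollow tube this is smaller than the
#' outer diameter: the annulus projection peaks at the inner radius.
#'
#' @param recon A `projection_density`, `projection_image`, or numeric
#'   profile along x (then `pixel_size` is required).
#' @param pixel_size Pixel size (nm) when `recon` is a bare profile.
#' @param y_halfwidth Rows within this distance (nm) of the center are
#'   averaged (default 40); `Inf` uses all rows.
#' @return Peak-to-peak distance, nm.
#' @export
peak_to_peak <- function(recon, pixel_size = NULL, y_halfwidth = 40) {
  if (inherits(recon, c("projection_density", "projection_image"))) {
    dens <- if (inherits(recon, "projection_density")) recon$density
            else recon$density
    grid <- recon$grid
    rows <- which(abs(grid_y(grid)) <= y_halfwidth)
    prof <- colMeans(dens[rows, , drop = FALSE])
    pixel_size <- grid$pixel_size
    center <- grid$center[2]
  } else {
    prof <- as.numeric(recon)
    stopifnot(!is.null(pixel_size))
    center <- (length(prof) + 1) / 2
  }
  n <- length(prof)
  is_max <- which(prof[2:(n - 1)] > prof[1:(n - 2)] &
                  prof[2:(n - 1)] >= prof[3:n]) + 1L
  if (length(is_max) < 2)
    stop("profile has fewer than two maxima: no wall separation defined",
         call. = FALSE)
  top2 <- is_max[order(-prof[is_max])][1:2]
  ref <- vapply(top2, function(i) parabolic_peak(prof, i), numeric(1))
  abs(diff(ref)) * pixel_size
}

#' Protofilament-number estimate from the mean helical radius
#'
#' Linear calibration `N = round(13 R / R13)` anchored at the 13-protofilament
#' form: `R13` is the mean helical radius of the 13-pf microtubule. The
#' default `R13 = 11.94` nm maps the experimental 12.9 nm to 14 while radii
#' in the 11.5-12.3 nm band map to 13. This mapping is a calibration
#' convention, not a derived relation.
#'
#' @param R Mean helical radius, nm (plausible range 8-18).
#' @param R13 Calibration radius of the 13-pf form, nm.
#' @return Integer protofilament number.
#' @export
protofilament_estimate <- function(R, R13 = 11.94) {
  if (any(R < 8 | R > 18))
    stop("helical radius outside the plausible 8-18 nm range", call. = FALSE)
  as.integer(round(13 * R / R13))
}

#' Axial power spectrum of a reconstruction
#'
#' Power along the helical (y) axis: mean over the wall region of the
#' squared modulus of the per-column 1D Fourier transform, as a function of
#' axial spatial frequency (1/d, nm^-1). A 4 nm monomer repeat appears as a
#' peak at 0.25 nm^-1.
#'
#' @param recon A `projection_density` or `projection_image`.
#' @param x_halfwidth Columns within this distance (nm) of the center enter
#'   the average (default 16, the filament wall region).
#' @param y_halfwidth Rows within this distance (nm) of the center are used
#'   (default 80, where the axial envelope is strong).
#' @return Data.frame with `q_y` (nm^-1, positive frequencies) and `power`.
#' @export
axial_power_spectrum <- function(recon, x_halfwidth = 16, y_halfwidth = 80) {
  dens <- recon$density
  grid <- recon$grid
  cols <- which(abs(grid_x(grid)) <= x_halfwidth)
  rows <- which(abs(grid_y(grid)) <= y_halfwidth)
  sub <- dens[rows, cols, drop = FALSE]
  sub <- sweep(sub, 2, colMeans(sub))  # remove DC per column
  pw <- Mod(stats::mvfft(sub))^2
  n <- nrow(sub)
  q_y <- (seq_len(n) - 1) / (n * grid$pixel_size)
  keep <- seq_len(floor(n / 2))
  data.frame(q_y = q_y[keep], power = rowMeans(pw)[keep])
}

#' Dominant axial-repeat frequency of a reconstruction
#'
#' Locates the most prominent local maximum of the axial power spectrum
#' after whitening: image power spectra fall steeply with frequency, so the
#' raw spectrum is divided by its running median before peak picking. A
#' reconstruction resolving the 4 nm monomer repeat peaks at 0.25 nm^-1.
#'
#' @param recon A `projection_density` or `projection_image`.
#' @param q_min Lowest axial frequency (nm^-1) considered (excludes the
#'   object envelope).
#' @param trend_halfwidth Half-width (bins) of the running-median trend.
#' @param ... Passed to [axial_power_spectrum()].
#' @return List with `q_y` (nm^-1) of the peak and `prominence` (power over
#'   trend).
#' @export
axial_repeat_peak <- function(recon, q_min = 0.1, trend_halfwidth = 4L, ...) {
  aps <- axial_power_spectrum(recon, ...)
  k <- 2L * trend_halfwidth + 1L
  trend <- stats::runmed(aps$power, k = k)
  white <- aps$power / pmax(trend, max(aps$power) * 1e-12)
  sel <- which(aps$q_y >= q_min & aps$q_y <= max(aps$q_y) - 2 *
                 (aps$q_y[2] - aps$q_y[1]))
  i <- sel[which.max(white[sel])]
  ref <- parabolic_peak(aps$power, i)
  dq <- aps$q_y[2] - aps$q_y[1]
  list(q_y = aps$q_y[1] + (ref - 1) * dq, prominence = white[i])
}

#' Locate layer lines in a diffraction pattern
#'
#' Sums intensity along rows (constant axial frequency q_y) and finds the
#' strongest off-equator layer line, optionally near a target frequency,
#' with parabolic sub-pixel refinement. Both Friedel-related halves are
#' averaged.
#'
#' @param pattern A `diffraction_image` whose equator is horizontal.
#' @param q_min Minimum |q_y| (nm^-1) considered off-equator.
#' @param near Optional target q_y; the search is restricted to
#'   `near * c(1 - tol, 1 + tol)`.
#' @param tol Relative half-width of the `near` window.
#' @return List with `q` (refined |q_y|, nm^-1) and `resolution` (`1/q`, nm).
#' @export
layer_line_position <- function(pattern, q_min = 0.06, near = NULL,
                                tol = 0.25) {
  inten <- pattern$intensity
  good <- !pattern$mask
  rs <- rowSums(inten * good) / pmax(rowSums(good), 1)
  bc <- pattern$beam_center[1]
  q_y <- (seq_len(nrow(inten)) - bc) * pattern$q_step
  # fold the two halves
  pos <- which(q_y > 0)
  prof_q <- q_y[pos]
  mate <- bc - (pos - bc)
  prof <- (rs[pos] + rs[pmax(mate, 1)]) / 2
  sel <- prof_q >= q_min
  if (!is.null(near)) sel <- sel & abs(prof_q - near) <= tol * near
  idx <- which(sel)
  if (length(idx) == 0) stop("no rows in the layer-line search range",
                             call. = FALSE)
  i <- idx[which.max(prof[idx])]
  ref <- parabolic_peak(prof, i)
  q <- prof_q[1] + (ref - 1) * pattern$q_step
  list(q = q, resolution = 1 / q)
}
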