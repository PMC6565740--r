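#' Real-space support mask parameters
#'
#' The solvent-flattening prior of the reconstruction: projected density is
#' known to vanish outside the filament. Across the helix (x) the mask is a
#' smoothed top-hat, amplitude 1 for `|x| <= x_half_width` falling to zero as
#' a half Gaussian of width `x_falloff`; along the helix (y) it is a Gaussian
#' of FWHM `y_fwhm` (the axial illumination envelope), maximal at y = 0.
#' The experimental parameters are 15.6 nm, 11.8 nm and 159 nm.
#'
#' @param x_half_width Flat-top half-width in x, nm.
#' @param x_falloff Half-Gaussian falloff width in x, nm.
#' @param y_fwhm Full width at half maximum of the y Gaussian, nm.
#' @param width_convention How `x_falloff` maps to the Gaussian sigma:
#'   `"fwhm"` (default; sigma = width / 2.3548, i.e. the value at one width
#'   beyond the flat top is 2^-4 = 0.0625) or `"sigma"` (sigma = width).
#' @return An object of class `support_mask`.
#' @export
support_mask <- function(x_half_width = 15.6, x_falloff = 11.8,
                         y_fwhm = 159, width_convention = c("fwhm", "sigma")) {
  width_convention <- match.arg(width_convention)
  stopifnot(x_half_width > 0, x_falloff > 0, y_fwhm > 0)
  structure(list(x_half_width = x_half_width, x_falloff = x_falloff,
                 y_fwhm = y_fwhm, width_convention = width_convention),
            class = "support_mask")
}

#' @export
print.support_mask <- function(x, ...) {
  cat(sprintf(
    "<support_mask> x: flat |x| <= %g nm + half-Gaussian width %g nm (%s); y: Gaussian FWHM %g nm\n",
    x$x_half_width, x$x_falloff, x$width_convention, x$y_fwhm))
  invisible(x)
}

# separable mask factors on a grid
support_profiles <- function(support, grid) {
  sig_x <- if (support$width_convention == "fwhm")
    support$x_falloff / (2 * sqrt(2 * log(2))) else support$x_falloff
  x <- grid_x(grid); y <- grid_y(grid)
  over <- pmax(abs(x) - support$x_half_width, 0)
  sx <- exp(-over^2 / (2 * sig_x^2))
  sy <- exp(-4 * log(2) * (y / support$y_fwhm)^2)
  list(sx = sx, sy = sy)
}

#' Evaluate the support mask on a grid
#'
#' @param support A `support_mask`.
#' @param grid A `grid2d`.
#' @return Matrix of mask values in `[0, 1]`, equal to 1 at the origin.
#' @export
support_matrix <- function(support, grid) {
  p <- support_profiles(support, grid)
  outer(p$sy, p$sx)
}

#' Apply the support to a real-space object
#'
#' Pixel-wise product with the separable mask. The mask is below 1 away from
#' the center, so repeated application keeps shrinking the object; it is
#' applied exactly once per retrieval cycle.
#'
#' @param object Numeric matrix (real-space density) or `projection_image`.
#' @param support A `support_mask`.
#' @param grid The `grid2d` of the object (taken from a `projection_image`
#'   automatically).
#' @return Object of the same type, masked.
#' @export
apply_support <- function(object, support, grid = NULL) {
  if (inherits(object, "projection_image")) {
    grid <- object$grid
    object$density <- object$density * support_matrix(support, grid)
    return(object)
  }
  stopifnot(!is.null(grid))
  object * support_matrix(support, grid)
}

#' Retrieval configuration
#'
#' @param n_cycles Number of iterative cycles (default 100).
#' @param symmetry_period Apply real-space inversion symmetry (average the
#'   object with its 180-degree rotation about the center) every this many
#'   cycles (default 10; 0 disables).
#' @param init_tube Featureless tube supplying the initial phases (default
#'   17.4 / 25.4 nm).
#' @param fill_tube Featureless tube used to model the unmeasured central
#'   beam; `NULL` (default) uses `init_tube`. The robustness scan varies
#'   `init_tube` while keeping one fill model.
#' @param central_fill_radius Radius (nm^-1) of the filled central region;
#'   `NULL` = half the distance to the first equatorial peak of the tube
#'   model.
#' @param real_object Enforce a real-valued object each cycle (default TRUE).
#' @param positivity Clip the object at zero each cycle (default FALSE).
#' @param phase_perturbation Amplitude (fraction of pi) of seeded uniform
#'   noise added to the initial phases; 0 (default) keeps the deterministic
#'   tube-model start, positive values enable perturbed multi-start runs.
#' @param seed Seed for the phase perturbation.
#' @return An object of class `retrieval_config`.
#' @export
retrieval_config <- function(n_cycles = 100L, symmetry_period = 10L,
                             init_tube = tube_model(17.4, 25.4),
                             fill_tube = NULL,
                             central_fill_radius = NULL,
                             real_object = TRUE, positivity = FALSE,
                             phase_perturbation = 0, seed = 1L) {
  stopifnot(n_cycles >= 1, symmetry_period >= 0,
            phase_perturbation >= 0, phase_perturbation <= 1)
  structure(list(n_cycles = as.integer(n_cycles),
                 symmetry_period = as.integer(symmetry_period),
                 init_tube = init_tube, fill_tube = fill_tube,
                 central_fill_radius = central_fill_radius,
                 real_object = real_object, positivity = positivity,
                 phase_perturbation = phase_perturbation,
                 seed = as.integer(seed)),
            class = "retrieval_config")
}

#' Initial reciprocal-space field from a tube model
#'
#' Forward transform of the featureless-tube projection modulated by the
#' axial (y) Gaussian support; its phases seed the first retrieval cycle and
#' its amplitudes model the unmeasurable central beam. The projection is real
#' and centro-symmetric, so the initial phases are 0 or pi.
#'
#' @param tube A `tube_model`.
#' @param grid The real-space `grid2d` conjugate to the data.
#' @param support A `support_mask` (supplies the y Gaussian).
#' @return Complex matrix (centered layout: origin at the center pixel).
#' @export
tube_initial_field <- function(tube, grid, support = support_mask()) {
  proj <- tube_projection(tube, grid)
  p <- support_profiles(support, grid)
  cfft2(proj$density * p$sy)
}

# first local maximum along +q_x of an equatorial amplitude profile, beyond
# `min_px` pixels from the center; NA if none
first_equatorial_peak <- function(amps, beam_center, min_px = 2L,
                                  good = NULL) {
  row <- amps[beam_center[1], ]
  if (!is.null(good)) row[!good[beam_center[1], ]] <- NA
  m <- length(row)
  idx <- (beam_center[2] + min_px):(m - 1L)
  for (j in idx) {
    y1 <- row[j - 1]; y2 <- row[j]; y3 <- row[j + 1]
    if (any(!is.finite(c(y1, y2, y3)))) next
    if (y2 >= y1 && y2 >= y3 && y2 > 0) return(j)
  }
  NA_integer_
}

#' Fill the unmeasured central beam from the tube model
#'
#' Inside the fill radius, amplitudes are replaced by the tube model's,
#' scaled so the tube's first equatorial peak matches the measured amplitude
#' of the corresponding experimental peak along the equator; outside, the
#' measured values are untouched.
#'
#' @param amplitudes Matrix of measured amplitudes (centered layout).
#' @param tube_field Complex field from [tube_initial_field()].
#' @param fill_radius Fill radius in pixels from the beam center.
#' @param beam_center Beam center `(row, col)`.
#' @param good Optional logical matrix of measured (unmasked) pixels.
#' @return List: `amplitudes` (filled matrix), `scale` (the factor s),
#'   `filled` (logical matrix of replaced pixels).
#' @export
fill_central_beam <- function(amplitudes, tube_field, fill_radius,
                              beam_center, good = NULL) {
  a_tube <- Mod(tube_field)
  jt <- first_equatorial_peak(a_tube, beam_center,
                              min_px = max(2L, ceiling(fill_radius)))
  if (is.na(jt))
    stop("no identifiable first equatorial peak in the tube model",
         call. = FALSE)
  # measured peak nearest the theoretical one (search a small window; use the
  # mean of the two Friedel-related sides for robustness)
  win <- 4L
  m <- ncol(amplitudes)
  js <- max(2L, jt - win):min(m - 1L, jt + win)
  meas_row <- amplitudes[beam_center[1], ]
  if (!is.null(good)) meas_row[!good[beam_center[1], ]] <- NA
  mate <- 2L * beam_center[2] - js
  both <- (meas_row[js] + meas_row[mate]) / 2
  if (all(!is.finite(both)))
    stop("no measurable equatorial peak near the tube model's first peak",
         call. = FALSE)
  je <- js[which.max(both)]
  s <- (meas_row[je] + meas_row[2L * beam_center[2] - je]) / 2 /
    a_tube[beam_center[1], jt]
  rad <- sqrt(outer((seq_len(nrow(amplitudes)) - beam_center[1])^2,
                    (seq_len(m) - beam_center[2])^2, `+`))
  filled <- rad <= fill_radius
  out <- amplitudes
  out[filled] <- s * a_tube[filled]
  list(amplitudes = out, scale = as.numeric(s), filled = filled)
}

# cyclic 180-degree rotation about the center pixel (consistent with the
# periodic DFT layout)
rot180_cyclic <- function(m) {
  n <- nrow(m); p <- ncol(m)
  ci <- floor(n / 2) + 1L; cj <- floor(p / 2) + 1L
  ri <- (2L * (ci - 1L) - (seq_len(n) - 1L)) %% n + 1L
  rj <- (2L * (cj - 1L) - (seq_len(p) - 1L)) %% p + 1L
  m[ri, rj]
}

#' Iterative phase retrieval with tailored supports
#'
#' Recovers a real-space 2D projection from diffraction amplitudes by cycling
#' between the measured-modulus constraint in reciprocal space and the
#' support constraint in real space: each cycle takes an inverse transform of
#' the measured amplitudes with the current phases, keeps the real part,
#' multiplies by the support mask, (every `symmetry_period` cycles) averages
#' the object with its 180-degree rotation, and forward transforms to obtain
#' new phases. Initial phases come from the featureless-tube projection; the
#' unmeasurable central beam is filled from the scaled tube model. After the
#' final cycle the object is divided by the axial (y) Gaussian to undo that
#' part of the support (clipped where the Gaussian is below 1e-3).
#'
#' @param pattern A `diffraction_image` (intensities; amplitudes are their
#'   square root) or a numeric matrix of amplitudes via
#'   `input = "amplitude"`. The beam center must be the grid's center pixel.
#' @param config A `retrieval_config`.
#' @param support A `support_mask`.
#' @param input `"intensity"` (default) or `"amplitude"`.
#' @return An object of class `projection_density`: `density` (the final,
#'   y-corrected object), `density_supported` (before the y inversion),
#'   `grid`, `error_history` (per-cycle relative amplitude misfit on
#'   measured pixels), `support`, `config`, `fill` (central-fill info) and
#'   `diverged` flag.
#' @export
retrieve <- function(pattern, config = retrieval_config(),
                     support = support_mask(), input = "intensity") {
  stopifnot(inherits(pattern, "diffraction_image"))
  q_step <- pattern$q_step
  good <- !pattern$mask
  bc <- pattern$beam_center
  amps <- if (input == "amplitude") pattern$intensity else sqrt(pattern$intensity)
  if (any(!is.finite(amps[good])) || any(amps[good] < 0))
    stop("amplitudes must be finite and non-negative", call. = FALSE)
  n <- nrow(amps); m <- ncol(amps)
  ctr <- c(floor(n / 2) + 1L, floor(m / 2) + 1L)
  if (!isTRUE(all.equal(as.numeric(bc), as.numeric(ctr))))
    stop("beam center must sit on the grid's center pixel", call. = FALSE)
  grid <- grid2d(n, m, pixel_size = 1 / (n * q_step))

  tube_field <- tube_initial_field(config$init_tube, grid, support)
  fill_tube <- if (is.null(config$fill_tube)) config$init_tube
               else config$fill_tube
  fill_field <- if (is.null(config$fill_tube)) tube_field
                else tube_initial_field(fill_tube, grid, support)
  a_fill <- Mod(fill_field)
  fill_q <- config$central_fill_radius
  jt <- first_equatorial_peak(a_fill, ctr)
  if (is.null(fill_q)) {
    if (is.na(jt)) stop("tube model has no equatorial peak on this grid",
                        call. = FALSE)
    fill_px <- (jt - ctr[2]) / 2
  } else fill_px <- fill_q / q_step
  fill <- fill_central_beam(amps, fill_field, fill_px, ctr, good)
  a_data <- fill$amplitudes
  measured <- (good | fill$filled)
  free <- !measured
  norm_meas <- sqrt(sum(a_data[measured]^2))

  smat <- support_matrix(support, grid)
  phases <- Arg(tube_field)
  if (config$phase_perturbation > 0) {
    old_rng <- .save_rng_state()
    set.seed(config$seed)
    phases <- phases + matrix(runif(n * m, -pi, pi), n, m) *
      config$phase_perturbation
    .restore_rng_state(old_rng)
  }
  model_f <- fill$scale * fill_field  # free-pixel model for cycle 1
  err <- numeric(config$n_cycles)
  obj <- NULL
  for (cyc in seq_len(config$n_cycles)) {
    g <- matrix(complex(modulus = a_data, argument = phases), n, m)
    g[free] <- model_f[free]
    obj <- cfft2(g, inverse = TRUE)
    if (config$real_object) obj <- Re(obj)
    if (config$positivity) obj[obj < 0] <- 0
    obj <- obj * smat
    if (config$symmetry_period > 0 && cyc %% config$symmetry_period == 0)
      obj <- (obj + rot180_cyclic(obj)) / 2
    f <- cfft2(obj)
    phases <- Arg(f)
    model_f <- f
    err[cyc] <- sqrt(sum((Mod(f)[measured] - a_data[measured])^2)) / norm_meas
  }
  # final object consistent with the data and the last phases
  g <- matrix(complex(modulus = a_data, argument = phases), n, m)
  g[free] <- model_f[free]
  obj <- cfft2(g, inverse = TRUE)
  if (config$real_object) obj <- Re(obj)
  obj <- obj * smat
  obj <- (obj + rot180_cyclic(obj)) / 2

  p <- support_profiles(support, grid)
  sy <- p$sy
  inv <- ifelse(sy >= 1e-3, 1 / sy, 0)
  density <- obj * inv  # row-wise: sy varies along rows
  diverged <- err[config$n_cycles] > 10 * err[1]
  structure(list(density = density, density_supported = obj, grid = grid,
                 error_history = err, support = support, config = config,
                 fill = list(scale = fill$scale, radius_px = fill_px,
                             n_filled = sum(fill$filled)),
                 diverged = diverged),
            class = "projection_density")
}

#' @export
print.projection_density <- function(x, ...) {
  cat(sprintf(
    "<projection_density> %d x %d px, %.3g nm/px; final misfit %.3g%s\n",
    x$grid$n_rows, x$grid$n_cols, x$grid$pixel_size,
    tail(x$error_history, 1), if (x$diverged) " [DIVERGED]" else ""))
  invisible(x)
}

#' Robustness scan over starting tube COM radii
#'
#' Repeats the retrieval from featureless tubes of varying center-of-mass
#' radius (fixed 4 nm wall), recording for each start the final peak-to-peak
#' separation of the reconstruction and the Pearson correlation between the
#' reconstruction's scattering intensities and the measured low-q equatorial
#' intensities. Diverged or degenerate starts are flagged and excluded from
#' the basin statistic by the caller.
#'
#' @param pattern A `diffraction_image`.
#' @param start_radii COM radii (nm) of the starting tubes.
#' @param config Base `retrieval_config` (its `init_tube` is replaced per
#'   start).
#' @param support A `support_mask`.
#' @param wall Tube wall thickness, nm.
#' @param q_max_corr Upper q (nm^-1) of the equatorial band used for the
#'   Pearson correlation.
#' @return Data frame: `start_com_radius`, `peak_to_peak`, `pearson_r`,
#'   `final_misfit`, `flagged`.
#' @export
com_radius_scan <- function(pattern, start_radii = 9:16,
                            config = retrieval_config(),
                            support = support_mask(), wall = 4,
                            q_max_corr = 0.15) {
  rows <- lapply(start_radii, function(r) {
    cfg <- config
    if (is.null(cfg$fill_tube)) cfg$fill_tube <- config$init_tube
    res <- tryCatch({
      cfg$init_tube <- tube_from_com_radius(r, wall)
      retrieve(pattern, cfg, support)
    }, error = function(e) NULL)
    if (is.null(res))
      return(data.frame(start_com_radius = r, peak_to_peak = NA_real_,
                        pearson_r = NA_real_, final_misfit = NA_real_,
                        flagged = TRUE))
    pp <- tryCatch(peak_to_peak(res), error = function(e) NA_real_)
    # correlate reconstruction intensities with measured equatorial band
    f2 <- Mod(cfft2(res$density_supported))^2
    bc <- pattern$beam_center
    qx <- (seq_len(ncol(f2)) - bc[2]) * pattern$q_step
    sel <- which(abs(qx) > res$fill$radius_px * pattern$q_step &
                 abs(qx) <= q_max_corr)
    sel <- sel[!pattern$mask[bc[1], sel]]
    r_p <- if (length(sel) > 3)
      stats::cor(f2[bc[1], sel], pattern$intensity[bc[1], sel]) else NA_real_
    data.frame(start_com_radius = r, peak_to_peak = pp, pearson_r = r_p,
               final_misfit = tail(res$error_history, 1),
               flagged = res$diverged || !is.finite(pp))
  })
  do.call(rbind, rows)
}
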