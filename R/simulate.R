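#' Default simulation detector
#'
#' A monolithic 400 x 400 grid standing in for the central region of a tiled
#' pixel-array detector at 3x pixel binning (330 um effective pitch, 565 mm
#' distance, 2.07 Angstrom). The resulting q-range (about 0.56 nm^-1 at the
#' edge) covers both the 4 nm and the 2 nm layer lines, and the conjugate
#' real-space field (about 354 nm) comfortably holds the 159 nm FWHM axial
#' illumination profile.
#'
#' @param n_rows Detector size in pixels.
#' @param ... Passed on to [detector_geometry()].
#' @return A `detector_geometry`.
#' @export
default_sim_geometry <- function(n_rows = 400, ...) {
  detector_geometry(n_rows = n_rows, pixel_pitch = 330, distance = 565,
                    wavelength = 2.07, ...)
}

# spatial-frequency step per pixel of a detector, taken at the beam center
geometry_q_step <- function(geometry) {
  q_of_pixel(geometry, geometry$beam_center[1], geometry$beam_center[2] + 1)
}

# real-space grid conjugate to a detector's linear-q pixel raster
geometry_real_grid <- function(geometry) {
  qs <- geometry_q_step(geometry)
  grid2d(geometry$n_rows, geometry$n_cols,
         pixel_size = 1 / (geometry$n_rows * qs))
}

#' Shot-generation configuration
#'
#' Statistical structure of one serial-XFEL exposure series: roughly twenty
#' flow-aligned filaments per hit, 5 degree alignment jitter about a
#' per-shot jet angle, solution background, Poisson photon noise, and a
#' mixed 11-16-protofilament population. Misses (background-only shots) and
#' jet-edge streak artefacts emulate the exposures that the sorting stage
#' must reject.
#'
#' @param n_filaments_mean Mean filament count per hit (Poisson).
#' @param alignment_sigma Within-shot filament alignment jitter, deg.
#' @param jet_angle_mean,jet_angle_sigma Per-shot equatorial-line angle
#'   distribution, deg (mod 180).
#' @param photons_per_pulse Incident photons per pulse.
#' @param scattering_efficiency Detected photons per filament per incident
#'   photon; with the defaults each filament contributes ~5e4 detected
#'   photons.
#' @param background_level Mean solution-background photons per unmasked
#'   pixel.
#' @param background_scale_q Decay scale (nm^-1) of the smooth isotropic
#'   background profile.
#' @param protofilament_mixture Named weights over the 11-16-protofilament
#'   forms; must sum to 1.
#' @param miss_fraction Fraction of background-only shots.
#' @param edge_streak_fraction Fraction of shots dominated by a jet-edge
#'   streak.
#' @param beamstop_radius_q Central masked radius (nm^-1), the unmeasurable
#'   forward-scattering region.
#' @param axial_rotations Number of precomputed filament rotations about the
#'   helical axis (per-filament rotation is drawn from this set).
#' @param beam_fwhm_y Axial FWHM (nm) of the illumination profile applied to
#'   each filament projection.
#' @param poisson_noise Apply Poisson noise (disable for noise-free checks).
#' @param random_seed Root seed; per-shot seeds are derived by counter.
#' @return An object of class `shot_config`.
#' @export
shot_config <- function(n_filaments_mean = 20, alignment_sigma = 5,
                        jet_angle_mean = 90, jet_angle_sigma = 25,
                        photons_per_pulse = photons_from_pulse_energy(2, 6),
                        scattering_efficiency = 2.5e-8,
                        background_level = 1,
                        background_scale_q = 0.15,
                        protofilament_mixture = c(`11` = 0.02, `12` = 0.08,
                                                  `13` = 0.40, `14` = 0.35,
                                                  `15` = 0.10, `16` = 0.05),
                        miss_fraction = 0.5, edge_streak_fraction = 0.1,
                        beamstop_radius_q = 0.02, axial_rotations = 16,
                        beam_fwhm_y = 159, poisson_noise = TRUE,
                        random_seed = 1L) {
  stopifnot(n_filaments_mean >= 0, alignment_sigma >= 0,
            photons_per_pulse >= 0, scattering_efficiency >= 0,
            background_level >= 0, miss_fraction >= 0, miss_fraction <= 1,
            edge_streak_fraction >= 0, miss_fraction + edge_streak_fraction <= 1,
            axial_rotations >= 1)
  w <- protofilament_mixture
  if (abs(sum(w) - 1) > 1e-8)
    stop("protofilament mixture weights must sum to 1", call. = FALSE)
  structure(list(n_filaments_mean = n_filaments_mean,
                 alignment_sigma = alignment_sigma,
                 jet_angle_mean = jet_angle_mean,
                 jet_angle_sigma = jet_angle_sigma,
                 photons_per_pulse = photons_per_pulse,
                 scattering_efficiency = scattering_efficiency,
                 background_level = background_level,
                 background_scale_q = background_scale_q,
                 protofilament_mixture = w,
                 miss_fraction = miss_fraction,
                 edge_streak_fraction = edge_streak_fraction,
                 beamstop_radius_q = beamstop_radius_q,
                 axial_rotations = as.integer(axial_rotations),
                 beam_fwhm_y = beam_fwhm_y,
                 poisson_noise = poisson_noise,
                 random_seed = as.integer(random_seed)),
            class = "shot_config")
}

#' @export
print.shot_config <- function(x, ...) {
  cat(sprintf(
    "<shot_config> ~%g filaments/hit, jitter %g deg, jet %g +/- %g deg\n  miss %.0f%%, streak %.0f%%, background %g ph/px, seed %d\n",
    x$n_filaments_mean, x$alignment_sigma, x$jet_angle_mean,
    x$jet_angle_sigma, 100 * x$miss_fraction, 100 * x$edge_streak_fraction,
    x$background_level, x$random_seed))
  invisible(x)
}

# helical radius of an N-protofilament lattice, proportional to the 14-pf
# validation radius of 11.2 nm
pf_helical_radius <- function(n_pf) 11.2 * n_pf / 14

# sphere-helix lattice for an N-protofilament filament spanning the grid
pf_model <- function(n_pf, grid) {
  field_y <- grid$n_rows * grid$pixel_size
  pitch_nm <- 3 * 4
  # leave margin for the start offsets (2 spheres) and the sphere radius on
  # the asymmetric even-sized grid
  n_turns <- max(3L, floor((field_y - 24) / pitch_nm))
  sphere_helix_model(sphere_diameter = 4, spheres_per_turn = n_pf,
                     pitch_spheres_per_turn = 3,
                     helical_radius = pf_helical_radius(n_pf),
                     n_turns = n_turns, n_starts = 3)
}

#' Simulate a diffraction pattern from a projection
#'
#' Squared modulus of the centered 2D Fourier transform of the projected
#' density, scaled to a photon budget. Before noise the result obeys Friedel
#' symmetry exactly. If a detector geometry is supplied, the pattern is
#' cropped to the detector raster (which must subdivide the projection grid's
#' reciprocal raster exactly) and panel-gap/bad-pixel masks are applied.
#'
#' @param projection A `projection_image`.
#' @param geometry Optional `detector_geometry`.
#' @param photons Total photons over the (unmasked) pattern; `NULL` keeps the
#'   raw squared modulus.
#' @return A `diffraction_image`.
#' @export
simulate_pattern <- function(projection, geometry = NULL, photons = NULL) {
  dens <- projection$density
  # oversampling is required across the helix (x): the object must occupy at
  # most half the field there; along the axis the illumination envelope
  # provides the falloff, so full-height filaments are legitimate
  nz <- which(dens > 1e-12 * max(dens), arr.ind = TRUE)
  if (nrow(nz) > 0 && diff(range(nz[, 2])) + 1 > ncol(dens) / 2)
    stop("object too wide for the grid: oversampling condition violated",
         call. = FALSE)
  inten <- Mod(cfft2(dens))^2
  qs <- unname(grid_q_step(projection$grid)["col"])
  mask <- NULL
  if (!is.null(geometry)) {
    gq <- geometry_q_step(geometry)
    if (abs(gq - qs) > 1e-6 * qs)
      stop("projection grid is not conjugate to the detector raster",
           call. = FALSE)
    n <- geometry$n_rows; m <- geometry$n_cols
    c0 <- c(floor(nrow(inten) / 2) + 1, floor(ncol(inten) / 2) + 1)
    rows <- (c0[1] - floor(n / 2)):(c0[1] - floor(n / 2) + n - 1)
    cols <- (c0[2] - floor(m / 2)):(c0[2] - floor(m / 2) + m - 1)
    inten <- inten[rows, cols]
    mask <- geometry$panel_gap_mask | geometry$bad_pixel_mask
  }
  if (!is.null(photons)) {
    keep <- if (is.null(mask)) sum(inten) else sum(inten[!mask])
    if (keep > 0) inten <- inten * (photons / keep)
  }
  diffraction_image(inten, qs, mask = mask, geometry = geometry)
}

# Precompute the per-(protofilament, axial rotation) single-filament pattern
# library, the normalized background profile, and the static mask for a
# config/geometry pair. Patterns are unit-sum intensities on the full grid.
pattern_library <- function(config, geometry) {
  grid <- geometry_real_grid(geometry)
  beam <- exp(-4 * log(2) * (grid_y(grid) / config$beam_fwhm_y)^2)
  pf_types <- as.integer(names(config$protofilament_mixture)[
    config$protofilament_mixture > 0])
  n_rot <- config$axial_rotations
  angles <- seq(0, 360, length.out = n_rot + 1)[seq_len(n_rot)]
  patterns <- list()
  for (pf in pf_types) {
    model <- pf_model(pf, grid)
    centers <- build_sphere_helix(model)
    mats <- vector("list", n_rot)
    for (k in seq_len(n_rot)) {
      proj <- project_model(centers, model$sphere_diameter, grid, angles[k])
      dens <- proj$density * beam
      p <- Mod(cfft2(dens))^2
      mats[[k]] <- p / sum(p)
    }
    patterns[[as.character(pf)]] <- mats
  }
  qpix <- geometry_q_step(geometry) *
    sqrt(outer((seq_len(geometry$n_rows) - geometry$beam_center[1])^2,
               (seq_len(geometry$n_cols) - geometry$beam_center[2])^2, `+`))
  static_mask <- geometry$panel_gap_mask | geometry$bad_pixel_mask |
    (qpix <= config$beamstop_radius_q)
  bg <- exp(-qpix / config$background_scale_q)
  bg <- bg / mean(bg[!static_mask])
  list(grid = grid, patterns = patterns, pf_types = pf_types,
       background = bg, static_mask = static_mask, qpix = qpix,
       photons_per_filament = config$photons_per_pulse *
         config$scattering_efficiency)
}

# deterministic per-shot seed derived from the root seed by counter
shot_seed <- function(config, shot_id) {
  (config$random_seed * 48271 + shot_id * 2654435761) %% 2147483647
}

#' Simulate one XFEL exposure
#'
#' Draws the shot class (hit, miss, or jet-edge streak), a per-shot jet
#' angle, a Poisson filament count and per-filament orientations (in-plane
#' jet angle + alignment jitter; discretized rotation about the filament's
#' own axis; protofilament number from the configured mixture), sums
#' single-filament intensities incoherently, adds the smooth isotropic
#' solution background, applies Poisson noise, and zeroes panel-gap, bad and
#' beamstop pixels. Bit-reproducible for a given config and shot id.
#'
#' @param config A `shot_config`.
#' @param geometry A `detector_geometry` (default [default_sim_geometry()]).
#' @param shot_id Integer shot counter; with the config's root seed it
#'   determines the shot completely.
#' @param library Optional precomputed [pattern_library] (built on the fly if
#'   omitted; precompute it when generating many shots).
#' @return A `diffraction_image` whose `metadata` records the shot id, kind
#'   (`"hit"`, `"miss"`, `"streak"`), true jet angle, filament count and
#'   seed.
#' @export
simulate_shot <- function(config, geometry = default_sim_geometry(),
                          shot_id = 1L, library = NULL) {
  if (is.null(library)) library <- pattern_library(config, geometry)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  seed <- shot_seed(config, shot_id)
  set.seed(seed)
  n <- geometry$n_rows; m <- geometry$n_cols
  expected <- matrix(0, n, m)
  u <- runif(1)
  kind <- if (u < config$miss_fraction) "miss"
          else if (u < config$miss_fraction + config$edge_streak_fraction) "streak"
          else "hit"
  jet_angle <- NA_real_
  n_fil <- 0L
  if (kind == "hit") {
    jet_angle <- (config$jet_angle_mean +
                  rnorm(1, 0, config$jet_angle_sigma)) %% 180
    n_fil <- rpois(1, config$n_filaments_mean)
    if (n_fil == 0L) kind <- "miss"
    if (n_fil > 0L) {
      ang <- jet_angle + rnorm(n_fil, 0, config$alignment_sigma)
      pf <- sample(as.character(library$pf_types), n_fil, replace = TRUE,
                   prob = config$protofilament_mixture[
                     as.character(library$pf_types)])
      rot_idx <- sample.int(config$axial_rotations, n_fil, replace = TRUE)
      for (k in seq_len(n_fil)) {
        # kernel advances feature angles by -angle: negate (see rotate_image)
        cpp_accumulate_rotated(expected, library$patterns[[pf[k]]][[rot_idx[k]]],
                               -ang[k], geometry$beam_center[1],
                               geometry$beam_center[2],
                               library$photons_per_filament)
      }
    }
  } else if (kind == "streak") {
    streak_angle <- runif(1, 0, 180)
    th <- streak_angle * pi / 180
    dr <- seq_len(n) - geometry$beam_center[1]
    dc <- seq_len(m) - geometry$beam_center[2]
    # perpendicular distance to a line through the beam center at streak_angle
    perp <- abs(outer(dr, rep(1, m)) * cos(th) -
                outer(rep(1, n), dc) * sin(th))
    streak <- exp(-perp^2 / (2 * 1.5^2))
    streak <- streak / sum(streak)
    expected <- expected +
      streak * 50 * config$n_filaments_mean * library$photons_per_filament
  }
  expected <- expected + config$background_level * library$background
  inten <- if (config$poisson_noise) {
    matrix(rpois(length(expected), expected), n, m)
  } else expected
  inten[library$static_mask] <- 0
  diffraction_image(inten, geometry_q_step(geometry),
                    geometry$beam_center, library$static_mask, geometry,
                    metadata = list(shot_id = shot_id, kind = kind,
                                    jet_angle = jet_angle,
                                    n_filaments = n_fil, seed = seed))
}

#' Lazy source of simulated shots
#'
#' Returns a shot source: a list with elements `n`, `get(i)` (returning shot
#' `i` as a `diffraction_image`), `geometry` and `config`. Shots are
#' regenerated deterministically on demand, so arbitrarily large series
#' stream with bounded memory.
#'
#' @param config A `shot_config`.
#' @param geometry A `detector_geometry`.
#' @param n_shots Number of shots in the series.
#' @return A shot source list.
#' @export
shot_source_simulated <- function(config, geometry = default_sim_geometry(),
                                  n_shots = 100L) {
  force(config); force(geometry)
  lib_env <- new.env(parent = emptyenv())
  get_lib <- function() {
    if (is.null(lib_env$lib)) lib_env$lib <- pattern_library(config, geometry)
    lib_env$lib
  }
  list(n = as.integer(n_shots),
       get = function(i) simulate_shot(config, geometry, i, get_lib()),
       geometry = geometry, config = config)
}

#' Mixture-averaged reference projection
#'
#' The generating model's own projection: the protofilament-mixture-weighted
#' mean of axially averaged filament projections, modulated by the axial
#' illumination profile. Serves as ground truth when validating end-to-end
#' reconstructions against the generator.
#'
#' @param config A `shot_config`.
#' @param geometry A `detector_geometry`.
#' @param n_angles Axial rotation angles used in the average.
#' @return A `projection_image`.
#' @export
reference_projection <- function(config, geometry = default_sim_geometry(),
                                 n_angles = 60) {
  grid <- geometry_real_grid(geometry)
  beam <- exp(-4 * log(2) * (grid_y(grid) / config$beam_fwhm_y)^2)
  acc <- matrix(0, grid$n_rows, grid$n_cols)
  w <- config$protofilament_mixture
  for (pf in as.integer(names(w)[w > 0])) {
    model <- pf_model(pf, grid)
    centers <- build_sphere_helix(model)
    avg <- project_model_averaged(centers, model$sphere_diameter, grid,
                                  n_angles = n_angles)
    acc <- acc + w[[as.character(pf)]] * avg$density
  }
  projection_image(acc * beam, grid)
}
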