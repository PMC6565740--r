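#' Featureless tube model
#'
#' A uniform hollow cylinder used as phase-retrieval starting model and as the
#' low-resolution stand-in for a microtubule. Parameterized by inner and outer
#' diameter; the experimental defaults are 17.4 and 25.4 nm.
#'
#' @param inner_diameter,outer_diameter Tube diameters in nm.
#' @return An object of class `tube_model`.
#' @export
tube_model <- function(inner_diameter = 17.4, outer_diameter = 25.4) {
  stopifnot(inner_diameter > 0, outer_diameter > inner_diameter)
  structure(list(inner_diameter = inner_diameter,
                 outer_diameter = outer_diameter),
            class = "tube_model")
}

#' @export
print.tube_model <- function(x, ...) {
  cat(sprintf("<tube_model> inner %.3g nm, outer %.3g nm (COM radius %.3g nm)\n",
              x$inner_diameter, x$outer_diameter, com_radius(x)))
  invisible(x)
}

#' Construct a tube model from its center-of-mass radius
#'
#' Inverts the annulus COM-radius relation for a fixed wall thickness: finds
#' inner radius `a` such that the annulus `[a, a + wall]` has the requested
#' mass-weighted mean radius. Used by the phase-retrieval robustness scan,
#' which parameterizes starting tubes by COM radius at a 4 nm wall.
#'
#' @param com_radius Target COM radius in nm.
#' @param wall Wall thickness in nm (default 4, one tubulin monomer).
#' @return A `tube_model`.
#' @export
tube_from_com_radius <- function(com_radius, wall = 4) {
  stopifnot(com_radius > wall / 2, wall > 0)
  f <- function(a) {
    b <- a + wall
    2 * (b^3 - a^3) / (3 * (b^2 - a^2)) - com_radius
  }
  a <- stats::uniroot(f, c(1e-6, 2 * com_radius), tol = 1e-12)$root
  tube_model(2 * a, 2 * (a + wall))
}

#' Sphere-helix validation model
#'
#' The oversimplified microtubule used to validate the imaging chain: spheres
#' of one tubulin-monomer diameter arranged on a helical lattice. With the
#' defaults (4 nm spheres, 14 per turn, pitch of 3 spheres per turn, helical
#' radius 11.2 nm) the model has an outer tube diameter of 26.4 nm.
#'
#' The pitch of 3 monomers per turn makes the monomer lattice a 3-start helix
#' family: `n_starts = 3` (the default) places three copies of the generating
#' helix offset axially by one sphere, which closes the tube wall (vertical
#' neighbours at the 4 nm monomer repeat) exactly as in a microtubule lattice,
#' and suppresses layer lines that are not multiples of the 4 nm spacing.
#' `n_starts = 1` gives the bare generating helix.
#'
#' @param sphere_diameter Sphere (monomer) diameter, nm.
#' @param spheres_per_turn Spheres per helical turn (protofilament count).
#' @param pitch_spheres_per_turn Helical pitch, in spheres per turn.
#' @param helical_radius Radius of the sphere-center cylinder, nm.
#' @param n_turns Number of helical turns to build.
#' @param n_starts Number of interleaved helix starts (see Details).
#' @return An object of class `sphere_helix_model`.
#' @export
sphere_helix_model <- function(sphere_diameter = 4, spheres_per_turn = 14,
                               pitch_spheres_per_turn = 3,
                               helical_radius = 11.2, n_turns = 10,
                               n_starts = pitch_spheres_per_turn) {
  stopifnot(sphere_diameter > 0, spheres_per_turn >= 3,
            pitch_spheres_per_turn > 0,
            helical_radius > sphere_diameter / 2,
            n_turns >= 1, n_starts >= 1)
  structure(list(sphere_diameter = sphere_diameter,
                 spheres_per_turn = as.integer(spheres_per_turn),
                 pitch_spheres_per_turn = pitch_spheres_per_turn,
                 helical_radius = helical_radius,
                 n_turns = as.integer(n_turns),
                 n_starts = as.integer(n_starts)),
            class = "sphere_helix_model")
}

#' @export
print.sphere_helix_model <- function(x, ...) {
  cat(sprintf(
    "<sphere_helix_model> %g nm spheres, %d/turn, pitch %g/turn, R %g nm, %d turn(s), %d start(s)\n  outer diameter %.3g nm\n",
    x$sphere_diameter, x$spheres_per_turn, x$pitch_spheres_per_turn,
    x$helical_radius, x$n_turns, x$n_starts,
    outer_diameter(x)))
  invisible(x)
}

#' Outer tube diameter of a sphere-helix model
#' @param model A `sphere_helix_model`.
#' @return Outer diameter in nm (`2 * helical_radius + sphere_diameter`).
#' @export
outer_diameter <- function(model) {
  2 * model$helical_radius + model$sphere_diameter
}

#' Build sphere centers of a helical lattice
#'
#' Places sphere centers on a cylinder of the model's helical radius.
#' Consecutive spheres of one start advance by `2 * pi / spheres_per_turn`
#' azimuthally and by `pitch * axial_spacing / spheres_per_turn` axially,
#' where the axial spacing between layer repeats is the sphere diameter
#' (the 4 nm monomer repeat). Additional starts are axially offset copies
#' spaced one sphere diameter apart. The lattice is centered axially on y = 0.
#'
#' @param model A `sphere_helix_model`.
#' @param n_starts Number of helix starts; defaults to the model's field.
#' @return Numeric matrix with columns `x`, `y`, `z` (nm); `y` is the helical
#'   axis, the beam runs along `z`.
#' @export
build_sphere_helix <- function(model, n_starts = model$n_starts) {
  spt <- model$spheres_per_turn
  rise <- model$pitch_spheres_per_turn * model$sphere_diameter / spt
  n_sph <- spt * model$n_turns
  n <- seq_len(n_sph) - 1
  theta <- 2 * pi * n / spt
  y0 <- rise * n
  centers <- do.call(rbind, lapply(seq_len(n_starts) - 1, function(s) {
    cbind(x = model$helical_radius * cos(theta),
          y = y0 + s * model$sphere_diameter,
          z = model$helical_radius * sin(theta))
  }))
  centers[, "y"] <- centers[, "y"] - mean(range(centers[, "y"]))
  centers
}

# Antiderivative of the chord profile 2*sqrt(R^2 - x^2) (clamped beyond |R|);
# pixel-averaged projections are exact differences of this, which conserves
# projected mass to machine precision.
.chord_antideriv <- function(x, R) {
  xc <- pmin(pmax(x, -R), R)
  xc * sqrt(pmax(R^2 - xc^2, 0)) + R^2 * asin(xc / R)
}

#' Project a featureless tube to a 2D image
#'
#' Analytic line integral of a uniform hollow cylinder along the beam,
#' replicated along the helical (y) axis. Pixel values are exact averages of
#' the chord-length profile over the pixel width, so projected mass per row
#' equals the annulus cross-section area and the two wall maxima sit at
#' `|x| =` inner radius.
#'
#' @param model A `tube_model`.
#' @param grid A `grid2d`; its field of view must exceed the outer diameter.
#' @return A `projection_image`.
#' @export
tube_projection <- function(model, grid) {
  a <- model$inner_diameter / 2
  b <- model$outer_diameter / 2
  x <- grid_x(grid)
  half <- grid$pixel_size / 2
  if (min(x) > -b || max(x) < b)
    stop("tube wider than grid field of view", call. = FALSE)
  lo <- x - half; hi <- x + half
  prof <- ((.chord_antideriv(hi, b) - .chord_antideriv(lo, b)) -
           (.chord_antideriv(hi, a) - .chord_antideriv(lo, a))) / (2 * half)
  density <- matrix(prof, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
  projection_image(density, grid)
}

#' 2D projection image
#'
#' Container for a real-space projected density on a `grid2d`. Density is
#' non-negative projected mass in arbitrary units; `orientation` is the angle
#' (deg) of the helical axis with respect to the image y-axis.
#'
#' @param density Numeric matrix of projected density.
#' @param grid The `grid2d` the density lives on.
#' @param orientation Helical-axis angle, degrees.
#' @return An object of class `projection_image`.
#' @export
projection_image <- function(density, grid, orientation = 0) {
  stopifnot(nrow(density) == grid$n_rows, ncol(density) == grid$n_cols)
  if (any(density < -1e-9 * max(abs(density))))
    stop("projection density must be non-negative", call. = FALSE)
  structure(list(density = density, grid = grid, orientation = orientation),
            class = "projection_image")
}

#' @export
print.projection_image <- function(x, ...) {
  cat(sprintf("<projection_image> %d x %d px, %.3g nm/px, total mass %.4g\n",
              x$grid$n_rows, x$grid$n_cols, x$grid$pixel_size,
              sum(x$density)))
  invisible(x)
}

#' Project a set of spheres to a 2D image
#'
#' Each sphere contributes its projected chord-length profile: a solid sphere
#' of radius r projects to `2 * sqrt(r^2 - rho^2)` at in-plane distance `rho`
#' from its center. An optional rotation about the helical (y) axis is applied
#' to the centers before projecting along the beam (z) axis.
#'
#' @param centers Matrix of sphere centers (`x`, `y`, `z`, nm), as returned by
#'   [build_sphere_helix()].
#' @param sphere_diameter Sphere diameter, nm.
#' @param grid A `grid2d`.
#' @param rotation Rotation about the helical axis, degrees.
#' @return A `projection_image`.
#' @export
project_model <- function(centers, sphere_diameter, grid, rotation = 0) {
  r <- sphere_diameter / 2
  phi <- rotation * pi / 180
  xr <- centers[, "x"] * cos(phi) + centers[, "z"] * sin(phi)
  yr <- centers[, "y"]
  x_ax <- grid_x(grid); y_ax <- grid_y(grid)
  if (any(xr - r < min(x_ax)) || any(xr + r > max(x_ax)) ||
      any(yr - r < min(y_ax)) || any(yr + r > max(y_ax)))
    stop("sphere extends outside the grid field of view", call. = FALSE)
  px <- grid$pixel_size
  density <- matrix(0, grid$n_rows, grid$n_cols)
  w <- ceiling(r / px) + 1L
  # nearest pixel indices of each center
  ci <- round((yr - y_ax[1]) / px) + 1L
  cj <- round((xr - x_ax[1]) / px) + 1L
  off <- (-w):w
  # each sphere's sampled patch is renormalized to its exact projected mass
  # (the sphere volume), so total mass is conserved under any rotation
  vol_px <- (4 / 3) * pi * r^3 / px^2
  for (k in seq_along(xr)) {
    ii <- ci[k] + off; jj <- cj[k] + off
    ii <- ii[ii >= 1 & ii <= grid$n_rows]
    jj <- jj[jj >= 1 & jj <= grid$n_cols]
    dy2 <- (y_ax[ii] - yr[k])^2
    dx2 <- (x_ax[jj] - xr[k])^2
    rho2 <- outer(dy2, dx2, `+`)
    patch <- 2 * sqrt(pmax(r^2 - rho2, 0))
    ps <- sum(patch)
    if (ps > 0) patch <- patch * (vol_px / ps)
    density[ii, jj] <- density[ii, jj] + patch
  }
  projection_image(density, grid)
}

#' Axially averaged projection of a sphere model
#'
#' Average of single-angle projections over a full revolution about the
#' helical axis, emulating incoherent averaging over filament rotations.
#'
#' @inheritParams project_model
#' @param n_angles Number of equally spaced rotation angles (default 180).
#' @return A `projection_image`.
#' @export
project_model_averaged <- function(centers, sphere_diameter, grid,
                                   n_angles = 180) {
  angles <- seq(0, 360, length.out = n_angles + 1)[seq_len(n_angles)]
  acc <- matrix(0, grid$n_rows, grid$n_cols)
  for (a in angles)
    acc <- acc + project_model(centers, sphere_diameter, grid, a)$density
  projection_image(acc / n_angles, grid)
}

#' Center-of-mass radius
#'
#' Mass-weighted mean radial distance `sum(r * m(r)) / sum(m(r))`, the
#' quantity used to parameterize tube starting models. For a uniform annulus
#' `[a, b]` it equals `2 (b^3 - a^3) / (3 (b^2 - a^2))`.
#'
#' @param x A `tube_model`, or a numeric vector of radii (nm) with masses in
#'   `mass`.
#' @param ... Passed to methods.
#' @return COM radius in nm.
#' @export
com_radius <- function(x, ...) UseMethod("com_radius")

#' @rdname com_radius
#' @export
com_radius.tube_model <- function(x, ...) {
  a <- x$inner_diameter / 2
  b <- x$outer_diameter / 2
  2 * (b^3 - a^3) / (3 * (b^2 - a^2))
}

#' @rdname com_radius
#' @param mass Non-negative masses, one per radius.
#' @export
com_radius.numeric <- function(x, mass, ...) {
  stopifnot(length(x) == length(mass), all(mass >= 0))
  tot <- sum(mass)
  if (tot <= 0) stop("zero total mass: COM radius undefined", call. = FALSE)
  sum(x * mass) / tot
}

#' COM radius of an atomic coordinate set about its helical axis
#'
#' Takes the principal axis of the (mass-weighted) coordinates as the helical
#' axis and returns the mass-weighted mean distance from it. Accepts any
#' n x 3 coordinate matrix (e.g. the `xyz` coordinates of a PDB/mmCIF model
#' read with an external reader); with `masses = NULL` all atoms weigh
#' equally.
#'
#' @param coords Numeric matrix (n x 3) of atomic coordinates, nm or any
#'   consistent length unit.
#' @param masses Optional atomic masses.
#' @return COM radius in the units of `coords`.
#' @export
com_radius_coords <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, nrow(coords) >= 3)
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  stopifnot(length(masses) == nrow(coords), all(masses >= 0), sum(masses) > 0)
  ctr <- colSums(coords * masses) / sum(masses)
  cc <- sweep(coords, 2, ctr)
  axis <- stats::prcomp(cc, center = FALSE)$rotation[, 1]
  along <- as.vector(cc %*% axis)
  perp2 <- rowSums(cc^2) - along^2
  com_radius.numeric(sqrt(pmax(perp2, 0)), masses)
}
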