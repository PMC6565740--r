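test_that("tube projection peaks at the inner radius and conserves mass", {
  tm <- tube_model(17.4, 25.4)
  g <- grid2d(8, 640, pixel_size = 0.1)
  tp <- tube_projection(tm, g)

  # two wall maxima separated by the inner diameter (sub-pixel refined; the
  # one-sided cusp of the annulus projection biases any quadratic
  # refinement a fraction of a nm outward, independent of pixel size)
  pp <- peak_to_peak(tp, y_halfwidth = Inf)
  expect_lt(abs(pp - 17.4), 0.5)

  # pixel-averaged analytic integration conserves projected mass exactly
  area <- pi * (12.7^2 - 8.7^2)
  expect_equal(sum(tp$density[1, ]) * g$pixel_size, area, tolerance = 1e-12)

  # mass conservation on the coarser default-style grid too
  g2 <- grid2d(8, 128, pixel_size = 0.5)
  tp2 <- tube_projection(tm, g2)
  expect_equal(sum(tp2$density[1, ]) * 0.5, area, tolerance = 1e-12)

  # thin-shell limit peaks at the outer radius
  shell <- tube_projection(tube_model(25.0, 25.4), g)
  pp_shell <- peak_to_peak(shell, y_halfwidth = Inf)
  expect_lt(abs(pp_shell - 25.2), 2 * g$pixel_size)

  expect_error(tube_projection(tube_model(30, 70), grid2d(16, 16, 0.5)),
               "wider than grid")
})

test_that("tube projection agrees with a voxelized 3D oracle", {
  tm <- tube_model(17.4, 25.4)
  g <- grid2d(8, 128, pixel_size = 0.25)
  tp <- tube_projection(tm, g)
  # oracle: fine voxelization of the annulus summed along the beam, with
  # the pixel's x-extent subdivided to match the pixel-averaged projection
  x <- (seq_len(g$n_cols) - g$center[2]) * g$pixel_size
  h <- 0.1
  z <- seq(-13 + h / 2, 13, by = h)
  sub <- seq(-g$pixel_size / 2, g$pixel_size / 2, length.out = 9)
  a <- 8.7; b <- 12.7
  oracle <- vapply(x, function(xi) {
    mean(vapply(xi + sub, function(xs) {
      r2 <- xs^2 + z^2
      sum(r2 >= a^2 & r2 <= b^2) * h
    }, numeric(1)))
  }, numeric(1))
  sel <- abs(x) < 12  # away from the tangent singularity at the outer edge
  expect_lt(max(abs(tp$density[1, sel] - oracle[sel])) / max(oracle), 0.01)
})

test_that("COM radius closed form, inversion and coordinate method agree", {
  tm <- tube_model(17.4, 25.4)
  a <- 8.7; b <- 12.7
  expect_equal(com_radius(tm), 2 * (b^3 - a^3) / (3 * (b^2 - a^2)),
               tolerance = 1e-12)
  expect_equal(com_radius(tm), 10.8246, tolerance = 1e-4)

  # numeric-integration oracle over the annulus
  r <- seq(a, b, length.out = 20001)
  m <- r  # annulus mass density per radius ~ r
  expect_equal(com_radius(r, m), com_radius(tm), tolerance = 1e-5)

  # thin shell at radius R has COM radius R
  expect_equal(com_radius(rep(10, 5), rep(1, 5)), 10)
  expect_error(com_radius(c(1, 2), c(0, 0)), "zero total mass")

  # round trip through the fixed-wall inversion
  for (cr in c(9, 11.5, 14))
    expect_equal(com_radius(tube_from_com_radius(cr, 4)), cr,
                 tolerance = 1e-9)

  # synthetic atomic set: points on a cylinder about a tilted axis
  set.seed(1)
  n <- 4000
  theta <- runif(n, 0, 2 * pi)
  yy <- runif(n, -80, 80)
  pts <- cbind(11.2 * cos(theta), yy, 11.2 * sin(theta))
  rot <- cbind(c(1, 0, 0), c(0, cos(0.3), sin(0.3)), c(0, -sin(0.3), cos(0.3)))
  expect_equal(com_radius_coords(pts %*% rot), 11.2, tolerance = 0.005)
})

test_that("sphere-helix lattice geometry matches its construction rules", {
  m <- sphere_helix_model()
  expect_equal(outer_diameter(m), 26.4)

  cen1 <- build_sphere_helix(sphere_helix_model(n_turns = 1), n_starts = 1)
  expect_equal(nrow(cen1), 14)

  cen <- build_sphere_helix(m)
  expect_equal(nrow(cen), 14 * m$n_turns * 3)
  # all centers on the helical cylinder to machine precision
  expect_lt(max(abs(cen[, "x"]^2 + cen[, "z"]^2 - 11.2^2)), 1e-10)

  # consecutive spheres of one start: azimuthal step 2 pi / 14, axial rise
  # pitch * diameter / 14
  c1 <- build_sphere_helix(m, n_starts = 1)
  expect_equal(diff(c1[1:2, "y"]), 3 * 4 / 14, tolerance = 1e-12)
  ang <- atan2(c1[, "z"], c1[, "x"])
  expect_equal((ang[2] - ang[1]) %% (2 * pi), 2 * pi / 14, tolerance = 1e-12)

  expect_error(sphere_helix_model(sphere_diameter = -1))
  expect_error(sphere_helix_model(spheres_per_turn = 2))
  expect_error(sphere_helix_model(helical_radius = 1))
})

test_that("sphere projection reproduces the chord profile and conserves mass", {
  g <- grid2d(48, 48, pixel_size = 0.25)
  cen <- cbind(x = 0, y = 0, z = 0)
  pr <- project_model(cen, 4, g)
  # peak value = sphere diameter (unit density), full width = 4 nm
  peak <- max(pr$density)
  expect_lt(abs(peak - 4) / 4, 0.02)
  nz <- range(which(pr$density[g$center[1], ] > 1e-9))
  expect_lt(abs(diff(nz) * g$pixel_size - 4), 3 * g$pixel_size)
  # rotational symmetry of a single sphere
  expect_equal(pr$density, t(pr$density), tolerance = 1e-12)

  # projected mass conserved under rotation of a full model
  gm <- grid2d(120, 120, pixel_size = 0.5)
  model <- sphere_helix_model(n_turns = 3)
  centers <- build_sphere_helix(model)
  m0 <- sum(project_model(centers, 4, gm, 0)$density)
  for (ang in c(17.3, 66, 123.4)) {
    ma <- sum(project_model(centers, 4, gm, ang)$density)
    expect_lt(abs(ma - m0) / m0, 1e-6)
  }

  expect_error(project_model(cbind(x = 100, y = 0, z = 0), 4, g),
               "outside the grid")
})

test_that("projections at different axial rotations differ but share mass", {
  gm <- grid2d(120, 120, pixel_size = 0.5)
  model <- sphere_helix_model(n_turns = 3)
  centers <- build_sphere_helix(model)
  p0 <- project_model(centers, 4, gm, 0)
  p66 <- project_model(centers, 4, gm, 66)
  expect_gt(max(abs(p0$density - p66$density)) / max(p0$density), 0.05)
  expect_lt(abs(sum(p0$density) - sum(p66$density)) / sum(p0$density), 1e-6)
})

test_that("axially averaged projection is left-right symmetric", {
  gm <- grid2d(100, 100, pixel_size = 0.5)
  model <- sphere_helix_model(n_turns = 2)
  centers <- build_sphere_helix(model)
  avg <- project_model_averaged(centers, 4, gm, n_angles = 360)
  d <- avg$density
  mirrored <- d[, ncol(d):1]
  # mirror about the helix axis column; center column c maps to 2c - j
  c0 <- gm$center[2]
  cols <- 2:(2 * c0 - 2)
  refl <- d[, 2 * c0 - cols]
  expect_lt(max(abs(d[, cols] - refl)) / max(d), 0.02)
})
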