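# Shared fixtures and small independent oracles, built in code at test time.

# cache for expensive fixtures shared across test files
.fixture_env <- new.env(parent = emptyenv())

memoize <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# a clean (gapless) small detector for fast simulation tests
clean_geometry <- function(n = 200) {
  default_sim_geometry(n_rows = n, gap_half_width = 0, bad_pixel_fraction = 0)
}

# noise-free axially averaged single-protofilament-type pattern: the mean of
# the pattern library over rotations, as an intensity image
averaged_pattern <- function(pf = 14, geometry = default_sim_geometry(
                               gap_half_width = 0, bad_pixel_fraction = 0)) {
  key <- sprintf("avg_pattern_%d_%d", pf, geometry$n_rows)
  memoize(key, function() {
    cfg <- shot_config(protofilament_mixture = stats::setNames(1, pf),
                       axial_rotations = 16)
    lib <- helixcdi:::pattern_library(cfg, geometry)
    pats <- lib$patterns[[as.character(pf)]]
    inten <- Reduce(`+`, pats) / length(pats)
    diffraction_image(inten, helixcdi:::geometry_q_step(geometry))
  })
}

# brute-force angular Radon oracle: mean bilinear-sampled intensity along a
# line through the beam center, scanned on a 0.1 degree grid
brute_force_equatorial_angle <- function(image, annulus = c(0.05, 0.30),
                                         step = 0.1) {
  qs <- image$q_step
  bc <- image$beam_center
  radii <- seq(annulus[1] / qs, annulus[2] / qs, by = 0.7)
  radii <- c(-radii, radii)
  angles <- seq(0, 180 - step, by = step)
  inten <- image$intensity
  n <- nrow(inten); m <- ncol(inten)
  best <- -Inf; best_angle <- NA
  for (a in angles) {
    th <- a * pi / 180
    rr <- bc[1] + radii * sin(th)
    cc <- bc[2] + radii * cos(th)
    ok <- rr >= 1 & rr <= n - 1 & cc >= 1 & cc <= m - 1
    r0 <- floor(rr[ok]); c0 <- floor(cc[ok])
    fr <- rr[ok] - r0; fc <- cc[ok] - c0
    i00 <- (c0 - 1) * n + r0
    v <- (1 - fr) * (1 - fc) * inten[i00] + fr * (1 - fc) * inten[i00 + 1] +
      (1 - fr) * fc * inten[i00 + n] + fr * fc * inten[i00 + n + 1]
    sc <- mean(v)
    if (sc > best) { best <- sc; best_angle <- a }
  }
  best_angle
}

# adjusted Rand index between two labelings (closed form on the
# contingency table)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# angular difference on the 180-degree circle
angle_diff_180 <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}
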