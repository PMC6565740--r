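test_that("shot statistics are deterministic and rotation-invariant", {
  # odd-sized image centered on its middle pixel so a 90-degree rotation
  # maps the pixel raster onto itself
  n <- 129
  set.seed(42)
  inten <- matrix(rpois(n * n, 3), n, n)
  img <- diffraction_image(inten, q_step = 0.004, beam_center = c(65, 65))
  st <- shot_statistics(img, ctx = sort_context(img, use_central_panels = FALSE))
  expect_equal(st$total_intensity, sum(inten))

  rot90 <- t(inten)[n:1, ]
  img90 <- diffraction_image(rot90, q_step = 0.004, beam_center = c(65, 65))
  st90 <- shot_statistics(img90,
                          ctx = sort_context(img90, use_central_panels = FALSE))
  expect_equal(st90$total_intensity, st$total_intensity)
  expect_equal(st90$anisotropy_score, st$anisotropy_score, tolerance = 1e-10)
  expect_equal(st90$radial_profile_deviation, st$radial_profile_deviation,
               tolerance = 1e-10)
  expect_equal(st90$edge_streak_score, st$edge_streak_score, tolerance = 1e-10)

  zero <- diffraction_image(matrix(0, 65, 65), q_step = 0.004)
  expect_equal(shot_statistics(zero)$total_intensity, 0)

  full <- diffraction_image(matrix(0, 33, 33), q_step = 0.004,
                            mask = matrix(TRUE, 33, 33))
  expect_error(shot_statistics(full), "fully masked")
})

# labelled synthetic mix (40 filament shots, 35 solution-only, 25 jet-edge
# streaks) shared by the streak-score and rejection tests
mixed_shot_set <- function() {
  memoize("mixed_shot_set", function() {
    geom <- default_sim_geometry()
    hit_cfg <- shot_config(miss_fraction = 0, edge_streak_fraction = 0,
                           random_seed = 17)
    miss_cfg <- shot_config(miss_fraction = 1, edge_streak_fraction = 0,
                            random_seed = 18)
    streak_cfg <- shot_config(miss_fraction = 0, edge_streak_fraction = 1,
                              random_seed = 19)
    lib <- helixcdi:::pattern_library(hit_cfg, geom)
    shots <- c(lapply(1:40, function(i) simulate_shot(hit_cfg, geom, i, lib)),
               lapply(1:35, function(i) simulate_shot(miss_cfg, geom, i, lib)),
               lapply(1:25, function(i)
                 simulate_shot(streak_cfg, geom, i, lib)))
    set.seed(99)
    shots <- shots[sample.int(length(shots))]
    ctx <- sort_context(shots[[1]])
    kinds <- vapply(shots, function(s) s$metadata$kind, character(1))
    stats <- do.call(rbind, lapply(shots, shot_statistics, ctx = ctx))
    list(stats = stats, kinds = kinds)
  })
}

test_that("jet-edge streak shots stand out in the streak statistic", {
  ms <- mixed_shot_set()
  clean <- ms$stats$edge_streak_score[ms$kinds != "streak"]
  streaks <- ms$stats$edge_streak_score[ms$kinds == "streak"]
  expect_gt(length(streaks), 2)
  thr <- stats::quantile(clean, 0.99)
  expect_gt(mean(streaks > thr), 0.75)
})

test_that("outlier rejection keeps the right count and mostly true hits", {
  ms <- mixed_shot_set()
  kept <- reject_outliers(ms$stats, 0.40)
  expect_length(kept, 40)
  # >= 90% of kept shots are true filament shots
  expect_gte(mean(ms$kinds[kept] == "hit"), 0.9)

  expect_equal(sort(reject_outliers(ms$stats, 1)), seq_len(nrow(ms$stats)))
  expect_length(reject_outliers(ms$stats[1:7, ], 0.5), 4)
})

test_that("equatorial-angle estimation matches a brute-force Radon scan", {
  geom <- clean_geometry(200)
  cfg <- shot_config(miss_fraction = 0, edge_streak_fraction = 0,
                     alignment_sigma = 0, jet_angle_mean = 30,
                     jet_angle_sigma = 0, background_level = 0,
                     poisson_noise = FALSE, n_filaments_mean = 1,
                     protofilament_mixture = c(`14` = 1), random_seed = 2)
  lib <- helixcdi:::pattern_library(cfg, geom)
  shot <- simulate_shot(cfg, geom, 3, lib)
  est <- estimate_equatorial_angle(shot)
  oracle <- brute_force_equatorial_angle(shot)
  expect_lt(angle_diff_180(est$angle, oracle), 0.5)
  expect_lt(angle_diff_180(est$angle, 30), 1)
  expect_false(est$low_confidence)

  # equivariance under in-plane rotation
  for (delta in c(20, 77.5)) {
    est_r <- estimate_equatorial_angle(rotate_image(shot, delta))
    expect_lt(angle_diff_180(est_r$angle, (30 + delta) %% 180), 1)
  }

  # isotropic image: flagged low-confidence, no error
  set.seed(9)
  iso <- diffraction_image(matrix(rpois(200 * 200, 5), 200, 200),
                           q_step = shot$q_step)
  expect_true(estimate_equatorial_angle(iso)$low_confidence)
})

test_that("block classification recovers well-separated angle modes", {
  set.seed(31)
  n <- 1000
  true_mode <- rbinom(n, 1, 0.5)
  angles <- ifelse(true_mode == 1, rnorm(n, 120, 2), rnorm(n, 40, 2)) %% 180
  labels <- classify_block(angles, block_size = 1000, k = 2, seed = 4)
  expect_gte(adjusted_rand(labels, true_mode), 0.9)

  # determinism given the seed
  expect_identical(labels, classify_block(angles, 1000, 2, seed = 4))

  # identical angles collapse to a single class
  expect_equal(length(unique(classify_block(rep(45, 50), 1000, 5))), 1)

  # bookkeeping: k label slots per block, all occupied for spread angles
  set.seed(8)
  a2 <- runif(2300, 0, 180)
  l2 <- classify_block(a2, block_size = 1000, k = 5, seed = 1)
  expect_equal(length(unique(l2)), ceiling(2300 / 1000) * 5)
})

test_that("class averages sum members and track Poisson SNR scaling", {
  q_step <- 0.004
  base <- matrix(10, 64, 64)
  base[40, ] <- 60  # a layer-line row on a flat background
  set.seed(12)
  shots <- lapply(1:200, function(i)
    diffraction_image(matrix(rpois(64 * 64, base), 64, 64), q_step))

  one <- class_average(shots[1], angles = 0)
  expect_equal(one$image$intensity, shots[[1]]$intensity)
  expect_equal(one$n_members, 1)

  dup <- class_average(rep(shots[1], 5), angles = rep(0, 5))
  expect_equal(dup$image$intensity, 5 * shots[[1]]$intensity)

  avg <- class_average(shots, angles = rep(0, 200))
  snr_one <- (mean(shots[[1]]$intensity[40, ]) - 10) /
    stats::sd(shots[[1]]$intensity[20, ])
  snr_avg <- (mean(avg$image$intensity[40, ]) - 200 * 10) /
    stats::sd(avg$image$intensity[20, ])
  expect_lt(abs(snr_avg / snr_one - sqrt(200)) / sqrt(200), 0.35)
})

test_that("layer-line contrast scores flat, structured and scaled profiles", {
  q_step <- 0.005
  n <- 101
  flat <- diffraction_image(matrix(7, n, n), q_step, beam_center = c(51, 51))
  ca_flat <- structure(list(image = flat, counts = matrix(1L, n, n),
                            n_members = 1, equatorial_angle = 0,
                            contrast_score = NA_real_),
                       class = "class_average")
  expect_equal(contrast_score(ca_flat), 2, tolerance = 1e-6)

  # two bright spots on the 4 nm layer line row
  row <- 51 - round(0.25 / q_step)
  structured <- matrix(7, n, n)
  structured[row, c(30, 72)] <- 120
  ca_str <- ca_flat
  ca_str$image <- diffraction_image(structured, q_step, beam_center = c(51, 51))
  s1 <- contrast_score(ca_str)
  expect_gt(s1, contrast_score(ca_flat))

  # invariant to global intensity scaling
  ca_scaled <- ca_str
  ca_scaled$image <- diffraction_image(structured * 37, q_step,
                                       beam_center = c(51, 51))
  expect_equal(contrast_score(ca_scaled), s1, tolerance = 1e-9)
})

test_that("merging a single class reproduces its per-pixel mean", {
  pat <- averaged_pattern(14, clean_geometry(200))
  ca <- class_average(list(pat, pat, pat), angles = rep(0, 3))
  ca$contrast_score <- 1
  merged <- select_align_merge(list(ca), select_fraction = 1)
  expect_equal(merged$intensity, pat$intensity, tolerance = 1e-8)
})

test_that("rotation-then-merge equals rotating the image", {
  # smooth synthetic pattern (features much wider than a pixel), so the
  # comparison isolates interpolation error rather than pixel-scale fringes
  n <- 200
  bc <- c(101, 101)
  rr <- outer(seq_len(n) - bc[1], rep(1, n))
  cc <- outer(rep(1, n), seq_len(n) - bc[2])
  smooth <- exp(-((rr^2 + cc^2) - 40^2)^2 / (2 * 900^2)) +
    0.5 * exp(-(rr - 30)^2 / 128 - (cc + 25)^2 / 128) +
    0.5 * exp(-(rr + 30)^2 / 128 - (cc - 25)^2 / 128)
  pat <- diffraction_image(smooth, q_step = 0.0028, beam_center = bc)
  tilted <- rotate_image(pat, 25)
  ca <- class_average(list(tilted), angles = 25)
  ca$contrast_score <- 1
  merged <- select_align_merge(list(ca), select_fraction = 1)
  good <- !merged$mask & !tilted$mask
  rad <- helixcdi:::pixel_radius(pat)
  good <- good & rad < 70
  rms <- sqrt(mean((merged$intensity[good] - pat$intensity[good])^2))
  expect_lt(rms / sqrt(mean(pat$intensity[good]^2)), 0.01)

  # two identical classes at 0 and 90 merge into a horizontal-equator image
  pat <- averaged_pattern(14, clean_geometry(200))
  ca0 <- class_average(list(pat), angles = 0); ca0$contrast_score <- 1
  ca90 <- class_average(list(rotate_image(pat, 90)), angles = 90)
  ca90$contrast_score <- 1
  m2 <- select_align_merge(list(ca0, ca90), select_fraction = 1)
  est <- estimate_equatorial_angle(m2)
  expect_lt(angle_diff_180(est$angle, 0), 1)
  ll <- layer_line_position(m2, q_min = 0.06)
  expect_lt(abs(ll$resolution - 4), 0.15)
})
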