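#' Precomputed sorting context
#'
#' Caches the geometry-dependent quantities (central-panel crop indices,
#' per-pixel q and polar angle, radial and angular bin assignments) shared by
#' [shot_statistics()] and [estimate_equatorial_angle()] across a series of
#' same-geometry shots. Building it once and passing it to those functions
#' removes the dominant per-shot cost when processing thousands of images.
#'
#' @param image A template `diffraction_image` (geometry and mask are taken
#'   from it; all shots of the series must share them).
#' @param use_central_panels Restrict sorting statistics to the central-panel
#'   crop (default TRUE), mirroring the use of the central four detector
#'   tiles.
#' @param signal_annulus q-range (nm^-1) for the anisotropy statistic.
#' @param streak_annulus q-range (nm^-1) for the jet-edge streak statistic.
#' @param angle_annulus q-range (nm^-1) for the equatorial-angle search.
#' @param bin_width Angular bin width (deg) of the angle search.
#' @param smooth Half-width (bins) of the circular smoothing of the angular
#'   profile.
#' @return An object of class `sort_context`.
#' @export
sort_context <- function(image, use_central_panels = TRUE,
                         signal_annulus = c(0.05, 0.30),
                         streak_annulus = c(0.35, 0.55),
                         angle_annulus = c(0.05, 0.30),
                         bin_width = 0.5, smooth = 2L) {
  crop <- if (use_central_panels) crop_central_panels(image) else image
  good <- !crop$mask
  if (!any(good)) stop("fully masked image", call. = FALSE)
  q <- pixel_q(crop)
  ang <- pixel_angle(crop)
  qmax <- max(q[good])
  nb_r <- 64L
  rbin <- pmin(pmax(ceiling(q / qmax * nb_r), 1L), nb_r)
  ann <- good & q >= signal_annulus[1] & q <= signal_annulus[2]
  th2 <- 2 * ang[ann] * pi / 180
  hi <- good & q >= min(streak_annulus[1], 0.7 * qmax) & q <= streak_annulus[2]
  wedge <- pmin(floor(ang[hi] / 15) + 1L, 12L)

  # full-frame angle-search context
  qf <- pixel_q(image)
  sel <- !image$mask & qf >= angle_annulus[1] & qf <= angle_annulus[2]
  nb_a <- as.integer(round(180 / bin_width))
  abin <- pmin(floor(pixel_angle(image)[sel] / bin_width) + 1L, nb_a)
  acnt <- tabulate(abin, nbins = nb_a)

  structure(list(
    use_central_panels = use_central_panels,
    crop_dim = dim(crop$intensity), crop_good = which(good),
    rbin_good = rbin[good], nb_r = nb_r,
    ann_idx = which(ann), cos2 = cos(th2), sin2 = sin(th2),
    hi_idx = which(hi), wedge = wedge,
    sel_idx = which(sel), abin = abin, nb_a = nb_a, acnt = acnt,
    bin_width = bin_width, smooth = as.integer(smooth),
    template_dim = dim(image$intensity),
    beam_center = image$beam_center, q_step = image$q_step
  ), class = "sort_context")
}

# intensity of the central-panel crop for a shot, as a plain vector aligned
# with the context's crop indexing
.crop_intensity <- function(image, ctx) {
  if (!ctx$use_central_panels) return(image$intensity)
  crop_central_panels(image)$intensity
}

#' Per-shot sorting statistics
#'
#' Robust statistics used to separate filament diffraction from solution
#' background and jet-edge artefacts, computed on unmasked pixels (of the
#' central-panel crop by default):
#' \describe{
#'   \item{total_intensity}{Summed unmasked photons.}
#'   \item{radial_profile_deviation}{Coefficient of variation of the
#'     azimuthal-mean radial profile about its running-median trend; high
#'     when layer-line structure is present.}
#'   \item{anisotropy_score}{Resultant length of the intensity-weighted
#'     angular distribution on the doubled angle within the signal annulus;
#'     0 for isotropic scatter, approaching 1 for a single diffraction
#'     line.}
#'   \item{edge_streak_score}{Max/mean ratio of the angular intensity
#'     profile in a high-q annulus where filament scattering is weak but a
#'     jet-edge streak remains strong.}
#' }
#' All four are invariant under 90 degree image rotation.
#'
#' @param image A `diffraction_image`.
#' @param ctx A [sort_context()]; built on the fly when omitted.
#' @return A one-row data.frame of class `shot_statistics`.
#' @export
shot_statistics <- function(image, ctx = NULL) {
  if (is.null(ctx)) ctx <- sort_context(image)
  v <- .crop_intensity(image, ctx)
  vg <- v[ctx$crop_good]
  total <- sum(vg)

  prof <- rep(0, ctx$nb_r)
  t <- tapply(vg, ctx$rbin_good, mean)
  prof[as.integer(names(t))] <- t
  trend <- stats::runmed(prof, k = 9)
  mprof <- mean(prof)
  rpd <- if (mprof > 0) stats::sd(prof - trend) / mprof else 0

  w <- v[ctx$ann_idx]
  sw <- sum(w)
  aniso <- if (sw > 0)
    sqrt(sum(w * ctx$cos2)^2 + sum(w * ctx$sin2)^2) / sw else 0

  streak <- 1
  wv <- v[ctx$hi_idx]
  if (length(wv) > 0 && sum(wv) > 0) {
    wm <- tapply(wv, ctx$wedge, mean)
    wm <- wm[is.finite(wm)]
    if (length(wm) > 1 && mean(wm) > 0) streak <- max(wm) / mean(wm)
  }
  structure(data.frame(total_intensity = total,
                       radial_profile_deviation = rpd,
                       anisotropy_score = aniso,
                       edge_streak_score = streak),
            class = c("shot_statistics", "data.frame"))
}

#' Rank shots and keep the best fraction
#'
#' Composite outlier rejection: shots whose high-q streak statistic is a
#' gross outlier (beyond `streak_veto` robust SDs of the batch) are vetoed
#' outright -- jet-edge exposures are bright and directional enough to
#' otherwise survive any soft ranking. The remainder are scored by robust
#' z-scores of the structure and anisotropy statistics, with a penalty for
#' residual streak excess, and the highest-scoring
#' `ceil(keep_fraction * n)` are kept (the conservative 40% cut of the
#' original processing). Ties break by lowest shot index.
#'
#' @param stats A data.frame of [shot_statistics()] rows (one per shot).
#' @param keep_fraction Fraction of shots to keep, in (0, 1].
#' @param streak_veto Hard veto threshold (robust SDs) on the streak
#'   statistic; `Inf` disables it.
#' @return Integer indices of the kept shots, in decreasing score order.
#' @export
reject_outliers <- function(stats, keep_fraction = 0.40, streak_veto = 5) {
  stopifnot(nrow(stats) >= 1, keep_fraction > 0, keep_fraction <= 1)
  rz <- function(v) {
    s <- stats::mad(v)
    if (s == 0) s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(rep(0, length(v)))
    (v - stats::median(v)) / s
  }
  z_streak <- rz(stats$edge_streak_score)
  vetoed <- is.finite(streak_veto) & z_streak > streak_veto
  score <- rz(stats$anisotropy_score) + rz(stats$radial_profile_deviation) -
    2 * pmax(z_streak, 0)
  score[vetoed] <- -Inf
  n_keep <- min(ceiling(keep_fraction * nrow(stats)), sum(!vetoed))
  order(-score, seq_len(nrow(stats)))[seq_len(n_keep)]
}

#' Estimate the equatorial-line angle of a diffraction image
#'
#' Angular Radon-style score: unmasked intensity within a q-annulus is
#' binned by polar angle (mod 180, default 0.5 degree bins), normalized by
#' pixels per bin, smoothed circularly, and the angle maximizing the profile
#' is refined by a 3-point parabola. A confidence flag is set when the
#' angular profile has no significant preferred direction (featureless or
#' isotropic images); such images return the best-scoring angle rather than
#' raising an error.
#'
#' @param image A `diffraction_image`.
#' @param ctx A [sort_context()]; built on the fly when omitted.
#' @return List with `angle` (deg, in `[0, 180)`), `confidence` (peak
#'   prominence in angular-profile SDs) and `low_confidence` flag.
#' @export
estimate_equatorial_angle <- function(image, ctx = NULL) {
  if (is.null(ctx)) ctx <- sort_context(image)
  w <- image$intensity[ctx$sel_idx]
  ssum <- rep(0, ctx$nb_a)
  t <- tapply(w, ctx$abin, sum)
  ssum[as.integer(names(t))] <- t
  prof <- ifelse(ctx$acnt > 0, ssum / pmax(ctx$acnt, 1), 0)
  nb <- ctx$nb_a
  if (ctx$smooth > 0) {
    s <- ctx$smooth
    k <- 2L * s + 1L
    prof <- stats::filter(c(tail(prof, s), prof, head(prof, s)),
                          rep(1 / k, k))[s + seq_len(nb)]
  }
  prof <- as.numeric(prof)
  i <- which.max(prof)
  conf <- if (stats::sd(prof) > 0) (prof[i] - mean(prof)) / stats::sd(prof) else 0
  im <- if (i == 1) nb else i - 1L
  ip <- if (i == nb) 1L else i + 1L
  den <- prof[im] - 2 * prof[i] + prof[ip]
  frac <- if (is.finite(den) && den != 0) 0.5 * (prof[im] - prof[ip]) / den else 0
  angle <- ((i - 1 + frac) * ctx$bin_width + ctx$bin_width / 2) %% 180
  list(angle = angle, confidence = conf, low_confidence = conf < 3)
}

# circular mean of angles defined mod 180 (doubled-angle embedding)
circular_mean_180 <- function(angles, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(angles))
  th <- 2 * angles * pi / 180
  (atan2(sum(weights * sin(th)), sum(weights * cos(th))) * 90 / pi) %% 180
}

#' Classify shots into angle subgroups block-wise
#'
#' Divides the shot series into consecutive blocks of about `block_size`
#' images and, within each block, partitions shots into `k` subgroups by
#' circular k-means on the doubled equatorial angle (each angle embedded as
#' a unit vector on 2 theta, so 0 and 180 degrees coincide). Deterministic
#' given the seed.
#'
#' @param angles Estimated equatorial angles (deg mod 180), one per shot.
#' @param block_size Nominal shots per block (default 1000).
#' @param k Subgroups per block (default 5).
#' @param seed RNG seed for the k-means starts.
#' @return Integer vector of global class labels (`k` labels reserved per
#'   block); blocks with fewer than `k` distinct angles form a single class.
#' @export
classify_block <- function(angles, block_size = 1000L, k = 5L, seed = 1L) {
  n <- length(angles)
  stopifnot(n >= 1, k >= 1)
  n_blocks <- max(1L, ceiling(n / block_size))
  block <- pmin(ceiling(seq_len(n) / block_size), n_blocks)
  labels <- integer(n)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  for (b in seq_len(n_blocks)) {
    idx <- which(block == b)
    offset <- (b - 1L) * k
    if (length(idx) < k || length(unique(round(angles[idx], 6))) < k) {
      labels[idx] <- offset + 1L
      next
    }
    th <- 2 * angles[idx] * pi / 180
    emb <- cbind(cos(th), sin(th))
    set.seed(seed + b)
    km <- stats::kmeans(emb, centers = k, nstart = 10, iter.max = 50)
    labels[idx] <- offset + km$cluster
  }
  labels
}

#' Class average of a shot subgroup
#'
#' Pixel-wise sum of the member images over unmasked pixels, stored together
#' with a per-pixel member count for later normalization (sums, not means,
#' are propagated; normalization is deferred to the merge). The class's
#' equatorial angle is the circular mean of its members' angles.
#'
#' @param images List of `diffraction_image` members, or a function
#'   `function(i)` returning member `i` (then give `indices`).
#' @param angles Members' equatorial angles (deg mod 180), one per member.
#' @param indices Member indices when `images` is an accessor function.
#' @return An object of class `class_average`: fields `image` (summed
#'   `diffraction_image`), `counts` (per-pixel member count), `n_members`,
#'   `equatorial_angle` and `contrast_score` (NA until scored).
#' @export
class_average <- function(images, angles, indices = NULL) {
  get <- if (is.function(images)) images else function(i) images[[i]]
  idx <- if (is.null(indices)) seq_along(angles) else indices
  stopifnot(length(idx) >= 1)
  first <- get(idx[1])
  acc <- matrix(0, nrow(first$intensity), ncol(first$intensity))
  cnt <- matrix(0L, nrow(first$intensity), ncol(first$intensity))
  for (i in idx) {
    im <- get(i)
    g <- !im$mask
    acc[g] <- acc[g] + im$intensity[g]
    cnt <- cnt + g
  }
  summed <- diffraction_image(acc, first$q_step, first$beam_center,
                              mask = cnt == 0L, geometry = first$geometry)
  structure(list(image = summed, counts = cnt, n_members = length(idx),
                 equatorial_angle = circular_mean_180(angles),
                 contrast_score = NA_real_),
            class = "class_average")
}

#' @export
print.class_average <- function(x, ...) {
  cat(sprintf(
    "<class_average> %d members, equatorial angle %.2f deg, contrast %.3g\n",
    x$n_members, x$equatorial_angle, x$contrast_score))
  invisible(x)
}

# intensity profile along the 4 nm layer line of a class average: samples the
# rows at q_y = +/- layer_q in the frame rotated so the equator is
# horizontal, averaging the two Friedel-related lines
layer_line_profile <- function(avg, layer_q = 0.25) {
  img <- rotate_image(avg$image, -avg$equatorial_angle)
  off <- round(layer_q / img$q_step)
  rows <- img$beam_center[1] + c(-off, off)
  rows <- rows[rows >= 1 & rows <= nrow(img$intensity)]
  if (length(rows) == 0) stop("layer line outside the image", call. = FALSE)
  vals <- img$intensity[rows, , drop = FALSE]
  good <- !img$mask[rows, , drop = FALSE]
  prof <- colSums(vals * good) / pmax(colSums(good), 1)
  prof[colSums(good) == 0] <- NA
  prof
}

#' Layer-line contrast of a class average
#'
#' Extracts the intensity profile along the 4 nm layer line (the row
#' parallel to the equator at `q = 0.25` nm^-1 in the rotated frame), finds
#' its two highest local maxima, and returns the ratio of their summed
#' intensity to the mean intensity across the entire line. A flat line
#' scores about 2; the score is invariant to global intensity scaling.
#'
#' @param avg A `class_average`.
#' @param layer_q Layer-line spatial frequency, nm^-1 (default 0.25, the
#'   4 nm line).
#' @return Dimensionless contrast score.
#' @export
contrast_score <- function(avg, layer_q = 0.25) {
  prof <- layer_line_profile(avg, layer_q)
  prof <- prof[is.finite(prof)]
  if (length(prof) < 5) stop("layer line fully masked", call. = FALSE)
  m <- mean(prof)
  if (m <= 0) return(0)
  n <- length(prof)
  is_max <- c(prof[1] >= prof[2],
              prof[2:(n - 1)] >= prof[1:(n - 2)] &
                prof[2:(n - 1)] >= prof[3:n],
              prof[n] >= prof[n - 1])
  peaks <- sort(prof[is_max], decreasing = TRUE)
  if (length(peaks) == 1) peaks <- c(peaks, peaks)
  (peaks[1] + peaks[2]) / m
}

#' Select, rotationally align and merge class averages
#'
#' Keeps the top `select_fraction` of class averages by layer-line contrast
#' (mirroring the histogram-based 69-of-186 selection), rotates each summed
#' image about the beam center by minus its equatorial angle so all
#' equators are horizontal, and combines them with per-pixel normalization
#' over the contributing (unmasked, in-bounds) member counts.
#'
#' @param averages List of `class_average` objects; missing contrast scores
#'   are computed here.
#' @param select_fraction Fraction of classes to keep (default 69/186).
#' @return A `diffraction_image`: the merged pattern, with
#'   `metadata$n_classes`, `metadata$n_members` and `metadata$selected`
#'   recording the selection.
#' @export
select_align_merge <- function(averages, select_fraction = 69 / 186) {
  stopifnot(length(averages) >= 1, select_fraction > 0, select_fraction <= 1)
  scores <- vapply(averages, function(a) {
    if (is.na(a$contrast_score)) contrast_score(a) else a$contrast_score
  }, numeric(1))
  n_keep <- ceiling(select_fraction * length(averages))
  keep <- order(-scores, seq_along(averages))[seq_len(n_keep)]
  first <- averages[[keep[1]]]$image
  acc <- matrix(0, nrow(first$intensity), ncol(first$intensity))
  wacc <- matrix(0, nrow(first$intensity), ncol(first$intensity))
  for (i in keep) {
    a <- averages[[i]]
    # rotate the class sum and its member-count weight map together; passing
    # +angle to the kernel moves features by -angle, aligning the equator
    # to the horizontal
    w <- matrix(as.numeric(a$counts), nrow(a$counts))
    rot <- cpp_rotate_weighted(a$image$intensity, w, a$equatorial_angle,
                               first$beam_center[1], first$beam_center[2])
    acc <- acc + rot$image
    wacc <- wacc + rot$weight
  }
  out <- ifelse(wacc > 1e-6, acc / pmax(wacc, 1e-12), 0)
  out[out < 0] <- 0
  diffraction_image(out, first$q_step, first$beam_center,
                    mask = wacc <= 1e-6,
                    metadata = list(
                      n_classes = n_keep,
                      n_members = sum(vapply(averages[keep], function(a)
                        a$n_members, numeric(1))),
                      selected = keep))
}
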