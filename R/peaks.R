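#' Separable Gaussian diffraction peak
#'
#' One diffraction spot modelled as
#' `A * exp(-(col - cc)^2 / (2 sx^2)) * exp(-(row - cr)^2 / (2 sy^2)) + b`,
#' the horizontal/vertical (separable, axis-aligned) Gaussian used to
#' idealize fiber-diffraction peaks. Equatorial streaks are represented by
#' strongly anisotropic sigmas.
#'
#' @param amplitude Peak amplitude above the local offset (> 0).
#' @param center Sub-pixel `(row, col)` center.
#' @param sigma_x,sigma_y Widths along columns/rows, pixels (> 0).
#' @param background_offset Local constant offset (not rendered).
#' @return An object of class `gaussian_peak`.
#' @export
gaussian_peak <- function(amplitude, center, sigma_x, sigma_y,
                          background_offset = 0) {
  stopifnot(amplitude > 0, sigma_x > 0, sigma_y > 0, length(center) == 2)
  center <- as.numeric(center)
  structure(list(amplitude = amplitude, center = center,
                 sigma_x = sigma_x, sigma_y = sigma_y,
                 background_offset = background_offset),
            class = "gaussian_peak")
}

#' @export
print.gaussian_peak <- function(x, ...) {
  cat(sprintf("<gaussian_peak> A %.4g at (%.2f, %.2f), sigma (%.2f, %.2f) px, offset %.3g\n",
              x$amplitude, x$center[1], x$center[2], x$sigma_y, x$sigma_x,
              x$background_offset))
  invisible(x)
}

# robust local noise scale per radial bin: MAD of unmasked intensity about
# the bin median, interpolated back to every pixel
local_noise_map <- function(img, n_bins = 48L) {
  q <- pixel_radius(img)
  good <- !img$mask
  qmax <- max(q[good])
  bin <- pmin(pmax(ceiling(q / qmax * n_bins), 1L), n_bins)
  sig <- rep(NA_real_, n_bins)
  med <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) {
    v <- img$intensity[good & bin == b]
    if (length(v) > 10) {
      med[b] <- stats::median(v)
      sig[b] <- stats::mad(v)
    }
  }
  # fall back to Poisson-like floor where MAD degenerates
  sig <- ifelse(!is.finite(sig) | sig <= 0,
                pmax(sqrt(pmax(med, 0)), 1e-12), sig)
  sig[!is.finite(sig)] <- max(sig[is.finite(sig)], 1e-12)
  med[!is.finite(med)] <- 0
  list(sigma = matrix(sig[bin], nrow(q)), median = matrix(med[bin], nrow(q)))
}

#' Detect candidate diffraction peaks
#'
#' Local maxima of the unmasked intensity exceeding
#' `median + min_snr * local RMS` (robust radial noise model), kept greedily
#' by decreasing intensity with a minimum mutual separation, and completed to
#' Friedel pairs: accepting a peak at q implies accepting its mate at -q.
#'
#' @param merged A `diffraction_image` (typically the merged pattern).
#' @param min_snr Detection threshold in local noise units.
#' @param min_separation Minimum center-to-center distance, pixels.
#' @param exclude_center_q Radius (nm^-1) around the beam center excluded
#'   from detection (beamstop region).
#' @return Matrix with columns `row`, `col`, `intensity`, ordered by
#'   decreasing intensity (may have zero rows).
#' @export
detect_peaks <- function(merged, min_snr = 5, min_separation = 5,
                         exclude_center_q = 0.02) {
  inten <- merged$intensity
  n <- nrow(inten); m <- ncol(inten)
  noise <- local_noise_map(merged)
  thresh <- noise$median + min_snr * noise$sigma
  q <- pixel_q(merged)
  cand <- which(!merged$mask & inten > thresh & q > exclude_center_q)
  if (length(cand) == 0)
    return(matrix(numeric(0), 0, 3,
                  dimnames = list(NULL, c("row", "col", "intensity"))))
  rr <- (cand - 1) %% n + 1
  cc <- (cand - 1) %/% n + 1
  inner <- rr > 1 & rr < n & cc > 1 & cc < m
  rr <- rr[inner]; cc <- cc[inner]; cand <- cand[inner]
  is_max <- vapply(seq_along(cand), function(k) {
    v <- inten[cand[k]]
    all(v >= inten[(rr[k] - 1):(rr[k] + 1), (cc[k] - 1):(cc[k] + 1)])
  }, logical(1))
  rr <- rr[is_max]; cc <- cc[is_max]
  vals <- inten[cbind(rr, cc)]
  o <- order(-vals, rr, cc)
  rr <- rr[o]; cc <- cc[o]; vals <- vals[o]
  keep_r <- numeric(0); keep_c <- numeric(0); keep_v <- numeric(0)
  for (k in seq_along(rr)) {
    if (length(keep_r) == 0 ||
        all((keep_r - rr[k])^2 + (keep_c - cc[k])^2 >= min_separation^2)) {
      keep_r <- c(keep_r, rr[k]); keep_c <- c(keep_c, cc[k])
      keep_v <- c(keep_v, vals[k])
    }
  }
  # Friedel completion: add the inversion mate of any unpaired peak
  bc <- merged$beam_center
  for (k in seq_along(keep_r)) {
    mr <- 2 * bc[1] - keep_r[k]; mc <- 2 * bc[2] - keep_c[k]
    if (mr < 1 || mr > n || mc < 1 || mc > m) next
    if (all((keep_r - mr)^2 + (keep_c - mc)^2 >= min_separation^2)) {
      keep_r <- c(keep_r, mr); keep_c <- c(keep_c, mc)
      keep_v <- c(keep_v, inten[round(mr), round(mc)])
    }
  }
  o <- order(-keep_v)
  cbind(row = keep_r[o], col = keep_c[o], intensity = keep_v[o])
}

#' Fit a separable Gaussian to one peak region
#'
#' Levenberg-Marquardt least squares of
#' `A exp(-(x - cx)^2 / 2 sx^2) exp(-(y - cy)^2 / 2 sy^2) + b` over the
#' unmasked pixels of a square window around the initial center. Pixels
#' closer to another listed peak center than to this one are excluded, so
#' adjacent peaks do not bias the fit.
#'
#' @param image A `diffraction_image`.
#' @param init A `gaussian_peak` with starting values (as produced by
#'   [detect_peaks()] + moment estimates, or user-supplied).
#' @param window Half-width of the fit window in pixels (default
#'   `max(4, ceiling(4 * max(sigma)))`).
#' @param other_centers Optional matrix of competing peak centers
#'   (`row`, `col`) used for the exclusion rule.
#' @return A `gaussian_peak` with fitted parameters and attribute
#'   `converged`; non-convergence returns the initial values flagged
#'   `converged = FALSE`.
#' @export
fit_peak <- function(image, init, window = NULL, other_centers = NULL) {
  if (is.null(window))
    window <- max(4L, ceiling(4 * max(init$sigma_x, init$sigma_y)))
  n <- nrow(image$intensity); m <- ncol(image$intensity)
  r0 <- round(init$center[1]); c0 <- round(init$center[2])
  rows <- max(1, r0 - window):min(n, r0 + window)
  cols <- max(1, c0 - window):min(m, c0 + window)
  rg <- rep(rows, times = length(cols))
  cg <- rep(cols, each = length(rows))
  z <- as.vector(image$intensity[rows, cols])
  ok <- !as.vector(image$mask[rows, cols])
  if (!is.null(other_centers) && nrow(other_centers) > 0) {
    d_own <- (rg - init$center[1])^2 + (cg - init$center[2])^2
    for (k in seq_len(nrow(other_centers))) {
      oc <- other_centers[k, ]
      if (sum((oc[1:2] - init$center)^2) < 1e-9) next
      d_oth <- (rg - oc[1])^2 + (cg - oc[2])^2
      ok <- ok & (d_own <= d_oth)
    }
  }
  rg <- rg[ok]; cg <- cg[ok]; z <- z[ok]
  if (length(z) < 7) {
    out <- init; attr(out, "converged") <- FALSE; return(out)
  }
  par0 <- c(A = as.numeric(init$amplitude),
            cr = as.numeric(init$center[1]),
            cc = as.numeric(init$center[2]),
            lsy = log(init$sigma_y), lsx = log(init$sigma_x),
            b = as.numeric(init$background_offset))
  resid_fn <- function(p) {
    mu <- p[["A"]] *
      exp(-(cg - p[["cc"]])^2 / (2 * exp(2 * p[["lsx"]]))) *
      exp(-(rg - p[["cr"]])^2 / (2 * exp(2 * p[["lsy"]]))) + p[["b"]]
    mu - z
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par0, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  # reject collapsed (sub-pixel) fits; elongated equatorial streaks are
  # legitimate, so the upper bound is generous
  sig_ok <- function(ls) {
    s <- exp(ls)
    is.finite(s) && s >= 0.3 && s <= max(n, m)
  }
  bad <- is.null(fit) || !all(is.finite(unlist(fit$par))) ||
    fit$par[["A"]] <= 0 || fit$info %in% c(0, 5) ||
    !sig_ok(fit$par[["lsx"]]) || !sig_ok(fit$par[["lsy"]]) ||
    abs(fit$par[["cr"]] - init$center[1]) > window ||
    abs(fit$par[["cc"]] - init$center[2]) > window
  if (bad) {
    out <- init; attr(out, "converged") <- FALSE; return(out)
  }
  p <- fit$par
  out <- gaussian_peak(p[["A"]], c(p[["cr"]], p[["cc"]]),
                       exp(p[["lsx"]]), exp(p[["lsy"]]), p[["b"]])
  attr(out, "converged") <- TRUE
  out
}

#' Detect and fit all peaks of a merged pattern
#'
#' Runs [detect_peaks()], derives moment-based starting values for each
#' candidate, fits them with [fit_peak()] (excluding pixels that belong to
#' neighbouring candidates) and drops non-converged fits.
#'
#' @inheritParams detect_peaks
#' @param init_sigma Starting sigma (px) for each fit.
#' @return A `peak_model`: list of fitted `gaussian_peak`s plus the source
#'   image dimensions/calibration.
#' @export
fit_peaks <- function(merged, min_snr = 5, min_separation = 5,
                      init_sigma = 2) {
  cand <- detect_peaks(merged, min_snr, min_separation)
  noise <- local_noise_map(merged)
  peaks <- list()
  dropped <- 0L
  for (k in seq_len(nrow(cand))) {
    off0 <- noise$median[cand[k, "row"], cand[k, "col"]]
    amp0 <- max(cand[k, "intensity"] - off0, 1e-6)
    init <- gaussian_peak(amp0, cand[k, c("row", "col")],
                          init_sigma, init_sigma, off0)
    f <- fit_peak(merged, init, other_centers = cand)
    if (isTRUE(attr(f, "converged"))) peaks[[length(peaks) + 1L]] <- f
    else dropped <- dropped + 1L
  }
  peak_model(peaks, dim(merged$intensity), merged$q_step,
             merged$beam_center, n_dropped = dropped)
}

#' Peak model
#'
#' A list of fitted separable Gaussians together with the grid they live on;
#' renders to the idealized noise-free pattern.
#'
#' @param peaks List of `gaussian_peak` objects.
#' @param dim Image dimensions `(rows, cols)`.
#' @param q_step Spatial-frequency step, nm^-1 per pixel.
#' @param beam_center Beam center `(row, col)`.
#' @param n_dropped Count of non-converged fits excluded from the model.
#' @return An object of class `peak_model`.
#' @export
peak_model <- function(peaks, dim, q_step, beam_center, n_dropped = 0L) {
  structure(list(peaks = peaks, dim = dim, q_step = q_step,
                 beam_center = beam_center, n_dropped = n_dropped),
            class = "peak_model")
}

#' @export
print.peak_model <- function(x, ...) {
  cat(sprintf("<peak_model> %d peaks on %d x %d px (%d fits dropped)\n",
              length(x$peaks), x$dim[1], x$dim[2], x$n_dropped))
  invisible(x)
}

#' Render the idealized noise-free pattern
#'
#' Sum of all fitted Gaussians on a zero background over the full grid, with
#' no mask: detector gaps, bad pixels and inter-peak noise vanish by
#' construction. Local background offsets are not rendered.
#'
#' @param model A `peak_model`.
#' @return A `diffraction_image`.
#' @export
render_fitted <- function(model) {
  out <- matrix(0, model$dim[1], model$dim[2])
  rows <- seq_len(model$dim[1]); cols <- seq_len(model$dim[2])
  for (p in model$peaks) {
    gy <- exp(-(rows - p$center[1])^2 / (2 * p$sigma_y^2))
    gx <- exp(-(cols - p$center[2])^2 / (2 * p$sigma_x^2))
    out <- out + p$amplitude * outer(gy, gx)
  }
  diffraction_image(out, model$q_step, model$beam_center)
}

#' Export a peak list as a table
#'
#' @param model A `peak_model`.
#' @param path Optional path; when given, writes a tab-separated table.
#' @return Data frame with center, q, amplitude and widths per peak.
#' @export
peak_table <- function(model, path = NULL) {
  df <- do.call(rbind, lapply(model$peaks, function(p) {
    data.frame(center_row = p$center[1], center_col = p$center[2],
               q = model$q_step *
                 sqrt((p$center[1] - model$beam_center[1])^2 +
                      (p$center[2] - model$beam_center[2])^2),
               amplitude = p$amplitude, sigma_x = p$sigma_x,
               sigma_y = p$sigma_y, offset = p$background_offset)
  }))
  if (is.null(df)) df <- data.frame()
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  df
}
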