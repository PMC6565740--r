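#' Write a shot stack to disk
#'
#' Serializes a series of diffraction images as a directory: `geometry.json`
#' (detector metadata, q calibration, shot count), `mask.rds` (the shared
#' static mask) and one `shot_NNNNNN.rds` per image (intensity + per-shot
#' metadata). The layout supports lazy single-shot reads so arbitrarily long
#' series stream with bounded memory.
#'
#' @param source A shot source (as from [shot_source_simulated()]) or a list
#'   of `diffraction_image`s.
#' @param path Directory to create (must not already contain a stack unless
#'   `overwrite = TRUE`).
#' @param overwrite Replace an existing stack.
#' @return `path`, invisibly.
#' @export
write_shot_stack <- function(source, path, overwrite = FALSE) {
  if (is.list(source) && is.null(source$get)) {
    shots <- source
    source <- list(n = length(shots), get = function(i) shots[[i]],
                   geometry = shots[[1]]$geometry)
  }
  if (dir.exists(path)) {
    if (!overwrite && file.exists(file.path(path, "geometry.json")))
      stop("stack already exists at ", path, call. = FALSE)
  } else dir.create(path, recursive = TRUE)
  first <- source$get(1)
  meta <- list(n_shots = source$n,
               n_rows = nrow(first$intensity), n_cols = ncol(first$intensity),
               q_step = first$q_step, beam_center = first$beam_center,
               geometry = if (!is.null(source$geometry))
                 source$geometry[c("n_rows", "n_cols", "pixel_pitch",
                                   "distance", "wavelength", "beam_center")]
               else NULL)
  jsonlite::write_json(meta, file.path(path, "geometry.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(first$mask, file.path(path, "mask.rds"))
  for (i in seq_len(source$n)) {
    im <- source$get(i)
    saveRDS(list(intensity = im$intensity, metadata = im$metadata),
            file.path(path, sprintf("shot_%06d.rds", i)))
  }
  invisible(path)
}

#' Read a shot stack lazily
#'
#' Opens a stack written by [write_shot_stack()] and returns a shot source:
#' list with `n`, `get(i)` and the shared calibration. Only one shot is
#' resident per `get` call; `selection` restricts and reorders the series.
#'
#' @param path Stack directory.
#' @param selection Optional integer indices into the stored series.
#' @return A shot source list.
#' @export
read_shot_stack <- function(path, selection = NULL) {
  gfile <- file.path(path, "geometry.json")
  if (!file.exists(gfile))
    stop("not a shot stack: missing ", gfile, call. = FALSE)
  meta <- jsonlite::read_json(gfile, simplifyVector = TRUE)
  mfile <- file.path(path, "mask.rds")
  if (!file.exists(mfile))
    stop("not a shot stack: missing ", mfile, call. = FALSE)
  mask <- readRDS(mfile)
  idx <- if (is.null(selection)) seq_len(meta$n_shots) else as.integer(selection)
  stopifnot(all(idx >= 1), all(idx <= meta$n_shots))
  get <- function(i) {
    f <- file.path(path, sprintf("shot_%06d.rds", idx[i]))
    if (!file.exists(f))
      stop("not a shot stack: missing ", f, call. = FALSE)
    rec <- readRDS(f)
    diffraction_image(rec$intensity, meta$q_step, meta$beam_center, mask,
                      metadata = rec$metadata)
  }
  list(n = length(idx), get = get, geometry = meta$geometry, path = path)
}

# one append-only manifest record per pipeline stage
manifest_record <- function(stage, n_in, n_out, seed = NA, extra = list()) {
  c(list(stage = stage, n_in = n_in, n_out = n_out, seed = seed,
         time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         version = as.character(utils::packageVersion("helixcdi"))),
    extra)
}

#' Run the full imaging pipeline
#'
#' Executes the processing chain on a shot source: per-shot statistics and
#' equatorial angles -> outlier rejection -> block-wise angle classification
#' -> class averaging -> contrast-based selection, rotational alignment and
#' merging -> (optionally) peak fitting and rendering of the idealized
#' pattern -> iterative phase retrieval -> radial/helical analysis. Each
#' stage appends one record (counts in/out, seed, parameters) to the run
#' manifest. Two passes are made over the source (statistics, then class
#' sums), so memory stays bounded regardless of series length.
#'
#' @param source A shot source ([shot_source_simulated()],
#'   [read_shot_stack()], or a list of `diffraction_image`s).
#' @param keep_fraction Fraction kept by outlier rejection (default 0.40).
#' @param block_size,k Classification block size and subgroups per block.
#' @param select_fraction Fraction of class averages merged (default
#'   69/186).
#' @param fit_peaks_stage If TRUE (default), phase retrieval inverts the
#'   rendered peak-model pattern; if FALSE, the merged pattern directly.
#' @param config A `retrieval_config`.
#' @param support A `support_mask`.
#' @param seed Seed for the classification stage.
#' @param min_snr,min_separation Peak-detection parameters.
#' @return List of class `helix_pipeline`: `merged`, `fitted` (peak model
#'   and rendered pattern or NULL), `recon` (`projection_density`),
#'   `analysis` (peak-to-peak, J01, helical radius, protofilament number),
#'   `stats`, `angles`, `kept`, `labels`, `class_averages` (summaries) and
#'   `manifest`.
#' @export
run_pipeline <- function(source, keep_fraction = 0.40, block_size = 1000L,
                         k = 5L, select_fraction = 69 / 186,
                         fit_peaks_stage = TRUE,
                         config = retrieval_config(),
                         support = support_mask(), seed = 1L,
                         min_snr = 5, min_separation = 5) {
  if (is.list(source) && is.null(source$get)) {
    shots <- source
    source <- list(n = length(shots), get = function(i) shots[[i]])
  }
  n <- source$n
  stopifnot(n >= 1)
  manifest <- list()

  # pass 1: statistics and angles
  first <- source$get(1)
  ctx <- sort_context(first)
  stats_df <- vector("list", n)
  angles <- numeric(n)
  lowconf <- logical(n)
  for (i in seq_len(n)) {
    im <- source$get(i)
    stats_df[[i]] <- shot_statistics(im, ctx)
    est <- estimate_equatorial_angle(im, ctx)
    angles[i] <- est$angle
    lowconf[i] <- est$low_confidence
  }
  stats_df <- do.call(rbind, stats_df)
  manifest[[length(manifest) + 1]] <-
    manifest_record("statistics", n, n)

  kept <- sort(reject_outliers(stats_df, keep_fraction))
  manifest[[length(manifest) + 1]] <-
    manifest_record("reject_outliers", n, length(kept),
                    extra = list(keep_fraction = keep_fraction))

  labels <- classify_block(angles[kept], block_size, k, seed)
  n_classes <- length(unique(labels))
  manifest[[length(manifest) + 1]] <-
    manifest_record("classify", length(kept), n_classes, seed = seed,
                    extra = list(block_size = block_size, k = k))

  # pass 2: class sums
  averages <- lapply(sort(unique(labels)), function(lb) {
    idx <- kept[labels == lb]
    class_average(function(i) source$get(i), angles = angles[idx],
                  indices = idx)
  })
  for (j in seq_along(averages))
    averages[[j]]$contrast_score <- contrast_score(averages[[j]])
  manifest[[length(manifest) + 1]] <-
    manifest_record("class_average", length(kept), length(averages))

  merged <- select_align_merge(averages, select_fraction)
  manifest[[length(manifest) + 1]] <-
    manifest_record("select_align_merge", length(averages),
                    merged$metadata$n_classes,
                    extra = list(n_members = merged$metadata$n_members,
                                 select_fraction = select_fraction))

  fitted <- NULL
  pattern <- merged
  if (fit_peaks_stage) {
    pm <- fit_peaks(merged, min_snr = min_snr,
                    min_separation = min_separation)
    rendered <- render_fitted(pm)
    fitted <- list(model = pm, pattern = rendered)
    pattern <- rendered
    manifest[[length(manifest) + 1]] <-
      manifest_record("fit_peaks", 1, length(pm$peaks),
                      extra = list(n_dropped = pm$n_dropped))
  }

  recon <- retrieve(pattern, config, support)
  manifest[[length(manifest) + 1]] <-
    manifest_record("retrieve", 1, 1,
                    extra = list(final_misfit = tail(recon$error_history, 1),
                                 diverged = recon$diverged))

  analysis <- list(peak_to_peak = tryCatch(peak_to_peak(recon),
                                           error = function(e) NA_real_))
  prof <- tryCatch(azimuthal_integrate(merged), error = function(e) NULL)
  if (!is.null(prof)) {
    analysis$profile <- prof
    j01 <- tryCatch(find_J01(prof), error = function(e) NA_real_)
    analysis$J01 <- j01
    if (is.finite(j01)) {
      analysis$helical_radius <- helical_radius_from_J01(j01)
      analysis$protofilaments <- tryCatch(
        protofilament_estimate(analysis$helical_radius),
        error = function(e) NA_integer_)
    }
  }
  manifest[[length(manifest) + 1]] <- manifest_record("analyze", 1, 1)

  structure(list(merged = merged, fitted = fitted, recon = recon,
                 analysis = analysis, stats = stats_df, angles = angles,
                 low_confidence = lowconf, kept = kept, labels = labels,
                 class_averages = lapply(averages, function(a)
                   list(n_members = a$n_members,
                        equatorial_angle = a$equatorial_angle,
                        contrast_score = a$contrast_score)),
                 manifest = manifest),
            class = "helix_pipeline")
}

#' @export
print.helix_pipeline <- function(x, ...) {
  cat("<helix_pipeline>\n")
  for (rec in x$manifest)
    cat(sprintf("  %-18s %6s -> %-6s\n", rec$stage,
                format(rec$n_in), format(rec$n_out)))
  if (!is.null(x$analysis$peak_to_peak))
    cat(sprintf("  peak-to-peak %.2f nm", x$analysis$peak_to_peak))
  if (!is.null(x$analysis$helical_radius))
    cat(sprintf(", helical radius %.2f nm (%d pf)",
                x$analysis$helical_radius, x$analysis$protofilaments))
  cat("\n")
  invisible(x)
}

#' Write a run manifest to disk
#'
#' @param pipeline A `helix_pipeline` result.
#' @param path Output file (JSON).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(pipeline, path) {
  jsonlite::write_json(pipeline$manifest, path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
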