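#' Real-space image grid
#'
#' Defines the discretization shared by model projections and reconstructions:
#' a rectangular pixel raster with an explicit origin. Coordinates follow the
#' fiber-diffraction layout used throughout the package: `x` runs along
#' columns, perpendicular to the helical axis, and `y` runs along rows, along
#' the helical axis.
#'
#' @param n_rows,n_cols Grid dimensions in pixels.
#' @param pixel_size Real-space pixel size in nm.
#' @param center Origin as `(row, col)`; defaults to the FFT-friendly center
#'   pixel `(floor(n/2) + 1, floor(m/2) + 1)`.
#' @return An object of class `grid2d`.
#' @export
grid2d <- function(n_rows, n_cols = n_rows, pixel_size = 0.5, center = NULL) {
  stopifnot(n_rows >= 4, n_cols >= 4, pixel_size > 0)
  if (is.null(center)) center <- c(floor(n_rows / 2) + 1, floor(n_cols / 2) + 1)
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    pixel_size = pixel_size, center = center
  ), class = "grid2d")
}

#' @export
print.grid2d <- function(x, ...) {
  cat(sprintf(
    "<grid2d> %d x %d px, %.3g nm/px (field %.0f x %.0f nm), origin (%g, %g)\n",
    x$n_rows, x$n_cols, x$pixel_size,
    x$n_rows * x$pixel_size, x$n_cols * x$pixel_size,
    x$center[1], x$center[2]
  ))
  invisible(x)
}

# x (perpendicular to axis, nm) of each column; y (along axis, nm) of each row
grid_x <- function(grid) (seq_len(grid$n_cols) - grid$center[2]) * grid$pixel_size
grid_y <- function(grid) (seq_len(grid$n_rows) - grid$center[1]) * grid$pixel_size

# Reciprocal-space step (spatial frequency 1/d, nm^-1) of the grid's DFT
grid_q_step <- function(grid) {
  c(row = 1 / (grid$n_rows * grid$pixel_size),
    col = 1 / (grid$n_cols * grid$pixel_size))
}

# Move the DFT origin (element [1,1]) to the center pixel and back. For even
# sizes ifftshift2 is the exact inverse of fftshift2.
fftshift2 <- function(m) {
  n <- nrow(m); p <- ncol(m)
  m[c((floor(n / 2) + 1):n, 1:floor(n / 2)),
    c((floor(p / 2) + 1):p, 1:floor(p / 2))]
}

ifftshift2 <- function(m) {
  n <- nrow(m); p <- ncol(m)
  m[c((ceiling(n / 2) + 1):n, 1:ceiling(n / 2)),
    c((ceiling(p / 2) + 1):p, 1:ceiling(p / 2))]
}

# Centered 2D DFT: input and output both have their origin at the center
# pixel (floor(n/2)+1). Used by the simulator and the phase-retrieval cycle.
cfft2 <- function(m, inverse = FALSE) {
  out <- fftshift2(stats::fft(ifftshift2(m), inverse = inverse))
  if (inverse) out / length(m) else out
}

# 3-point parabolic refinement of a local maximum at index i of profile v;
# returns the fractional index of the vertex (falls back to i at the edges).
parabolic_peak <- function(v, i) {
  if (i <= 1L || i >= length(v)) return(as.numeric(i))
  y1 <- v[i - 1]; y2 <- v[i]; y3 <- v[i + 1]
  den <- y1 - 2 * y2 + y3
  if (!is.finite(den) || den == 0) return(as.numeric(i))
  i + 0.5 * (y1 - y3) / den
}
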