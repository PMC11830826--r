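#' Sampling grid for angle-resolved complex fields
#'
#' Defines the shared real-space / k-space lattice used throughout the
#' package. Lengths are in micrometres and wave vectors in rad/um. The
#' forward Fourier convention is \eqn{\tilde f(k) = \int f(r) e^{-i k r} dr},
#' and k-space is centred: on even-sized axes k = 0 sits at (1-based) index
#' `n/2 + 1`.
#'
#' @param nx,ny Pixel counts along x and y (at least 8).
#' @param dx Pixel pitch in the sample plane (um).
#' @param wavelength Vacuum wavelength (um).
#' @param n_medium Refractive index of the immersion/mounting medium.
#' @param na_det Detection numerical aperture.
#' @param na_ill Illumination numerical aperture (must not exceed `na_det`).
#' @return A `grid2d` object: list with the above fields plus derived
#'   quantities `dkx`, `dky` (k-space pitch, rad/um) and `k_medium`
#'   (\eqn{2 \pi n / \lambda}).
#' @examples
#' g <- grid2d(64, 64, dx = 0.2, wavelength = 0.532, n_medium = 1.33,
#'             na_det = 1.15, na_ill = 1.0)
#' g$dkx * g$nx * g$dx / (2 * pi)  # = 1 by construction
#' @export
grid2d <- function(nx, ny = nx, dx, wavelength, n_medium = 1.33,
                   na_det = n_medium, na_ill = na_det) {
  if (nx < 8 || ny < 8) stop("grid must be at least 8x8 pixels")
  stopifnot_scalar(dx, "dx")
  stopifnot_scalar(wavelength, "wavelength")
  if (na_ill > na_det + 1e-12) stop("na_ill must not exceed na_det")
  k_na <- 2 * pi * na_det / wavelength
  if (k_na > pi / dx + 1e-9) {
    stop(sprintf(
      "detection pupil (k_NA = %.3f rad/um) exceeds the Nyquist limit pi/dx = %.3f; decrease dx",
      k_na, pi / dx))
  }
  g <- list(nx = as.integer(nx), ny = as.integer(ny), dx = dx,
            wavelength = wavelength, n_medium = n_medium,
            na_det = na_det, na_ill = na_ill,
            dkx = 2 * pi / (nx * dx), dky = 2 * pi / (ny * dx),
            k_medium = 2 * pi * n_medium / wavelength)
  class(g) <- "grid2d"
  g
}

#' @export
print.grid2d <- function(x, ...) {
  cat(sprintf(
    "<grid2d> %d x %d px, dx = %g um, lambda = %g um, n = %g, NA det/ill = %g/%g\n",
    x$nx, x$ny, x$dx, x$wavelength, x$n_medium, x$na_det, x$na_ill))
  invisible(x)
}

# Centred axes. x runs over (0:(n-1) - floor(n/2)) * dx, likewise k.
grid_axis_r <- function(n, dx) (seq_len(n) - 1 - floor(n / 2)) * dx
grid_axis_k <- function(n, dk) (seq_len(n) - 1 - floor(n / 2)) * dk

#' Coordinate matrices for a grid
#'
#' @param grid A [grid2d()].
#' @param space `"r"` for sample-plane coordinates (um) or `"k"` for
#'   wave vectors (rad/um).
#' @return List with matrices `x`, `y` of dim `c(nx, ny)` (first index x).
#' @export
grid_coords <- function(grid, space = c("k", "r")) {
  space <- match.arg(space)
  if (space == "r") {
    ax <- grid_axis_r(grid$nx, grid$dx); ay <- grid_axis_r(grid$ny, grid$dx)
  } else {
    ax <- grid_axis_k(grid$nx, grid$dkx); ay <- grid_axis_k(grid$ny, grid$dky)
  }
  list(x = matrix(ax, grid$nx, grid$ny),
       y = matrix(ay, grid$nx, grid$ny, byrow = TRUE))
}

#' Spatial-frequency coordinates u = k / (2 pi)
#'
#' Convenience accessor mirroring [grid_coords()] but in inverse
#' micrometres (the unit in which tilt magnitudes such as
#' \eqn{\Delta u = 0.0054 \lambda^{-1}} are usually quoted).
#'
#' @inheritParams grid_coords
#' @return List with matrices `u`, `v` (um^-1).
#' @export
grid_coords_u <- function(grid) {
  kc <- grid_coords(grid, "k")
  list(u = kc$x / (2 * pi), v = kc$y / (2 * pi))
}

fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c(seq(floor(n1 / 2) + 1, n1), seq_len(floor(n1 / 2))),
    c(seq(floor(n2 / 2) + 1, n2), seq_len(floor(n2 / 2)))]
}

ifftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c(seq(ceiling(n1 / 2) + 1, n1), seq_len(ceiling(n1 / 2))),
    c(seq(ceiling(n2 / 2) + 1, n2), seq_len(ceiling(n2 / 2)))]
}

#' Centred 2D Fourier transform
#'
#' Forward transform with the `exp(-i k r)` convention and continuous
#' normalisation: a constant image `c` maps to a single pixel of value
#' `c * nx * ny * dx^2` at the k = 0 pixel (array centre).
#'
#' @param field Complex (or numeric) matrix of dim `c(nx, ny)`.
#' @param grid A [grid2d()] matching the field shape.
#' @return Complex matrix of k-space samples on the centred lattice.
#' @export
fft2_centered <- function(field, grid) {
  if (nrow(field) != grid$nx || ncol(field) != grid$ny) {
    stop("field shape does not match grid")
  }
  fftshift2(stats::fft(ifftshift2(field))) * grid$dx^2
}

#' Inverse of [fft2_centered()]
#'
#' @param kimage Complex matrix on the centred k lattice.
#' @inheritParams fft2_centered
#' @return Complex real-space matrix; `ifft2_centered(fft2_centered(f))`
#'   reproduces `f` to machine precision.
#' @export
ifft2_centered <- function(kimage, grid) {
  if (nrow(kimage) != grid$nx || ncol(kimage) != grid$ny) {
    stop("k-image shape does not match grid")
  }
  fftshift2(stats::fft(ifftshift2(kimage), inverse = TRUE)) /
    (grid$nx * grid$ny * grid$dx^2)
}

#' Sample a spectrum on a sub-pixel shifted k lattice
#'
#' Returns the Fourier samples of `field` evaluated at `k + delta_k`,
#' exactly for band-limited fields and arbitrary (sub-pixel) shifts: the
#' real-space field is multiplied by `exp(-i delta_k . r)` before the
#' forward transform. Integer-pixel shifts therefore agree with an integer
#' roll of the unshifted spectrum.
#'
#' @param field Complex matrix of dim `c(nx, ny)`.
#' @param delta_k Length-2 numeric, shift (rad/um).
#' @param grid A [grid2d()].
#' @return Complex matrix: `fft2_centered` of the phase-ramped field.
#' @export
shift_sample_kspace <- function(field, delta_k, grid) {
  stopifnot(length(delta_k) == 2)
  k_na <- 2 * pi * grid$na_det / grid$wavelength
  if (sqrt(sum(delta_k^2)) >= k_na) {
    warning("|delta_k| exceeds the detection pupil radius; the tilt-tilt correlation is undefined there")
  }
  if (all(delta_k == 0)) return(fft2_centered(field, grid))
  rc <- grid_coords(grid, "r")
  fft2_centered(field * exp(-1i * (delta_k[1] * rc$x + delta_k[2] * rc$y)), grid)
}

#' Pupil support mask
#'
#' Logical mask on the centred k lattice, true where
#' \eqn{|k| \le 2 \pi \mathrm{NA} / \lambda}. Symmetric under k -> -k by
#' construction of the centred axes.
#'
#' @param grid A [grid2d()].
#' @param na Numerical aperture; defaults to the grid's detection NA.
#' @return Logical matrix of dim `c(nx, ny)`.
#' @export
pupil_mask <- function(grid, na = grid$na_det) {
  if (!is.numeric(na) || na <= 0) stop("na must be positive")
  if (na > grid$n_medium + 1e-9) stop("na cannot exceed n_medium")
  kc <- grid_coords(grid, "k")
  sqrt(kc$x^2 + kc$y^2) <= 2 * pi * na / grid$wavelength + 1e-12
}

# 1-based index of the k = 0 pixel.
grid_center_index <- function(grid) {
  c(floor(grid$nx / 2) + 1L, floor(grid$ny / 2) + 1L)
}

# Spectral power within a mask (Parseval bookkeeping).
spectral_power <- function(kimage, grid, mask = NULL) {
  p <- Mod(kimage)^2
  if (!is.null(mask)) p <- p[mask]
  sum(p) * grid$dkx * grid$dky / (2 * pi)^2
}
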