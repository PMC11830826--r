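#' Illumination layout of tilt groups
#'
#' Places group centres on a Fermat spiral inside the illumination NA, each
#' with two extra incidences tilted along two orthogonal directions — the
#' minimum needed to recover a 2D phase gradient. The default tilt spans
#' one k-space pixel of the grid, which is what the commonly used
#' `Delta u = 0.0054 / lambda` amounts to at a typical camera field of
#' view; tilts must stay well inside the memory-effect range, and
#' sub-pixel values are handled exactly by the phase-ramp sampler.
#'
#' @param grid A [grid2d()].
#' @param n_groups Number of groups (76 mirrors the experimental layout;
#'   24 is a fast preset).
#' @param delta_u Tilt magnitude as a spatial frequency (um^-1); the wave
#'   vector tilt is `2 pi delta_u`. Default: one k-pixel,
#'   `1 / (nx dx)`.
#' @param na_frac Fraction of the illumination NA to fill (margin so that
#'   tilted incidences stay inside).
#' @param snap Round the group centres to the k lattice (required by the
#'   CLASS baseline, whose K-indexing presupposes a common lattice).
#' @return List of [tilt_group()]s.
#' @export
illumination_groups <- function(grid, n_groups = 24,
                                delta_u = 1 / (grid$nx * grid$dx),
                                na_frac = 0.9, snap = FALSE) {
  dk <- 2 * pi * delta_u
  k_ill_full <- 2 * pi * grid$na_ill / grid$wavelength
  # leave room for the tilted incidences on coarse grids
  k_ill <- min(k_ill_full * na_frac, k_ill_full - 1.5 * dk)
  if (k_ill <= 0) stop("tilt magnitude does not fit inside the illumination NA")
  golden <- pi * (3 - sqrt(5))
  lapply(seq_len(n_groups), function(i) {
    r <- if (n_groups == 1) 0 else k_ill * sqrt((i - 1) / (n_groups - 1))
    th <- (i - 1) * golden
    kc <- c(r * cos(th), r * sin(th))
    if (snap) {
      kc <- c(round(kc[1] / grid$dkx) * grid$dkx,
              round(kc[2] / grid$dky) * grid$dky)
    }
    tilt_group(kc, list(c(dk, 0), c(0, dk)), grid = grid)
  })
}

#' Ground-truth pupil aberration screen
#'
#' Deterministic given `(spec, seed)`. Two generators: `"zernike"`
#' (analytic low-order polynomials via [zernike_phase()]) and
#' `"correlated"` (Gaussian random phase with Gaussian autocorrelation of
#' width `corr_px` k-pixels, normalised to the requested RMS on the pupil
#' support).
#'
#' @param spec List: `list(kind = "zernike", coefficients = c(...))` or
#'   `list(kind = "correlated", rms = <rad>, corr_px = <pixels>)`.
#' @param grid A [grid2d()].
#' @param seed Integer seed (used by the correlated generator).
#' @return An [aberration_function()] carrying the screen phase, with the
#'   generator spec attached as attribute `"screen_spec"`.
#' @export
make_aberration_screen <- function(spec, grid, seed = 1L) {
  support <- pupil_mask(grid)
  kind <- spec$kind %||% "zernike"
  if (kind == "zernike") {
    phase <- zernike_phase(grid, spec$coefficients)
  } else if (kind == "correlated") {
    rms <- spec$rms %||% 1
    if (rms > 20) stop("requested screen RMS > 20 rad is unphysical for a pupil model")
    corr_px <- spec$corr_px %||% 3
    phase <- with_seed(seed, {
      w <- matrix(stats::rnorm(grid$nx * grid$ny), grid$nx, grid$ny)
      gaussian_blur(w, corr_px / sqrt(2))
    })
    v <- phase[support]
    phase <- (phase - mean(v)) / stats::sd(v) * rms
    phase[!support] <- 0
  } else {
    stop("unknown screen kind: ", kind)
  }
  out <- aberration_function(phase, support, grid, "outgoing",
                             gauge = list(piston = "generator"))
  attr(out, "screen_spec") <- c(spec, list(seed = seed))
  out
}

# Periodic Gaussian blur with kernel standard deviation `sigma_px` pixels.
gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  n1 <- nrow(m); n2 <- ncol(m)
  f1 <- exp(-2 * pi^2 * sigma_px^2 * (((seq_len(n1) - 1 + n1 / 2) %% n1 - n1 / 2) / n1)^2)
  f2 <- exp(-2 * pi^2 * sigma_px^2 * (((seq_len(n2) - 1 + n2 / 2) %% n2 - n2 / 2) / n2)^2)
  Re(stats::fft(stats::fft(m) * outer(f1, f2), inverse = TRUE)) / (n1 * n2)
}

# Gaussian sigma (pixels) of a field's autocorrelation, from real-space
# lag products restricted to `mask` (internal; validates screen specs).
# For an ACF exp(-r^2/(2 s^2)), -2 log rho(l) = l^2 / s^2.
estimate_acf_sigma <- function(m, mask = NULL, max_lag = 8L) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(m), ncol(m))
  mu <- mean(m[mask]); v0 <- stats::var(m[mask])
  lags <- seq_len(max_lag)
  rho <- vapply(lags, function(l) {
    ok <- mask[seq_len(nrow(m) - l), ] & mask[-seq_len(l), ]
    a <- (m[seq_len(nrow(m) - l), ] - mu)[ok]
    b <- (m[-seq_len(l), ] - mu)[ok]
    okc <- mask[, seq_len(ncol(m) - l)] & mask[, -seq_len(l)]
    a2 <- (m[, seq_len(ncol(m) - l)] - mu)[okc]
    b2 <- (m[, -seq_len(l)] - mu)[okc]
    (sum(a * b) + sum(a2 * b2)) / (length(a) + length(a2)) / v0
  }, numeric(1))
  use <- rho > 0.2
  if (!any(use)) return(NA_real_)
  sqrt(sum(lags[use]^4) / sum(lags[use]^2 * (-2 * log(rho[use]))))
}

#' Thin complex-transmittance phantom
#'
#' @param kind `"letterA"` (a phase letter on unit background), `"dots"`
#'   (random absorbing point scatterers), `"rough"` (unit-modulus random
#'   phase per pixel, i.e. a fully developed diffuser — the regime the
#'   image-synthesis baseline assumes), or `"uniform"`.
#' @param grid A [grid2d()].
#' @param strength Phase excursion (rad) of the letter, or dot absorption
#'   depth in `(0, 1]`.
#' @param n_dots Number of dots for `"dots"`.
#' @param seed Seed for the dot positions / roughness.
#' @return Complex matrix `S(r)` with `|S| <= 1`, class `phantom_thin`.
#' @export
phantom_thin <- function(kind = c("letterA", "dots", "rough", "uniform"),
                         grid, strength = 1, n_dots = 40, seed = 1L) {
  kind <- match.arg(kind)
  S <- matrix(1 + 0i, grid$nx, grid$ny)
  if (kind == "letterA") {
    mask <- rasterize_letter_a(grid$nx, grid$ny)
    S[mask] <- exp(1i * strength)
  } else if (kind == "dots") {
    idx <- with_seed(seed, sample.int(grid$nx * grid$ny, n_dots))
    S[idx] <- 1 - min(strength, 1)
  } else if (kind == "rough") {
    S <- with_seed(seed, matrix(exp(2i * pi * stats::runif(grid$nx * grid$ny)),
                                grid$nx, grid$ny))
    # a letter-shaped amplitude pattern on the diffuser
    S[rasterize_letter_a(grid$nx, grid$ny)] <-
      S[rasterize_letter_a(grid$nx, grid$ny)] * 0.4
  }
  class(S) <- c("phantom_thin", class(S))
  S
}

# Letter "A" stroke mask in a centred ~60% box.
rasterize_letter_a <- function(nx, ny) {
  x <- seq(0, 1, length.out = nx); y <- seq(0, 1, length.out = ny)
  X <- matrix(x, nx, ny); Y <- matrix(y, nx, ny, byrow = TRUE)
  seg <- function(x1, y1, x2, y2, w) {
    vx <- x2 - x1; vy <- y2 - y1
    t <- pmin(pmax(((X - x1) * vx + (Y - y1) * vy) / (vx^2 + vy^2), 0), 1)
    (X - x1 - t * vx)^2 + (Y - y1 - t * vy)^2 < w^2
  }
  w <- 0.035
  seg(0.30, 0.25, 0.50, 0.75, w) | seg(0.70, 0.25, 0.50, 0.75, w) |
    seg(0.385, 0.46, 0.615, 0.46, w)
}

#' Volumetric refractive-index phantom
#'
#' @param values 3D array of refractive index, dim `c(nx, ny, nz)`.
#' @param dz Slice spacing (um).
#' @param z0 z-coordinate (um) of the first slice centre; the volume spans
#'   `z0 + (0:(nz-1)) dz`.
#' @return A `phantom_volume` object.
#' @export
phantom_volume <- function(values, dz, z0 = -(dim(values)[3] - 1) * dz / 2) {
  stopifnot(length(dim(values)) == 3, all(values >= 1))
  structure(list(values = values, dz = dz, z0 = z0), class = "phantom_volume")
}

#' Weakly scattering sphere phantom
#'
#' @param grid A [grid2d()].
#' @param radius Sphere radius (um).
#' @param delta_n RI contrast above the medium.
#' @param center Length-3 centre (um), z relative to the focal plane.
#' @param dz,nz Axial sampling.
#' @return A [phantom_volume()].
#' @export
phantom_sphere <- function(grid, radius = 2, delta_n = 0.01,
                           center = c(0, 0, 0), dz = grid$dx, nz = 32) {
  rc <- grid_coords(grid, "r")
  z <- (seq_len(nz) - 1 - floor(nz / 2)) * dz
  vol <- array(grid$n_medium, c(grid$nx, grid$ny, nz))
  for (iz in seq_len(nz)) {
    d2 <- (rc$x - center[1])^2 + (rc$y - center[2])^2 + (z[iz] - center[3])^2
    vol[, , iz][d2 <= radius^2] <- grid$n_medium + delta_n
  }
  phantom_volume(vol, dz, z0 = z[1])
}

#' Random fibrous thick phantom
#'
#' Smooth correlated RI fluctuations emulating a fibrous tissue slab; used
#' to generate data with a finite angular memory-effect range.
#'
#' @param grid A [grid2d()].
#' @param thickness_um Slab thickness (um).
#' @param delta_n_rms RMS RI contrast.
#' @param corr_um Lateral correlation length (um).
#' @param dz Slice spacing (um).
#' @param seed Seed.
#' @return A [phantom_volume()] centred on the focal plane.
#' @export
phantom_fibrous <- function(grid, thickness_um = 24, delta_n_rms = 0.02,
                            corr_um = 1.2, dz = 2, seed = 1L) {
  nz <- max(2L, round(thickness_um / dz))
  vol <- with_seed(seed, {
    a <- array(stats::rnorm(grid$nx * grid$ny * nz), c(grid$nx, grid$ny, nz))
    for (iz in seq_len(nz)) {
      a[, , iz] <- gaussian_blur(a[, , iz], corr_um / grid$dx / sqrt(2))
    }
    # mild axial smoothing links slices into fibre-like structures
    if (nz >= 3) {
      a <- (a + a[, , c(1, seq_len(nz - 1))] + a[, , c(seq_len(nz - 1) + 1, nz)]) / 3
    }
    a
  })
  vol <- vol / stats::sd(vol) * delta_n_rms
  phantom_volume(grid$n_medium + pmax(vol, 1 - grid$n_medium), dz,
                 z0 = -(nz - 1) * dz / 2)
}

# Bilinear sample of a pupil-phase matrix at arbitrary k (rad/um).
interp_phase <- function(phase, grid, k) {
  fx <- k[1] / grid$dkx + floor(grid$nx / 2) + 1
  fy <- k[2] / grid$dky + floor(grid$ny / 2) + 1
  ix <- floor(fx); iy <- floor(fy)
  if (ix < 1 || ix + 1 > grid$nx || iy < 1 || iy + 1 > grid$ny) {
    stop("k outside the sampled pupil grid")
  }
  wx <- fx - ix; wy <- fy - iy
  (1 - wx) * (1 - wy) * phase[ix, iy] + wx * (1 - wy) * phase[ix + 1, iy] +
    (1 - wx) * wy * phase[ix, iy + 1] + wx * wy * phase[ix + 1, iy + 1]
}

screen_phase <- function(screen, grid) {
  if (is.null(screen)) return(matrix(0, grid$nx, grid$ny))
  if (inherits(screen, "aberration_function")) screen$phase else screen
}

#' Thin-target forward model
#'
#' Exact discrete realisation of the single-plane aberration model:
#' the plane-wave illumination acquires the incoming pupil phase at its
#' incidence angle, is multiplied by the thin transmittance `S(r)`, and the
#' outgoing spectrum is multiplied by `exp(i phi_out)` on the detection
#' pupil.
#'
#' @param groups List of [tilt_group()]s (see [illumination_groups()]).
#' @param screen_in,screen_out Incoming/outgoing pupil screens
#'   ([aberration_function()] or plain phase matrices); `NULL` for none.
#' @param phantom A [phantom_thin()] complex transmittance.
#' @param grid A [grid2d()].
#' @param noise_snr Per-pixel amplitude SNR of added complex Gaussian
#'   noise; `Inf` (default) for noise-free fields.
#' @param seed Seed for the noise.
#' @return A [field_stack()].
#' @export
forward_thin <- function(groups, screen_in = NULL, screen_out = NULL,
                         phantom, grid, noise_snr = Inf, seed = 1L) {
  phi_in <- screen_phase(screen_in, grid)
  phi_out <- screen_phase(screen_out, grid)
  support <- pupil_mask(grid)
  rc <- grid_coords(grid, "r")
  out_filter <- exp(1i * phi_out) * support
  S <- unclass(phantom)
  data <- lapply(groups, function(gr) {
    slots <- c(list(c(0, 0)), gr$tilt_offsets)
    lapply(slots, function(d) {
      kin <- gr$k_center + d
      e_ill <- exp(1i * (kin[1] * rc$x + kin[2] * rc$y)) *
        exp(1i * interp_phase(phi_in, grid, kin))
      spec <- fft2_centered(e_ill * S, grid) * out_filter
      f <- ifft2_centered(spec, grid)
      add_field_noise(f, noise_snr, seed + 17L)
    })
  })
  field_stack(grid, groups, data)
}

add_field_noise <- function(f, snr, seed) {
  if (!is.finite(snr)) return(f)
  sigma <- sqrt(mean(Mod(f)^2)) / snr
  f + with_seed(seed, matrix(crnorm(length(f), sd = sigma), nrow(f), ncol(f)))
}

# Axial wave number kz(k + k_offset) on the grid; evanescent bins NA.
# The offset realises a tilted (envelope) propagator, exact for off-grid
# plane-wave carriers.
propagator_kz <- function(grid, wavelength = grid$wavelength,
                          k_offset = c(0, 0)) {
  kc <- grid_coords(grid, "k")
  km <- 2 * pi * grid$n_medium / wavelength
  kz2 <- km^2 - (kc$x + k_offset[1])^2 - (kc$y + k_offset[2])^2
  kz <- sqrt(pmax(kz2, 0))
  kz[kz2 < 0] <- NA  # evanescent; zeroed by callers
  kz
}

#' Thick-target forward model (multi-slice split-step)
#'
#' The target operator is realised by beam propagation through the RI
#' volume: each slice multiplies the field by
#' `exp(i k0 (n - n_medium) dz)` and free-space angular-spectrum
#' propagation advances between slices. The exit field is numerically
#' back-propagated to the focal plane z = 0 before the outgoing pupil
#' screen is applied, so the reference illumination at z = 0 is exactly
#' the plane wave `exp(i k_in r)`. This generates data with a finite
#' angular memory-effect range, unlike [forward_thin()].
#'
#' @inheritParams forward_thin
#' @param phantom A [phantom_volume()].
#' @return A [field_stack()].
#' @export
forward_thick <- function(groups, screen_in = NULL, screen_out = NULL,
                          phantom, grid, noise_snr = Inf, seed = 1L) {
  stopifnot(inherits(phantom, "phantom_volume"))
  phi_in <- screen_phase(screen_in, grid)
  phi_out <- screen_phase(screen_out, grid)
  support <- pupil_mask(grid)
  rc <- grid_coords(grid, "r")
  k0 <- 2 * pi / grid$wavelength
  dn_max <- max(abs(phantom$values - grid$n_medium))
  if (dn_max > 0 && phantom$dz > grid$wavelength / (4 * dn_max)) {
    warning("slice thickness exceeds lambda/(4 dn_max); split-step accuracy degrades")
  }
  nz <- dim(phantom$values)[3]
  # slices are discrete screens at z_j = z0 + (j-1) dz; propagation runs
  # between slice planes only, so a single-slice volume reduces exactly
  # to the thin model
  z_exit <- phantom$z0 + (nz - 1) * phantom$dz
  out_filter <- exp(1i * phi_out) * support
  slices <- lapply(seq_len(nz), function(iz) {
    exp(1i * k0 * (phantom$values[, , iz] - grid$n_medium) * phantom$dz)
  })
  data <- lapply(groups, function(gr) {
    slots <- c(list(c(0, 0)), gr$tilt_offsets)
    lapply(slots, function(d) {
      kin <- gr$k_center + d
      # envelope (tilted-carrier) split-step: E = exp(i k_in r) * a(r);
      # the envelope spectrum advances with kz(k + k_in), exact for
      # off-grid (sub-pixel tilted) carriers
      kz <- propagator_kz(grid, k_offset = kin)
      valid <- !is.na(kz)
      kz0 <- ifelse(valid, kz, 0)
      step <- exp(1i * kz0 * phantom$dz) * valid
      back <- exp(-1i * kz0 * z_exit) * valid
      a <- matrix(exp(1i * interp_phase(phi_in, grid, kin)) *
                    exp(1i * sqrt(grid$k_medium^2 - sum(kin^2)) * phantom$z0),
                  grid$nx, grid$ny)
      carrier <- exp(1i * (kin[1] * rc$x + kin[2] * rc$y))
      for (iz in seq_len(nz)) {
        a <- a * slices[[iz]]
        if (iz < nz) a <- ifft2_centered(fft2_centered(a, grid) * step, grid)
      }
      a <- ifft2_centered(fft2_centered(a, grid) * back, grid)
      spec <- fft2_centered(carrier * a, grid) * out_filter
      f <- ifft2_centered(spec, grid)
      add_field_noise(f, noise_snr, seed + 23L)
    })
  })
  field_stack(grid, groups, data)
}
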