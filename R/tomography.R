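#' 3D refractive-index tomogram
#'
#' @param values Real 3D array, dim `c(nx, ny, nz)`.
#' @param grid The lateral [grid2d()].
#' @param dz Axial voxel pitch (um).
#' @param z0 z-coordinate (um) of the first slice (relative to focal plane).
#' @return A `tomogram` object.
#' @export
tomogram <- function(values, grid, dz, z0 = -(dim(values)[3] - 1) * dz / 2) {
  stopifnot(length(dim(values)) == 3, all(is.finite(values)))
  structure(list(values = values, grid = grid, dz = dz, z0 = z0,
                 n_medium = grid$n_medium),
            class = "tomogram")
}

#' @export
print.tomogram <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<tomogram> %d x %d x %d voxels, pitch %.3g x %.3g um, RI range [%.4f, %.4f]\n",
              d[1], d[2], d[3], x$grid$dx, x$dz, min(x$values), max(x$values)))
  invisible(x)
}

#' Propagate a 2D field to a set of axial planes
#'
#' Angular-spectrum method: `E(r, z) = IFT[ FT(E) exp(i k_z(k) z) ]` with
#' `k_z = sqrt(k_medium^2 - |k|^2)`; evanescent components are zeroed
#' (with a warning when they carry energy).
#'
#' @param field Complex matrix at z = 0.
#' @param z_planes Numeric vector of target planes (um).
#' @param grid A [grid2d()].
#' @return Complex array of dim `c(nx, ny, length(z_planes))`.
#' @export
angular_spectrum_propagate <- function(field, z_planes, grid) {
  spec <- fft2_centered(field, grid)
  kz <- propagator_kz(grid)
  ev <- is.na(kz)
  if (any(ev) && sum(Mod(spec[ev])^2) > 1e-9 * sum(Mod(spec)^2)) {
    warning("field has energy beyond k_medium; evanescent components zeroed")
  }
  kz0 <- ifelse(ev, 0, kz)
  out <- array(0i, c(grid$nx, grid$ny, length(z_planes)))
  for (i in seq_along(z_planes)) {
    out[, , i] <- ifft2_centered(spec * exp(1i * kz0 * z_planes[i]) * !ev, grid)
  }
  out
}

#' Wrapped-gradient Rytov data of a corrected field
#'
#' Finite differences of the complex log of the normalised field without
#' any 2D phase unwrapping: the real part is the difference of
#' `log |E / E_in|` and the imaginary part the *wrapped* difference of
#' `arg(E / E_in)`, each divided by the pixel pitch. Well defined even in
#' the presence of phase vortices, where path-dependent unwrapping fails.
#'
#' @param field Complex matrix (aberration-corrected outgoing field at the
#'   focal plane).
#' @param k_in Length-2 incident wave vector (rad/um) of the plane-wave
#'   illumination.
#' @param grid A [grid2d()].
#' @param amplitude_floor Relative amplitude floor applied before the log
#'   (the log diverges at zeros); warns when more than 20 percent of
#'   pixels sit at the floor (Rytov validity).
#' @return List of complex matrices `gx`, `gy` (per um, periodic forward
#'   differences).
#' @export
rytov_gradient_data <- function(field, k_in, grid, amplitude_floor = 1e-3) {
  rc <- grid_coords(grid, "r")
  ratio <- field * exp(-1i * (k_in[1] * rc$x + k_in[2] * rc$y))
  a <- Mod(ratio)
  floor_v <- amplitude_floor * max(a)
  low <- a < floor_v
  if (mean(low) > 0.2) {
    warning("amplitude below the floor on > 20% of pixels; Rytov validity is doubtful")
  }
  la <- log(pmax(a, floor_v))
  ph <- Arg(ratio)
  roll <- function(m, di, dj) {
    n1 <- nrow(m); n2 <- ncol(m)
    m[((seq_len(n1) - 1 + di) %% n1) + 1, ((seq_len(n2) - 1 + dj) %% n2) + 1]
  }
  gx <- (roll(la, 1, 0) - la) / grid$dx +
    1i * wrap_phase(roll(ph, 1, 0) - ph) / grid$dx
  gy <- (roll(la, 0, 1) - la) / grid$dx +
    1i * wrap_phase(roll(ph, 0, 1) - ph) / grid$dx
  list(gx = gx, gy = gy)
}

# Recover the 2D spectrum of the complex Rytov phase psi = log(E/E_in)
# from its periodic forward-difference data, dividing by the discrete
# difference transfer function; the irrecoverable DC bin is zeroed.
psi_spectrum_from_gradients <- function(g, grid) {
  sx <- fft2_centered(g$gx, grid)
  sy <- fft2_centered(g$gy, grid)
  kc <- grid_coords(grid, "k")
  fx <- (exp(1i * kc$x * grid$dx) - 1) / grid$dx
  fy <- (exp(1i * kc$y * grid$dx) - 1) / grid$dx
  denom <- Mod(fx)^2 + Mod(fy)^2
  psi <- (Conj(fx) * sx + Conj(fy) * sy)
  ok <- denom > (min(grid$dkx, grid$dky) / 10)^2
  psi[ok] <- psi[ok] / denom[ok]
  psi[!ok] <- 0i
  psi
}

#' Reconstruct a refractive-index tomogram (gradient-based Rytov)
#'
#' For every corrected incidence the wrapped-gradient Rytov data are
#' converted to the complex Rytov phase spectrum and mapped onto the
#' Ewald sphere cap of the scattering-potential spectrum
#' (`V = k0^2 (n^2 - n_medium^2)`, Fourier diffraction theorem
#' `V~(k - k_in, kz - kz_in) = -2 i kz psi~(k)`). The axial inverse
#' transform is evaluated at the exact (off-lattice) `Kz` of every sample
#' — a nonuniform discrete transform with density compensation (samples
#' sharing a `Kz` cell are averaged), which avoids the gridding phase
#' error that would blur axially displaced structures. No iterative
#' regularization is applied. The irrecoverable global offset is fixed by
#' setting the volume background (median) to `n_medium`.
#'
#' @param stack A corrected [field_stack()] (incoming offsets applied).
#' @param z_range Length-2 axial range (um) or vector of z planes.
#' @param dz Axial voxel pitch (um); defaults to the lateral pitch.
#' @param use_all_slots Use tilted slots as extra incidences (default) or
#'   central incidences only.
#' @param na_limit Restrict the mapped detection band to this NA.
#' @return A [tomogram()].
#' @export
reconstruct_tomogram <- function(stack, z_range = c(-8, 8), dz = NULL,
                                 use_all_slots = TRUE, na_limit = NULL) {
  grid <- stack$grid
  dz <- dz %||% grid$dx
  z <- if (length(z_range) == 2) seq(z_range[1], z_range[2], by = dz) else z_range
  nz <- length(z)
  dkz <- 2 * pi / (nz * dz)
  kc <- grid_coords(grid, "k")
  km <- grid$k_medium
  na_l <- na_limit %||% grid$na_det
  k_band <- 2 * pi * na_l / grid$wavelength
  # pass 1: collect per-view Ewald-cap samples
  samples <- list()
  for (g in seq_len(n_groups(stack))) {
    slots <- if (use_all_slots) seq_along(stack$data[[g]]) else 1L
    for (s in slots) {
      kin <- stack_kin(stack, g, s)
      if (sum(kin^2) >= km^2) next
      kz_in <- sqrt(km^2 - sum(kin^2))
      gdat <- rytov_gradient_data(stack_field(stack, g, s), kin, grid)
      psi <- psi_spectrum_from_gradients(gdat, grid)
      # the normalised ratio removed the carrier, so the spectrum bin q
      # corresponds to the outgoing wave vector k_out = q + k_in
      kox <- kc$x + kin[1]; koy <- kc$y + kin[2]
      ko2 <- kox^2 + koy^2
      band <- ko2 <= k_band^2 & ko2 < km^2
      bidx <- which(band)
      if (!length(bidx)) next
      kz_out <- sqrt(km^2 - ko2[bidx])
      samples[[length(samples) + 1L]] <-
        list(bidx = bidx, kzrel = kz_out - kz_in,
             val = -2i * kz_out * psi[bidx])
      # the scattering potential is real, so every sample also determines
      # the Hermitian mirror point (-q, -Kz); adding it fills the
      # one-sided low-q axial coverage of a transmission geometry
      bi <- arrayInd(bidx, c(grid$nx, grid$ny))
      ci2 <- grid_center_index(grid)
      mx <- 2L * ci2[1] - bi[, 1]; my <- 2L * ci2[2] - bi[, 2]
      okm <- mx >= 1 & mx <= grid$nx & my >= 1 & my <= grid$ny
      samples[[length(samples) + 1L]] <-
        list(bidx = (my[okm] - 1L) * grid$nx + mx[okm],
             kzrel = -(kz_out - kz_in)[okm],
             val = Conj(-2i * kz_out * psi[bidx])[okm])
    }
  }
  if (!length(samples)) stop("empty spectral coverage; no usable incidences")
  # density compensation: samples sharing a (lateral bin, Kz cell) average
  kz_cells <- ceiling(2 * km / dkz)
  keys <- lapply(samples, function(sm) {
    (round(sm$kzrel / dkz) + kz_cells) * grid$nx * grid$ny + sm$bidx
  })
  uk <- sort(unique(unlist(keys)))
  cnt <- tabulate(match(unlist(keys), uk), nbins = length(uk))
  # pass 2: exact nonuniform Kz -> z transform per lateral bin
  acc <- array(0i, c(grid$nx, grid$ny, nz))
  dim(acc) <- c(grid$nx * grid$ny, nz)
  for (i in seq_along(samples)) {
    sm <- samples[[i]]
    w <- 1 / cnt[match(keys[[i]], uk)]
    phase <- exp(1i * outer(sm$kzrel, z))
    acc[sm$bidx, ] <- acc[sm$bidx, ] + (sm$val * w) * phase
  }
  # continuous normalisation: each occupied Kz cell contributes dkz/(2 pi)
  # to the axial inverse integral; the lateral inverse is the centred 2D
  # IFT, whose 1/(N dx^2) factor equals the dq^2/(2 pi)^2 measure
  acc <- acc * dkz / (2 * pi)
  dim(acc) <- c(grid$nx, grid$ny, nz)
  V <- array(0, c(grid$nx, grid$ny, nz))
  for (iz in seq_len(nz)) {
    V[, , iz] <- Re(ifft2_centered(acc[, , iz], grid))
  }
  k0 <- 2 * pi / grid$wavelength
  V <- V - stats::median(V)  # DC is irrecoverable; pin background
  n_vol <- sqrt(pmax(grid$n_medium^2 + V / k0^2, 0.25))
  tomogram(n_vol, grid, dz, z0 = z[1])
}

# fftshift/ifftshift along all three axes of a 3D array.
apply_shift3 <- function(a, inverse = FALSE) {
  d <- dim(a)
  ix <- lapply(d, function(n) {
    h <- if (inverse) ceiling(n / 2) else floor(n / 2)
    c(seq(h + 1, n), seq_len(h))
  })
  a[ix[[1]], ix[[2]], ix[[3]]]
}

#' Write a tomogram as a 32-bit float TIFF stack plus YAML metadata
#'
#' @param tomo A [tomogram()].
#' @param path Base path; writes `<path>.tif` and `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_tomogram <- function(tomo, path) {
  nz <- dim(tomo$values)[3]
  lo <- min(tomo$values); hi <- max(tomo$values)
  span <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF(lapply(seq_len(nz), function(iz) {
    (tomo$values[, , iz] - lo) / span
  }), paste0(path, ".tif"), bits.per.sample = 32L)
  yaml::write_yaml(list(dx = tomo$grid$dx, dz = tomo$dz, z0 = tomo$z0,
                        n_medium = tomo$n_medium,
                        scale = list(lo = lo, span = span)),
                   paste0(path, ".yaml"))
  invisible(path)
}
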