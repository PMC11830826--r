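#' Tilt-tilt field correlation curve
#'
#' Normalised cross-correlation of the k-space fields at incidences
#' differing by a small tilt,
#' \deqn{C(\Delta k) = \frac{\langle \tilde E^*(k; k_{in})
#'   \tilde E(k + \Delta k; k_{in} + \Delta k)\rangle_k}
#'   {\langle|\tilde E|^2\rangle_k^{1/2}
#'    \langle|\tilde E(+\Delta k)|^2\rangle_k^{1/2}},}
#' the g1-type correlation whose decay with tilt defines the angular
#' memory-effect range. The k-average runs over the detection pupil
#' intersected with its shifted copy and is pooled over groups; one curve
#' point is produced per tilt slot.
#'
#' @param stack A [field_stack()] whose slots `> 1` realise tilts of
#'   (possibly different) magnitudes.
#' @param slots Tilt slots to evaluate (default: all).
#' @return A data frame of class `correlation_curve`: `delta_u` (um^-1),
#'   `value` (complex), `modulus`, `n_pairs`. A `delta_u = 0` point with
#'   `C = 1` is always included.
#' @export
field_correlation <- function(stack, slots = NULL) {
  grid <- stack$grid
  support <- pupil_mask(grid)
  nslot <- min(vapply(stack$data, length, 1L))
  slots <- slots %||% seq(2L, nslot)
  if (n_groups(stack) < 2) {
    warning("fewer than 2 groups; correlation estimates have high variance")
  }
  kc <- grid_coords(grid, "k")
  k_na <- 2 * pi * grid$na_det / grid$wavelength
  rows <- list(list(delta_u = 0, value = 1 + 0i, n_pairs = n_groups(stack)))
  for (s in slots) {
    dk0 <- stack$groups[[1]]$tilt_offsets[[s - 1L]]
    num <- 0i; p1 <- 0; p2 <- 0; np <- 0L
    shifted_support <- sqrt((kc$x + dk0[1])^2 + (kc$y + dk0[2])^2) <= k_na
    mask <- support & shifted_support
    for (g in seq_len(n_groups(stack))) {
      dkg <- stack$groups[[g]]$tilt_offsets[[s - 1L]]
      if (max(abs(dkg - dk0)) > 1e-6) {
        stop("slot ", s, " has heterogeneous tilts across groups")
      }
      ec <- fft2_centered(stack_field(stack, g, 1L), grid)
      et <- shift_sample_kspace(stack_field(stack, g, s), dk0, grid)
      num <- num + sum(Conj(ec[mask]) * et[mask])
      p1 <- p1 + sum(Mod(ec[mask])^2)
      p2 <- p2 + sum(Mod(et[mask])^2)
      np <- np + 1L
    }
    rows[[length(rows) + 1L]] <-
      list(delta_u = sqrt(sum(dk0^2)) / (2 * pi),
           value = num / sqrt(p1 * p2), n_pairs = np)
  }
  df <- data.frame(delta_u = vapply(rows, `[[`, 1, "delta_u"),
                   modulus = Mod(vapply(rows, `[[`, 1i, "value")),
                   argument = Arg(vapply(rows, `[[`, 1i, "value")),
                   n_pairs = vapply(rows, `[[`, 1L, "n_pairs"))
  df <- df[order(df$delta_u), ]
  class(df) <- c("correlation_curve", class(df))
  df
}

#' Memory-effect range of a correlation curve
#'
#' Tilt magnitude at which `|C|` first falls to `1/e`, by linear
#' interpolation between curve samples.
#'
#' @param curve A `correlation_curve` (or data frame with `delta_u`,
#'   `modulus`).
#' @param threshold Correlation threshold (default `exp(-1)`).
#' @return The crossing `delta_u` in the curve's units; if the curve never
#'   crosses, the largest sampled `delta_u` with attribute
#'   `"lower_bound" = TRUE`.
#' @export
memory_effect_range <- function(curve, threshold = exp(-1)) {
  o <- order(curve$delta_u)
  du <- curve$delta_u[o]; m <- curve$modulus[o]
  below <- which(m < threshold)
  if (!length(below)) {
    out <- max(du)
    attr(out, "lower_bound") <- TRUE
    return(out)
  }
  i <- below[1]
  if (i == 1) return(du[1])
  if (m[i] > 0 && m[i - 1] > 0) {
    # interpolate in log space (exact for exponential decays)
    frac <- (log(m[i - 1]) - log(threshold)) / (log(m[i - 1]) - log(m[i]))
  } else {
    frac <- (m[i - 1] - threshold) / (m[i - 1] - m[i])
  }
  du[i - 1] + frac * (du[i] - du[i - 1])
}

#' 3D phase correlation of two fields
#'
#' Proxy for the 3D intensity PSF linking two measurements of the same
#' sample: both 2D fields are propagated to a z-stack by the angular
#' spectrum method, the unit-modulus 3D cross-spectrum is restricted to
#' the (pupil-truncated) Ewald shell `| |k3D| - k_medium | < dk/2`,
#' inverse transformed and normalised by the ideal-shell peak at the
#' origin; the squared modulus is returned. Identical aberration-free
#' fields give a peak of 1 at the origin; an aberration difference spreads
#' and lowers the peak exactly like its 3D PSF.
#'
#' @param field_a,field_b Complex matrices on `grid`.
#' @param grid A [grid2d()].
#' @param z_range Length-2 range (um) or vector of z planes.
#' @param dz Axial pitch (um); the default keeps the axial Nyquist wave
#'   number 20 percent above `k_medium` so the top of the Ewald shell is
#'   not aliased.
#' @return Real 3D array (squared correlation), with attribute `"peak"`.
#' @export
phase_correlation_3d <- function(field_a, field_b, grid,
                                 z_range = c(-8, 8), dz = NULL) {
  dz <- dz %||% min(grid$dx, pi / (1.2 * grid$k_medium))
  z <- if (length(z_range) == 2) seq(z_range[1], z_range[2], by = dz) else z_range
  nz <- length(z)
  if (nz < 8) warning("z range very small; the correlation peak may not be localised")
  ea <- angular_spectrum_propagate(field_a, z, grid)
  eb <- angular_spectrum_propagate(field_b, z, grid)
  fa <- apply_shift3(stats::fft(apply_shift3(ea, inverse = TRUE)), FALSE)
  fb <- apply_shift3(stats::fft(apply_shift3(eb, inverse = TRUE)), FALSE)
  cross <- fa * Conj(fb)
  km <- grid$k_medium
  dkz <- 2 * pi / (nz * dz)
  kc <- grid_coords(grid, "k")
  kzv <- (seq_len(nz) - 1 - floor(nz / 2)) * dkz
  shell_w <- max(grid$dkx, grid$dky, dkz) / 2
  k_na <- 2 * pi * grid$na_det / grid$wavelength
  kperp2 <- kc$x^2 + kc$y^2
  u <- array(0i, dim(cross))
  n_shell <- 0L
  shell_k <- list(); shell_u <- list()
  for (iz in seq_len(nz)) {
    kmag <- sqrt(kperp2 + kzv[iz]^2)
    on_shell <- abs(kmag - km) < shell_w & kzv[iz] > 0 & kperp2 <= k_na^2
    sl <- matrix(0i, grid$nx, grid$ny)
    cz <- cross[, , iz]
    sl[on_shell] <- exp(1i * Arg(cz[on_shell]))
    u[, , iz] <- sl
    if (any(on_shell)) {
      shell_k[[length(shell_k) + 1L]] <-
        cbind(kc$x[on_shell], kc$y[on_shell], kzv[iz])
      shell_u[[length(shell_u) + 1L]] <- sl[on_shell]
    }
    n_shell <- n_shell + sum(on_shell)
  }
  if (n_shell == 0) stop("no voxels on the Ewald shell; increase the z range")
  m <- apply_shift3(stats::fft(apply_shift3(u, inverse = TRUE), inverse = TRUE), FALSE)
  out <- (Mod(m) / n_shell)^2
  # the correlation peak is diffraction-sharp, so the lattice maximum can
  # undersample it; refine by direct evaluation on a sub-voxel grid
  pk <- which(out == max(out), arr.ind = TRUE)[1, ]
  r0 <- c(grid_axis_r(grid$nx, grid$dx)[pk[1]],
          grid_axis_r(grid$ny, grid$dx)[pk[2]], z[pk[3]])
  K <- do.call(rbind, shell_k)
  uu <- unlist(shell_u)
  best <- max(out)
  steps <- seq(-0.5, 0.5, by = 0.25)
  for (ddx in steps) for (ddy in steps) for (ddz in steps) {
    r <- r0 + c(ddx * grid$dx, ddy * grid$dx, ddz * dz)
    val <- (Mod(sum(uu * exp(1i * (K %*% r)))) / n_shell)^2
    if (val > best) best <- val
  }
  attr(out, "peak") <- best
  attr(out, "z") <- z
  out
}

#' Strehl ratio of a focus against an ideal (guide-star) focus
#'
#' @param focus_field Complex field at the target plane.
#' @param ideal_field Ideal reference focus (same grid and input power),
#'   e.g. from phase conjugation of a guide star.
#' @return `max |focus|^2 / max |ideal|^2`.
#' @export
strehl_ratio <- function(focus_field, ideal_field) {
  pk <- max(Mod(ideal_field)^2)
  if (pk == 0) stop("ideal field is zero")
  max(Mod(focus_field)^2) / pk
}
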