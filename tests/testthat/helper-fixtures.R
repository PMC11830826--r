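# Shared fixtures: small grids and synthetic stacks built in code.

test_grid <- function(nx = 64, dx = 0.2) {
  grid2d(nx, nx, dx = dx, wavelength = 0.532, n_medium = 1.33,
         na_det = 1.15, na_ill = 1.0)
}

random_field <- function(grid, seed = 1) {
  set.seed(seed)
  matrix(complex(real = rnorm(grid$nx * grid$ny),
                 imaginary = rnorm(grid$nx * grid$ny)),
         grid$nx, grid$ny)
}

# Band-limited random field (supported on the detection pupil).
bandlimited_field <- function(grid, seed = 1) {
  spec <- random_field(grid, seed) * pupil_mask(grid)
  ifft2_centered(spec, grid)
}

# Memory-effect-perfect stack built exactly in k-space: the target operator
# is unimodular, T(k_out; k_in) = exp(i psi(k_out - k_in)), so the
# tilt-pair product cancels it exactly (all k_in and tilts on-lattice).
exact_tilt_stack <- function(grid, phi_out, phi_in, n_groups = 8,
                             seed = 4) {
  set.seed(seed)
  psi <- matrix(runif(grid$nx * grid$ny, -pi, pi), grid$nx, grid$ny)
  support <- pupil_mask(grid)
  k_ill_px <- floor(2 * pi * grid$na_ill / grid$wavelength / grid$dkx * 0.7)
  centers <- lapply(seq_len(n_groups), function(i) {
    round(k_ill_px * (i - (n_groups + 1) / 2) / n_groups *
            c(cos(i), sin(i))) * c(grid$dkx, grid$dky)
  })
  roll_idx <- function(n, p) ((seq_len(n) - 1 + p) %% n) + 1
  groups <- lapply(centers, function(kc) {
    tilt_group(kc, list(c(grid$dkx, 0), c(0, grid$dky)))
  })
  ci <- c(floor(grid$nx / 2) + 1, floor(grid$ny / 2) + 1)
  data <- lapply(groups, function(gr) {
    lapply(c(list(c(0, 0)), gr$tilt_offsets), function(d) {
      kin <- gr$k_center + d
      px <- round(kin / c(grid$dkx, grid$dky))
      # sample psi(k - kin): index shift by -px (circular)
      psis <- psi[roll_idx(grid$nx, -px[1]), roll_idx(grid$ny, -px[2])]
      phin <- phi_in[ci[1] + px[1], ci[2] + px[2]]
      spec <- exp(1i * (phi_out + psis + phin)) * support
      ifft2_centered(spec, grid)
    })
  })
  field_stack(grid, groups, data)
}

# Circular correlation after piston/tip/tilt alignment (the gauge the
# integration leaves free).
aligned_circ_corr <- function(phase, truth, support, grid) {
  kc <- grid_coords(grid, "k")
  # fit the plane on the unwrapped error (the integrated phase and the
  # truth are both smooth surfaces; wrapping first would alias large
  # gauge tilts into a sawtooth the fit cannot follow)
  err <- (phase - truth)[support]
  X <- cbind(1, kc$x[support], kc$y[support])
  err <- err - X %*% qr.coef(qr(X), err)
  Mod(mean(exp(1i * err)))
}
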