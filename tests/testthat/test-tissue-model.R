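test_that("layer screens satisfy their invariants and determinism", {
  g <- tissue_grid(96)
  cfg <- tissue_config(deflection_rms = 2)
  l1 <- generate_layer_screens(cfg, g, seed = 4)
  l2 <- generate_layer_screens(cfg, g, seed = 4)
  expect_identical(l1$t[[3]], l2$t[[3]])
  expect_true(all(vapply(l1$t, function(t) max(Mod(t)) <= 1 + 1e-12, TRUE)))
  expect_identical(length(l1$t), 10L)
  expect_error(tissue_config(reflectance_total = 0.05), "0.04")
  # infeasible anisotropy on a coarse grid is rejected with a range
  g_coarse <- grid2d(64, 64, dx = 0.4, wavelength = 0.532, n_medium = 1.2,
                     na_det = 0.4)
  expect_error(generate_layer_screens(tissue_config(l_s = 500, l_t = 600),
                                      g_coarse), "feasible")
})

test_that("BPM through unity layers is free-space propagation", {
  g <- tissue_grid(64)
  cfg <- tissue_config(l_s = 1e9, l_t = 1e12, reflectance_total = 1e-12)
  layers <- generate_layer_screens(cfg, g, seed = 1)
  f <- bandlimited_field(g, seed = 2)
  bp <- bpm_propagate(f, layers, "forward", g)
  free <- angular_spectrum_propagate(f, 10 * length(layers$t), g)[, , 1]
  expect_lt(max(Mod(bp$exit - free)), 1e-10 * max(Mod(free)))
  # single phase-screen layer equals direct multiply-then-propagate
  cfg1 <- tissue_config(n_layers = 1)
  l1 <- generate_layer_screens(cfg1, g, seed = 3)
  bp1 <- bpm_propagate(f, l1, "forward", g)
  direct <- suppressWarnings(
    angular_spectrum_propagate(f * l1$t[[1]], 10, g))[, , 1]
  expect_lt(max(Mod(bp1$exit - direct)), 1e-10 * max(Mod(direct)))
})

test_that("the power audit closes: input = exit + reflected + clipped", {
  g <- tissue_grid(96)
  layers <- generate_layer_screens(tissue_config(), g, seed = 5)
  sr <- stack_reflectance(layers, g)
  bal <- (sr$audit[["exit"]] + sr$audit[["reflected"]] +
            sr$audit[["clipped"]]) / sr$audit[["input"]]
  # |t|^2 + |r|^2 = 1 pointwise, so only round-off and the per-layer
  # reflected power (never re-propagated) enter the balance
  expect_lt(abs(bal - 1), 1e-6)
  expect_lt(sr$reflectance, 0.04)
  # zero-variance screens: no ballistic decay
  cfg0 <- tissue_config(l_s = 1e9, l_t = 1e12, reflectance_total = 1e-12)
  l0 <- generate_layer_screens(cfg0, g, seed = 1)
  bp <- bpm_propagate(matrix(1 + 0i, 96, 96), l0, "forward", g)
  pb <- vapply(c(bp$incident[-1], list(bp$exit)),
               function(e) Mod(mean(e))^2, numeric(1))
  expect_lt(max(abs(pb - 1)), 1e-6)
})

test_that("fitted scattering lengths reproduce the configured targets", {
  g <- tissue_grid(128)
  fit <- fit_scattering_lengths(tissue_config(), g, seeds = 1:3)
  expect_lt(abs(fit$l_s - 53) / 53, 0.1)
  expect_lt(abs(fit$l_t - 1100) / 1100, 0.2)
})

test_that("the time gate has the requested axial width and no near replicas", {
  g <- tissue_grid(64)
  gate <- time_gate_spec(g, n_wavelengths = 20, fwhm_um = 11)
  z <- seq(-60, 60, by = 0.25)
  resp <- gate_axial_response(gate, z)
  half <- which(resp >= 0.5)
  fwhm <- z[max(half)] - z[min(half)]
  expect_lt(abs(fwhm - 11) / 11, 0.1)
  far <- abs(z) > 15 & abs(z) < 55
  expect_lt(max(resp[far]), 0.05)
  # a single wavelength applies no gating at all
  g1 <- time_gate_spec(g, n_wavelengths = 1)
  expect_true(all(abs(gate_axial_response(g1, z) - 1) < 1e-12))
})

test_that("the gate passes the reference depth and rejects off-depth reflectors", {
  g <- tissue_grid(64)
  cfg <- tissue_config(l_s = 1e9, l_t = 1e12, reflectance_total = 1e-12)
  layers <- generate_layer_screens(cfg, g, seed = 1)
  gate <- time_gate_spec(g, n_wavelengths = 20)
  grp <- list(tilt_group(c(0, 0)))
  # mirror at the reference depth (106 um): passes the gate
  st_on <- time_gated_reflection(grp, layers, matrix(0.1 + 0i, 64, 64),
                                 106, gate, g)
  a_on <- mean(Mod(stack_field(st_on, 1, 1)))
  # equal-amplitude reflector at the deepest layer (z = 90 um, 16 um off
  # the reference): suppressed by the 11-um coherence gate
  layers_off <- layers
  layers_off$r[[10]] <- matrix(0.1 + 0i, 64, 64)
  st_off <- time_gated_reflection(grp, layers_off, NULL, 106, gate, g)
  a_off <- mean(Mod(stack_field(st_off, 1, 1)))
  expect_lt(a_off, 0.15 * a_on)
  # without gating (single wavelength) the same reflector is not suppressed
  g1 <- time_gate_spec(g, n_wavelengths = 1)
  a_off1 <- mean(Mod(stack_field(
    time_gated_reflection(grp, layers_off, NULL, 106, g1, g), 1, 1)))
  expect_gt(a_off1, 0.5 * a_on)
})

test_that("focusing through free space is ideal and oracle correction works", {
  g <- tissue_grid(64)
  cfg0 <- tissue_config(l_s = 1e9, l_t = 1e12, reflectance_total = 1e-12)
  l0 <- generate_layer_screens(cfg0, g, seed = 1)
  free <- focusing_experiment(l0, 40, NULL, g)
  expect_gt(free$strehl, 0.999)
  # one deflecting screen: the time-reversed guide-star pupil phase
  # restores most of the focus
  cfg1 <- tissue_config(l_s = 1e9, l_t = 1e12, reflectance_total = 1e-12,
                        n_layers = 1, deflection_rms = 1,
                        deflection_corr_um = 5)
  l1 <- generate_layer_screens(cfg1, g, seed = 2)
  unc <- focusing_experiment(l1, 30, NULL, g)
  kz <- abermat:::propagator_kz(g)
  kz0 <- ifelse(is.na(kz), 0, kz)
  src <- matrix(0i, 64, 64); src[33, 33] <- 1
  b <- ifft2_centered(fft2_centered(src, g) * exp(1i * kz0 * 30) *
                        !is.na(kz), g)
  b <- b * l1$t[[1]]
  phi_true <- aberration_function(Arg(fft2_centered(b, g) *
                                        exp(-1i * kz0 * 30)),
                                  pupil_mask(g), g, "outgoing")
  cor <- focusing_experiment(l1, 30, time_reversal_incoming(phi_true), g)
  # phase-only pupil correction: the residual amplitude structure of the
  # diffracted screen caps the Strehl slightly below unity
  expect_gt(cor$strehl, 0.8)
  expect_gt(cor$strehl / unc$strehl, 2)
})
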