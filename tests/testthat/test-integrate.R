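make_diff_fields <- function(g, phi, dk1, dk2, erode = 0) {
  kc <- grid_coords(g, "k")
  k_na <- 2 * pi * g$na_det / g$wavelength
  sup <- sqrt(kc$x^2 + kc$y^2) <= k_na - erode
  idx <- which(sup)
  mk <- function(dk) {
    vapply(idx, function(ii) {
      k <- c(kc$x[ii], kc$y[ii])
      abermat:::interp_phase(phi, g, k + dk) - phi[ii]
    }, numeric(1))
  }
  list(f1 = abermat:::phase_difference_field(mk(dk1), dk1, "outgoing",
                                             index = idx, grid = g),
       f2 = abermat:::phase_difference_field(mk(dk2), dk2, "outgoing",
                                             index = idx, grid = g),
       sup = sup)
}

test_that("zero differences integrate to the zero phase", {
  g <- test_grid(32)
  sup <- pupil_mask(g)
  idx <- which(sup)
  z <- abermat:::phase_difference_field(rep(0, length(idx)), c(g$dkx, 0),
                                        "outgoing", index = idx, grid = g)
  z2 <- abermat:::phase_difference_field(rep(0, length(idx)), c(0, g$dky),
                                         "outgoing", index = idx, grid = g)
  out <- integrate_gradients(z, z2)
  expect_true(all(out$phase == 0))
})

test_that("a linear ramp is reproduced with tip/tilt retained", {
  g <- test_grid(32)
  kc <- grid_coords(g, "k")
  a <- 0.8
  phi <- a * kc$x
  ff <- make_diff_fields(g, phi, c(g$dkx, 0), c(0, g$dky), erode = 2 * g$dkx)
  out <- integrate_gradients(ff$f1, ff$f2)
  err <- (out$phase - phi)[out$support]
  expect_lt(max(abs(err - mean(err))), 1e-9)
  # with tilt removal the recovered phase is flat and the gauge records it
  out2 <- integrate_gradients(ff$f1, ff$f2, remove_tilt = TRUE)
  expect_lt(stats::sd(out2$phase[out2$support]), 1e-9)
  expect_equal(out2$gauge$mean_gradient[1], a, tolerance = 1e-6)
})

test_that("Zernike phases round-trip through differences to < 0.02 rad", {
  g <- test_grid(64)
  phi <- zernike_phase(g, c(defocus = 3, coma_x = 2))  # 5 rad peak-ish
  # sub-pixel tilt directions (the experimental regime)
  dk1 <- c(0.4 * g$dkx, 0); dk2 <- c(0, 0.4 * g$dky)
  ff <- make_diff_fields(g, phi, dk1, dk2, erode = 2 * g$dkx)
  out <- integrate_gradients(ff$f1, ff$f2)
  err <- (out$phase - phi)[out$support]
  expect_lt(max(abs(err - mean(err))), 0.02)
  # lattice-aligned tilts are exact
  ff2 <- make_diff_fields(g, phi, c(g$dkx, 0), c(0, g$dky), erode = 2 * g$dkx)
  out2 <- integrate_gradients(ff2$f1, ff2$f2)
  err2 <- (out2$phase - phi)[out2$support]
  expect_lt(max(abs(err2 - mean(err2))), 1e-8)
})

test_that("collinear tilt directions are rejected", {
  g <- test_grid(32)
  sup <- pupil_mask(g)
  idx <- which(sup)
  f1 <- abermat:::phase_difference_field(rep(0, length(idx)), c(g$dkx, 0),
                                         "outgoing", index = idx, grid = g)
  f2 <- abermat:::phase_difference_field(rep(0, length(idx)), c(2 * g$dkx, 0),
                                         "outgoing", index = idx, grid = g)
  expect_error(integrate_gradients(f1, f2), "collinear")
})

test_that("extension fills the pupil rim from the nearest valid pixels", {
  g <- test_grid(32)
  sup <- pupil_mask(g)
  inner <- pupil_mask(g, 0.9)
  phi <- aberration_function(zernike_phase(g, c(defocus = 1)) * inner,
                             inner, g, "outgoing")
  ext <- extend_aberration(phi, sup)
  expect_true(all(ext$support == sup))
  expect_equal(ext$phase[inner], phi$phase[inner])
  rim <- sup & !inner
  expect_true(all(is.finite(ext$phase[rim])))
  expect_lt(max(abs(ext$phase[rim])), max(abs(phi$phase[inner])) + 0.1)
})

test_that("the PSF of a flat pupil is Airy-like and ramps shift it", {
  g <- test_grid(64)
  sup <- pupil_mask(g)
  flat <- aberration_function(matrix(0, 64, 64), sup, g, "outgoing")
  p0 <- retrieve_psf(flat)
  expect_equal(sum(Mod(p0)^2), 1, tolerance = 1e-12)
  pk <- which(Mod(p0) == max(Mod(p0)), arr.ind = TRUE)
  expect_equal(as.integer(pk), c(33L, 33L))
  # linear ramp a*kx shifts the PSF by -a under the exp(-i k r) forward
  # convention (Fourier shift theorem)
  kc <- grid_coords(g, "k")
  shift_px <- 4L
  ramp <- aberration_function(shift_px * g$dx * kc$x * sup, sup, g, "outgoing")
  p1 <- retrieve_psf(ramp)
  pk1 <- which(Mod(p1) == max(Mod(p1)), arr.ind = TRUE)
  expect_equal(as.integer(pk1), c(33L - shift_px, 33L))
  expect_error(retrieve_psf(aberration_function(matrix(0, 64, 64),
                                                matrix(FALSE, 64, 64),
                                                g, "outgoing")), "empty")
})

test_that("weak random screens obey the Marechal Strehl estimate", {
  g <- test_grid(64)
  for (s in c(0.3, 0.5)) {
    scr <- make_aberration_screen(list(kind = "correlated", rms = s,
                                       corr_px = 4), g, seed = 12)
    p <- retrieve_psf(scr)
    p0 <- retrieve_psf(aberration_function(matrix(0, 64, 64), scr$support,
                                           g, "outgoing"))
    strehl <- max(Mod(p)^2) / max(Mod(p0)^2)
    expect_lt(abs(strehl - exp(-s^2)) / exp(-s^2), 0.2)
  }
})

test_that("end-to-end recovery holds for screens up to 3 rad RMS", {
  g <- test_grid(96)
  si <- make_aberration_screen(list(kind = "zernike",
                                    coefficients = c(defocus = 1.5,
                                                     coma_x = 0.8)), g)
  groups <- illumination_groups(g, 24)
  for (rms in c(1.5, 3)) {
    so <- make_aberration_screen(list(kind = "correlated", rms = rms,
                                      corr_px = 5), g, seed = 9)
    st <- forward_thin(groups, si, so, phantom_thin("letterA", g), g)
    det <- detect_aberration(st)
    sup <- det$phi_out$support & so$support
    expect_gt(aligned_circ_corr(det$phi_out$phase, so$phase, sup, g), 0.99)
  }
})
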