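test_that("outgoing windowing is pointwise and matches the convolution theorem", {
  g <- grid2d(8, 8, dx = 0.3, wavelength = 0.532, n_medium = 1.33,
              na_det = 0.8)
  f <- random_field(g, seed = 1)
  st <- field_stack(g, list(tilt_group(c(0, 0))), list(list(f)))
  ones <- window_spec("array", values = matrix(1, 8, 8))
  expect_identical(window_outgoing(st, ones)$data[[1]][[1]], f)
  w <- window_spec("gaussian", sigma = 0.6)
  wf <- window_outgoing(st, w)$data[[1]][[1]]
  # convolution-theorem oracle on the 8x8 field: the windowed spectrum is
  # the circular convolution of the two centred spectra
  Fw <- fft2_centered(abermat:::window_values(w, g), g)
  Ff <- fft2_centered(f, g)
  ctr <- 5L
  wrap8 <- function(i) ((i - 1L) %% 8L) + 1L
  conv <- matrix(0i, 8, 8)
  for (a in 1:8) for (b in 1:8) {
    acc <- 0i
    for (p in 1:8) for (q in 1:8) {
      acc <- acc + Ff[p, q] * Fw[wrap8(a - p + ctr), wrap8(b - q + ctr)]
    }
    conv[a, b] <- acc * g$dkx * g$dky / (2 * pi)^2
  }
  expect_lt(max(Mod(fft2_centered(wf, g) - conv)), 1e-10 * max(Mod(conv)))
  # attenuation at a point scatterer equals the window value there
  expect_equal(wf[3, 6], f[3, 6] * abermat:::window_values(w, g)[3, 6])
})

test_that("incoming-window synthesis uses the 4/2/1 moduli and localises a beam", {
  g <- test_grid(64)
  # scan pitch chosen so the (periodic) synthesized window spans the FOV:
  # the 3 x 3 coefficient comb has period 2 pi / dk_scan in the sample plane
  dk_scan <- g$dkx
  syn <- incoming_window_synthesis(dk_scan)
  r2 <- vapply(syn$offsets, function(o) sum((o / dk_scan)^2), numeric(1))
  expect_identical(syn$moduli[r2 == 0], 4)
  expect_true(all(syn$moduli[abs(r2 - 1) < 1e-9] == 2))
  expect_true(all(syn$moduli[abs(r2 - 2) < 1e-9] == 1))
  # free-space plane waves: the synthesized illumination peaks at r_c
  groups <- illumination_groups(g, 5, delta_u = 0.5 / (g$nx * g$dx),
                                snap = TRUE)
  S <- phantom_thin("uniform", g)
  stacks <- lapply(syn$offsets, function(o) {
    shifted <- lapply(groups, function(gr) {
      tilt_group(gr$k_center + o, gr$tilt_offsets)
    })
    forward_thin(shifted, NULL, NULL, S, g)
  })
  sc <- scanned_stack(stacks, syn)
  r_c <- c(2.4, -1.6)
  win <- window_incoming(sc, r_c)
  beam <- Mod(stack_field(win, 2, 1))^2
  pk <- which(beam == max(beam), arr.ind = TRUE)
  rc <- grid_coords(g, "r")
  expect_lt(abs(rc$x[pk[1], 1] - r_c[1]), 2 * g$dx + 1e-9)
  expect_lt(abs(rc$y[1, pk[2]] - r_c[2]), 2 * g$dx + 1e-9)
  # >= 60% of the beam energy within 3 effective widths of r_c
  d2 <- (rc$x - r_c[1])^2 + (rc$y - r_c[2])^2
  sigma_eff <- 1 / (dk_scan / 2)  # transform width of the 3x3 coefficient set
  frac <- sum(beam[d2 <= (3 * sigma_eff)^2]) / sum(beam)
  expect_gte(frac, 0.6)
  # a 1x1 synthesis with unit coefficient is the identity
  syn1 <- incoming_window_synthesis(dk_scan)
  syn1$offsets <- list(c(0, 0)); syn1$moduli <- 1
  sc1 <- scanned_stack(stacks[5], syn1)
  expect_equal(window_incoming(sc1, c(0, 0))$data[[1]][[1]],
               stacks[[5]]$data[[1]][[1]], tolerance = 1e-12)
  expect_error(scanned_stack(stacks[1:3], syn), "missing scan offsets")
})

test_that("uniform aberrations give consistent per-patch estimates", {
  g <- test_grid(96)
  so <- make_aberration_screen(list(kind = "correlated", rms = 1.5,
                                    corr_px = 5), g, seed = 21)
  st <- forward_thin(illumination_groups(g, 16), NULL, so,
                     phantom_thin("letterA", g), g)
  centers <- list(c(-4, 0), c(0, 0), c(4, 0))
  res <- detect_per_patch(st, centers, window_sigma = 5)
  expect_length(res$failures, 0)
  sup <- Reduce(`&`, lapply(res$phi_out, `[[`, "support"))
  for (i in c(1, 3)) {
    expect_gt(aligned_circ_corr(res$phi_out[[i]]$phase,
                                res$phi_out[[2]]$phase, sup, g), 0.98)
  }
  expect_true(all(res$relative[[2]][sup] == 0))
})

test_that("a two-region aberration phantom separates into its patches", {
  g <- test_grid(96)
  sA <- make_aberration_screen(list(kind = "correlated", rms = 1.5,
                                    corr_px = 6), g, seed = 31)
  sB <- make_aberration_screen(list(kind = "correlated", rms = 1.5,
                                    corr_px = 6), g, seed = 32)
  groups <- illumination_groups(g, 16)
  stA <- forward_thin(groups, NULL, sA, phantom_thin("letterA", g), g)
  stB <- forward_thin(groups, NULL, sB, phantom_thin("letterA", g), g)
  rc <- grid_coords(g, "r")
  left <- rc$x < 0
  st <- stack_map(stA, function(f, gi, s) {
    f * left + stB$data[[gi]][[s]] * !left
  })
  res <- detect_per_patch(st, list(c(-4.8, 0), c(4.8, 0)), window_sigma = 3)
  sup <- sA$support & pupil_mask(g, 1.0)
  cLA <- aligned_circ_corr(res$phi_out[[1]]$phase, sA$phase, sup, g)
  cLB <- aligned_circ_corr(res$phi_out[[1]]$phase, sB$phase, sup, g)
  cRB <- aligned_circ_corr(res$phi_out[[2]]$phase, sB$phase, sup, g)
  cRA <- aligned_circ_corr(res$phi_out[[2]]$phase, sA$phase, sup, g)
  expect_gt(cLA, cLB + 0.2)
  expect_gt(cRB, cRA + 0.2)
})

test_that("stitching recovers injected constant offsets exactly", {
  g <- test_grid(48)
  set.seed(7)
  base <- array(g$n_medium + 0.01 * rnorm(48 * 48 * 6), c(48, 48, 6))
  offsets <- c(0, 0.003, -0.002)
  centers <- list(c(-3.2, 0), c(0, 0), c(3.2, 0))
  patches <- lapply(offsets, function(o) tomogram(base + o, g, dz = 0.5))
  out <- stitch_tomograms(patches, centers, overlap_margin = 1.5,
                          background_sigma = 0)
  rec <- attr(out, "patch_offsets")
  expect_lt(max(abs((rec - rec[2]) - (offsets - offsets[2]))), 1e-9)
  # the stitched volume equals the centre patch (up to the global gauge)
  expect_lt(max(abs(out$values - patches[[2]]$values)), 1e-9)
  # single patch: identity when the background filter is off
  one <- stitch_tomograms(patches[2], centers[2], background_sigma = 0)
  expect_equal(one$values, patches[[2]]$values, tolerance = 1e-12)
})

test_that("the isoplanatic correlation length follows the closed form", {
  expect_warning(lc <- correlation_length(100, 100, 0.4), "small-angle")
  expect_equal(lc, 0.4 / sqrt(2))
  expect_equal(correlation_length(1100, 110, 0.4),
               0.4 / sqrt(2) * sqrt(10), tolerance = 1e-12)
  expect_error(correlation_length(-1, 10, 0.4), "positive")
  # cross-check against the angular spectrum of a simulated slab:
  # l_c ~ 1 / sqrt(<(sin theta / lambda)^2>) within a factor of 1.5
  g <- tissue_grid(96)
  cfg <- tissue_config()
  layers <- generate_layer_screens(cfg, g, seed = 2)
  bp <- bpm_propagate(matrix(1 + 0i, 96, 96), layers, "forward", g)
  spec <- Mod(fft2_centered(bp$exit, g))^2
  kc <- grid_coords(g, "k")
  sin2 <- (kc$x^2 + kc$y^2) / g$k_medium^2
  lam_med <- g$wavelength / g$n_medium
  msq <- sum(spec * sin2 / lam_med^2) / sum(spec)
  lc_sim <- 1 / sqrt(msq)
  L_total <- cfg$n_layers * cfg$dz_layer
  lc_theory <- correlation_length(cfg$l_t, L_total, lam_med)
  expect_lt(max(lc_sim / lc_theory, lc_theory / lc_sim), 1.5)
})
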