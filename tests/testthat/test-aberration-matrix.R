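test_that("the matrix phase separates exactly on memory-effect-perfect data", {
  g <- test_grid(48)
  set.seed(5)
  phi_out <- zernike_phase(g, c(defocus = 1.2, coma_x = 0.7, astig_oblique = 0.5))
  phi_in <- zernike_phase(g, c(defocus = -0.8, tilt = 0.6))
  st <- exact_tilt_stack(g, phi_out, phi_in, n_groups = 6)
  A <- build_aberration_matrix(st, 2)
  # predicted: [phi_out(k+dk) - phi_out(k)] + [phi_in(kin+dk) - phi_in(kin)]
  dpo <- rbind(phi_out[-1, ], 0) - phi_out
  ci <- c(25, 25)
  for (gi in c(1, 4)) {
    px <- round(st$groups[[gi]]$k_center / c(g$dkx, g$dky))
    dpi <- phi_in[ci[1] + px[1] + 1, ci[2] + px[2]] -
      phi_in[ci[1] + px[1], ci[2] + px[2]]
    pred <- dpo[A$pupil_index] + dpi
    ok <- Mod(A$entries[, gi]) > 0.5 * stats::median(Mod(A$entries[, gi]))
    err <- wrap_phase(Arg(A$entries[, gi]) - pred)[ok]
    expect_lt(max(abs(err)), 1e-6)
  }
})

test_that("an aberration-free thin target gives a flat matrix phase", {
  g <- test_grid(48)
  st <- forward_thin(illumination_groups(g, 8), NULL, NULL,
                     phantom_thin("letterA", g), g)
  A <- threshold_reweight(build_aberration_matrix(st, 2), list(q = 0.6))
  args <- Arg(A$entries[Mod(A$entries) > 0])
  expect_lt(max(abs(args)), 0.05)
})

test_that("the raw modulus approximates the squared target spectrum", {
  g <- test_grid(48)
  st <- exact_tilt_stack(g, matrix(0, 48, 48), matrix(0, 48, 48), n_groups = 4)
  A <- build_aberration_matrix(st, 2)
  # |T| = 1 on the pupil for the exact stack, so |A| = 1 there
  m <- Mod(A$entries[, 1])
  sup_ok <- m > 0.5
  expect_lt(max(abs(m[sup_ok] - 1)), 1e-6)
})

test_that("thresholding keeps the advertised survivors and is idempotent", {
  g <- test_grid(16)
  A0 <- build_aberration_matrix(
    forward_thin(illumination_groups(g, 4), NULL, NULL,
                 phantom_thin("letterA", g), g), 2)
  # numeric threshold on a printed 6 x 4 matrix of moduli
  moduli <- c(3, 1, 0.2, 0.8, 0.45, 2, 0.55, 0.1, 0.9, 1.4, 0.3, 0.5,
              0.7, 0.05, 1.1, 0.6, 0.51, 0.49, 2.2, 0.15, 0.65, 0.25, 1.7, 0.35)
  Am <- A0
  Am$entries <- matrix(moduli * exp(1i * seq_along(moduli)), 6, 4)
  Am$pupil_index <- A0$pupil_index[1:6]
  Am$kin <- A0$kin
  thr <- threshold_reweight(Am, 0.5)
  expect_identical(sum(Mod(thr$entries) > 0), sum(moduli > 0.5))
  expect_true(all(abs(Mod(thr$entries[Mod(thr$entries) > 0]) - 1) < 1e-12))
  expect_identical(thr$weight_state, "thresholded")
  # quantile spec keeps exactly ceiling((1 - q) * n_nonzero) survivors
  thq <- threshold_reweight(Am, "q:0.7")
  expect_identical(sum(Mod(thq$entries) > 0), as.integer(ceiling(0.3 * 24)))
  # idempotence
  thr2 <- threshold_reweight(thr, 0.5)
  expect_equal(thr2$entries, thr$entries)
  # a threshold above everything warns about an ill-posed factorization
  expect_warning(threshold_reweight(Am, 10), "ill-posed")
})

test_that("off-diagonal masking matches brute-force distance tests", {
  g <- test_grid(48)
  st <- forward_thin(illumination_groups(g, 6), NULL, NULL,
                     phantom_thin("letterA", g), g)
  A <- build_aberration_matrix(st, 2)
  Am <- mask_offdiagonal(A, 0.35)
  kc <- grid_coords(g, "k")
  r <- 2 * pi * 0.35 / g$wavelength
  for (gi in c(2, 5)) {
    d <- sqrt((kc$x[A$pupil_index] - A$kin[1, gi])^2 +
                (kc$y[A$pupil_index] - A$kin[2, gi])^2)
    expect_true(all(Am$entries[d > r, gi] == 0))
    expect_equal(Am$entries[d <= r, gi], A$entries[d <= r, gi])
  }
  # radius at the detection NA is a no-op for near-axis incidences
  g0 <- mask_offdiagonal(A, g$na_det)
  expect_equal(g0$entries[, 1], A$entries[, 1])
})

test_that("both factorizations recover an exact rank-1 unimodular matrix", {
  set.seed(8)
  g <- test_grid(16)
  A0 <- build_aberration_matrix(
    forward_thin(illumination_groups(g, 6), NULL, NULL,
                 phantom_thin("letterA", g), g), 2)
  n <- nrow(A0$entries); m <- ncol(A0$entries)
  u <- runif(n, -pi, pi); v <- runif(m, -pi, pi)
  A0$entries <- exp(1i * u) %o% exp(1i * v)
  A0$weight_state <- "thresholded"
  for (fac in list(factorize_svd(A0), factorize_projection_power(A0))) {
    est <- fac$dphi_out$values + rep(fac$dphi_in$values, each = 0)  # keep shape
    # combine both sides: A_hat = e^{i out} e^{i in^T} must equal A
    Ahat <- exp(1i * fac$dphi_out$values) %o% exp(1i * fac$dphi_in$values)
    expect_lt(max(Mod(Ahat - A0$entries)), 1e-9)
  }
  # the power iteration hits the fixed point immediately
  fp <- factorize_projection_power(A0)
  expect_true(attr(fp, "converged"))
  expect_lte(attr(fp, "iterations"), 2L)
  expect_true(all(diff(attr(fp, "objective")) > -1e-9))
})

test_that("an all-ones matrix factorizes to zero phases", {
  g <- test_grid(16)
  A0 <- build_aberration_matrix(
    forward_thin(illumination_groups(g, 4), NULL, NULL,
                 phantom_thin("letterA", g), g), 2)
  A0$entries <- matrix(1 + 0i, nrow(A0$entries), ncol(A0$entries))
  A0$weight_state <- "thresholded"
  fac <- factorize_projection_power(A0)
  expect_lt(max(abs(fac$dphi_out$values)), 1e-12)
  expect_lt(max(abs(fac$dphi_in$values)), 1e-12)
  A0$entries[] <- 0i
  expect_error(factorize_projection_power(A0), "zero")
  expect_error(factorize_svd(A0), "zero")
})

test_that("noisy rank-1 factorization stays accurate and power beats SVD", {
  g <- test_grid(16)
  A0 <- build_aberration_matrix(
    forward_thin(illumination_groups(g, 8), NULL, NULL,
                 phantom_thin("letterA", g), g), 2)
  n <- nrow(A0$entries); m <- ncol(A0$entries)
  # sigma = 0.1: circular correlation of the recovered factors > 0.99
  set.seed(42)
  u <- runif(n, -pi, pi); v <- runif(m, -pi, pi)
  A0$entries <- exp(1i * u) %o% exp(1i * v) +
    matrix(complex(real = rnorm(n * m, sd = 0.1 / sqrt(2)),
                   imaginary = rnorm(n * m, sd = 0.1 / sqrt(2))), n, m)
  A0$weight_state <- "thresholded"
  fac <- factorize_projection_power(A0)
  expect_gt(Mod(mean(exp(1i * (fac$dphi_out$values - u)))), 0.99)
  # paired comparison at sigma = 0.3 over 50 seeded trials on thresholded
  # matrices with missing entries (the pipeline's regime): the projection
  # power iteration must never be systematically worse than the SVD
  wins <- 0L; advantage <- numeric(0)
  for (s in 1:50) {
    set.seed(s)
    u <- runif(n, -pi, pi); v <- runif(m, -pi, pi)
    A0$weight_state <- "raw"
    E <- exp(1i * u) %o% exp(1i * v) +
      matrix(complex(real = rnorm(n * m, sd = 0.3 / sqrt(2)),
                     imaginary = rnorm(n * m, sd = 0.3 / sqrt(2))), n, m)
    E[sample(n * m, round(0.6 * n * m))] <- 0i
    A0$entries <- E
    At <- threshold_reweight(A0, 0)
    ep <- factorize_projection_power(At)
    es <- factorize_svd(At)
    err <- function(fac) {
      ok <- fac$dphi_out$valid
      1 - Mod(mean(exp(1i * (fac$dphi_out$values[ok] - u[ok]))))
    }
    advantage <- c(advantage, err(es) - err(ep))
    if (err(ep) <= err(es) + 1e-12) wins <- wins + 1L
  }
  expect_gte(mean(advantage), 0)
  expect_gte(wins, 25L)
})

test_that("the projection power iteration attains the brute-force UQP optimum", {
  # exhaustive oracle on a 3 x 3 matrix over a 16^3 phase grid
  set.seed(3)
  M0 <- matrix(complex(real = rnorm(9), imaginary = rnorm(9)), 3, 3)
  M <- Conj(t(M0)) %*% M0  # PSD Hermitian
  phases <- seq(-pi, pi, length.out = 17)[-17]
  best <- -Inf
  for (a in phases) for (b in phases) for (cc in phases) {
    v <- exp(1i * c(a, b, cc))
    val <- Re(Conj(v) %*% M %*% v)[1]
    if (val > best) best <- val
  }
  v <- c(1, 1, 1) + 0i
  for (it in 1:200) v <- exp(1i * Arg(M %*% v)[, 1])
  attained <- Re(Conj(v) %*% M %*% v)[1]
  # discretization penalty of the 16-point grid is O(step^2)
  expect_gte(attained, best - 1e-9)
  expect_lte(best, attained + 0.05 * abs(attained))
})

test_that("factorization consistency: residual phases centre on zero", {
  g <- test_grid(48)
  so <- make_aberration_screen(list(kind = "correlated", rms = 2, corr_px = 4),
                               g, seed = 6)
  st <- forward_thin(illumination_groups(g, 12), NULL, so,
                     phantom_thin("letterA", g), g)
  A <- threshold_reweight(build_aberration_matrix(st, 2), list(q = 0.6))
  fac <- factorize_projection_power(A)
  surv <- Mod(A$entries) > 0
  pred <- outer(fac$dphi_out$values, rep(1, ncol(A$entries))) +
    outer(rep(1, nrow(A$entries)), fac$dphi_in$values)
  res <- wrap_phase(Arg(A$entries) - pred)[surv]
  expect_lt(abs(Arg(mean(exp(1i * res)))), 0.02)
  expect_gt(Mod(mean(exp(1i * res))), 0.9)
})
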