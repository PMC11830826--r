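#' Correct the outgoing aberration of a field stack
#'
#' Phase-only pupil deconvolution: every field's spectrum is multiplied by
#' `exp(-i phi_out(k))` on the pupil support (the modulus of the pupil
#' function is taken as 1, so spectral energy within the pupil is
#' conserved).
#'
#' @param stack A [field_stack()].
#' @param phi_out An outgoing [aberration_function()] on the stack's grid.
#' @return The corrected [field_stack()].
#' @export
correct_outgoing <- function(stack, phi_out) {
  grid <- stack$grid
  if (!identical(dim(phi_out$phase), c(grid$nx, grid$ny))) {
    stop("aberration function support does not match the stack grid")
  }
  filt <- matrix(1 + 0i, grid$nx, grid$ny)
  filt[phi_out$support] <- exp(-1i * phi_out$phase[phi_out$support])
  stack_map(stack, function(f, g, s) {
    ifft2_centered(fft2_centered(f, grid) * filt, grid)
  })
}

#' Correct the incoming aberration of a field stack
#'
#' Under plane-wave illumination the incoming aberration reduces to one
#' constant phase offset per incidence: each field of group `g`, slot `s`
#' is multiplied by the scalar `exp(-i phi_in(k_in))`, with `phi_in`
#' interpolated bilinearly at the incidence wave vector. Needed before
#' tomographic synthesis; optional for single-field viewing.
#'
#' @param stack A [field_stack()].
#' @param phi_in An incoming [aberration_function()].
#' @return The corrected [field_stack()].
#' @export
correct_incoming <- function(stack, phi_in) {
  grid <- stack$grid
  ci <- grid_center_index(grid)
  stack_map(stack, function(f, g, s) {
    kin <- stack_kin(stack, g, s)
    ix <- round(kin[1] / grid$dkx) + ci[1]
    iy <- round(kin[2] / grid$dky) + ci[2]
    inside <- ix >= 1 && ix <= grid$nx && iy >= 1 && iy <= grid$ny &&
      phi_in$support[ix, iy]
    val <- if (inside) {
      interp_phase(phi_in$phase, grid, kin)
    } else {
      warning("k_in outside the incoming aberration support; using nearest support pixel")
      idx <- which(phi_in$support)
      kc <- grid_coords(grid, "k")
      d2 <- (kc$x[idx] - kin[1])^2 + (kc$y[idx] - kin[2])^2
      phi_in$phase[idx[which.min(d2)]]
    }
    f * exp(-1i * val)
  })
}

#' Estimate incoming aberration by time-reversal symmetry
#'
#' `phi_in(k) = phi_out(-k)`; useful when the incoming pupil is sparsely
#' probed, e.g. for wavefront-shaping focusing.
#'
#' @param phi_out An outgoing [aberration_function()].
#' @return An incoming [aberration_function()].
#' @export
time_reversal_incoming <- function(phi_out) {
  grid <- phi_out$grid
  ci <- grid_center_index(grid)
  ix <- 2 * ci[1] - seq_len(grid$nx); iy <- 2 * ci[2] - seq_len(grid$ny)
  okx <- ix >= 1 & ix <= grid$nx; oky <- iy >= 1 & iy <= grid$ny
  phase <- matrix(0, grid$nx, grid$ny)
  support <- matrix(FALSE, grid$nx, grid$ny)
  phase[okx, oky] <- phi_out$phase[ix[okx], iy[oky]]
  support[okx, oky] <- phi_out$support[ix[okx], iy[oky]]
  aberration_function(phase, support, grid, "incoming",
                      gauge = c(phi_out$gauge, list(time_reversed = TRUE)))
}

#' Detect incoming and outgoing aberrations from a tilt-group stack
#'
#' Full single-pass pipeline: build one aberration matrix per tilt
#' direction, threshold (and optionally mask off-diagonal entries),
#' factorize each into phase-difference fields, and integrate the two
#' outgoing difference fields into the outgoing pupil phase. The incoming
#' phase is integrated over the scattered incidence points and fitted with
#' a smooth polynomial surface on the pupil.
#'
#' @param stack A [field_stack()] whose groups carry (at least) two tilt
#'   slots with linearly independent directions.
#' @param tilt_slots Indices of the two tilt slots to use.
#' @param threshold Passed to [threshold_reweight()].
#' @param mask_na If non-`NULL`, passed to [mask_offdiagonal()].
#' @param solver `"power"` ([factorize_projection_power()]) or `"svd"`
#'   ([factorize_svd()]).
#' @param remove_tilt Remove the mean outgoing gradient (tip/tilt) before
#'   integration; off by default since tip/tilt encodes true image shift
#'   and defocus.
#' @param use_cross_pair Additionally build the aberration matrix of the
#'   cross pair (second tilt slot against the first), contributing a third
#'   difference direction to the least-squares integration.
#' @param phi_in_degree Polynomial degree of the incoming-surface fit.
#' @return List with `phi_out`, `phi_in` ([aberration_function()]s),
#'   `phi_in_samples` (per-group incoming phases at `k_in`),
#'   `objective` (factorization objective values), and the
#'   intermediate `dphi` fields.
#' @export
detect_aberration <- function(stack, tilt_slots = c(2L, 3L),
                              threshold = list(q = 0.6), mask_na = NULL,
                              solver = c("power", "svd"),
                              remove_tilt = FALSE, use_cross_pair = FALSE,
                              phi_in_degree = 4L) {
  solver <- match.arg(solver)
  one_fac <- function(s, ref = 1L) {
    A <- build_aberration_matrix(stack, s, ref_slot = ref)
    A <- threshold_reweight(A, threshold)
    if (!is.null(mask_na)) A <- mask_offdiagonal(A, mask_na)
    if (solver == "power") factorize_projection_power(A) else factorize_svd(A)
  }
  facs <- lapply(tilt_slots, one_fac)
  if (use_cross_pair && length(tilt_slots) == 2) {
    facs[[3]] <- one_fac(tilt_slots[2], ref = tilt_slots[1])
  }
  phi_out <- integrate_gradients(facs[[1]]$dphi_out, facs[[2]]$dphi_out,
                                 extra = lapply(facs[-(1:2)], `[[`, "dphi_out"),
                                 side = "outgoing", remove_tilt = remove_tilt)
  # cover the pupil rim where tilted samples leave the detection pupil
  phi_out <- extend_aberration(phi_out, pupil_mask(stack$grid))
  dk1 <- facs[[1]]$dphi_in$direction; dk2 <- facs[[2]]$dphi_in$direction
  det_m <- dk1[1] * dk2[2] - dk1[2] * dk2[1]
  d1 <- facs[[1]]$dphi_in$values; d2 <- facs[[2]]$dphi_in$values
  g_in <- rbind(( dk2[2] * d1 - dk1[2] * d2) / det_m,
                (-dk2[1] * d1 + dk1[1] * d2) / det_m)
  kin <- facs[[1]]$dphi_in$index
  samples <- integrate_scattered_gradients(kin, g_in)
  phi_in <- fit_pupil_surface(kin, samples, stack$grid, degree = phi_in_degree)
  obj <- lapply(facs, function(f) attr(f, "objective"))
  list(phi_out = phi_out, phi_in = phi_in, phi_in_samples = samples,
       objective = obj,
       dphi_out = lapply(facs, `[[`, "dphi_out"),
       dphi_in = lapply(facs, `[[`, "dphi_in"))
}

# Integrate per-point 2D gradients over scattered k_in points by least
# squares on a nearest-neighbour graph; value pinned at the point nearest
# the pupil centre.
integrate_scattered_gradients <- function(pts, grads, n_neighbors = 4L) {
  n <- ncol(pts)
  if (n == 1) return(0)
  d2 <- as.matrix(stats::dist(t(pts)))^2
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[seq(2, min(n_neighbors + 1L, n))]
    from <- c(from, rep(i, length(nb))); to <- c(to, nb)
  }
  keep <- !duplicated(paste(pmin(from, to), pmax(from, to)))
  from <- from[keep]; to <- to[keep]
  ne <- length(from)
  dkx <- pts[1, to] - pts[1, from]; dky <- pts[2, to] - pts[2, from]
  tv <- wrap_phase((grads[1, from] + grads[1, to]) / 2 * dkx +
                     (grads[2, from] + grads[2, to]) / 2 * dky)
  D <- Matrix::sparseMatrix(i = rep(seq_len(ne), 2L), j = c(to, from),
                            x = rep(c(1, -1), each = ne), dims = c(ne, n))
  L <- Matrix::crossprod(D)
  b <- Matrix::crossprod(D, tv)
  pin <- which.min(pts[1, ]^2 + pts[2, ]^2)
  L[pin, pin] <- L[pin, pin] + 1
  phi <- as.numeric(Matrix::solve(L, b))
  phi - phi[pin]
}

# Fit phase samples at scattered k points with a 2D polynomial surface and
# evaluate it on the pupil grid (incoming side).
fit_pupil_surface <- function(pts, values, grid, degree = 4L) {
  k_na <- 2 * pi * grid$na_det / grid$wavelength
  x <- pts[1, ] / k_na; y <- pts[2, ] / k_na
  basis <- function(x, y) {
    cols <- list()
    for (p in 0:degree) for (q in 0:(degree - p)) {
      cols[[length(cols) + 1L]] <- x^p * y^q
    }
    do.call(cbind, cols)
  }
  B <- basis(x, y)
  coef <- tryCatch(qr.coef(qr(B), values), error = function(e) NULL)
  support <- pupil_mask(grid)
  phase <- matrix(0, grid$nx, grid$ny)
  if (!is.null(coef)) {
    coef[is.na(coef)] <- 0
    kc <- grid_coords(grid, "k")
    Bg <- basis(kc$x[support] / k_na, kc$y[support] / k_na)
    phase[support] <- Bg %*% coef
  }
  ci <- grid_center_index(grid)
  phase <- phase - phase[ci[1], ci[2]]
  aberration_function(phase, support, grid, "incoming",
                      gauge = list(piston = "pupil-center",
                                   fit = sprintf("polynomial degree %d", degree)))
}

#' Iterative windowed detection and correction
#'
#' For deep-tissue scenarios where the aberration PSF is larger than the
#' isoplanatic patch, a single windowed detection sees a mixture of
#' patches. The loop (i) detects aberrations from windowed fields,
#' (ii) corrects the *original* fields with the accumulated pupil phase,
#' and (iii) reapplies the window, repeating until the per-iteration pupil
#' update RMS falls below `rms_tol` or `n_iter` is reached.
#'
#' @param stack The original (uncorrected) [field_stack()].
#' @param window A [window_spec()] applied to the outgoing fields.
#' @param n_iter Maximum number of outer iterations.
#' @param detector_config List of arguments passed to
#'   [detect_aberration()].
#' @param rms_tol Early-stop threshold on the pupil-phase update RMS (rad).
#' @return List with `stack` (corrected fields), `phi_out` (accumulated
#'   outgoing aberration), and `record` (per-iteration update RMS and
#'   final factorization objectives; the objective history of each outer
#'   iteration is non-decreasing by construction of the power iteration).
#' @export
iterative_windowed_correction <- function(stack, window = NULL, n_iter = 3L,
                                          detector_config = list(),
                                          rms_tol = 0.01) {
  stopifnot(n_iter >= 1)
  grid <- stack$grid
  support <- pupil_mask(grid)
  acc <- aberration_function(matrix(0, grid$nx, grid$ny), support, grid,
                             "outgoing")
  corrected <- stack
  rms_hist <- numeric(0); obj_hist <- list()
  for (it in seq_len(n_iter)) {
    ws <- if (is.null(window)) corrected else window_outgoing(corrected, window)
    det <- tryCatch(do.call(detect_aberration, c(list(ws), detector_config)),
                    error = function(e) e)
    if (inherits(det, "error")) {
      warning("detection failed at iteration ", it, ": ", conditionMessage(det),
              "; returning last good state")
      attr(corrected, "failed_iteration") <- it
      break
    }
    upd <- det$phi_out
    rms <- phase_rms(upd)
    rms_hist <- c(rms_hist, rms)
    obj_hist[[it]] <- vapply(det$objective,
                             function(o) if (is.null(o)) NA_real_ else max(o),
                             numeric(1))
    acc$phase <- wrap_phase(acc$phase + upd$phase)
    corrected <- correct_outgoing(stack, acc)
    if (rms < rms_tol) break
  }
  record <- list(n_outer_iterations = length(rms_hist),
                 update_rms = rms_hist, objective = obj_hist)
  list(stack = corrected, phi_out = acc, record = record)
}
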