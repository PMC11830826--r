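#' Build the aberration matrix from a tilt slot
#'
#' For every group the selected tilted incidence is paired with the central
#' one: the tilted field's spectrum is sampled on the lattice shifted by the
#' group tilt `Delta k` (sub-pixel exact) and multiplied by the conjugate of
#' the untilted spectrum,
#' \deqn{A(k_{out}; k_{in}) = \tilde E(k_{out}+\Delta k;\, k_{in}+\Delta k)\,
#'       \tilde E^*(k_{out};\, k_{in}).}
#' Because the target-volume contribution cancels within the angular
#' memory-effect range, the argument of `A` separates into outgoing (row)
#' and incoming (column) aberration phase differences, while its modulus
#' approximates the squared target spectrum `|T|^2`.
#'
#' @param stack A [field_stack()]; every group must contain `tilt_slot` and
#'   share the same tilt offset (tolerance 1e-6 rad/um).
#' @param tilt_slot Slot index (> 1) of the tilted incidence to use.
#' @param ref_slot Reference slot (1 by default, the central incidence);
#'   any other slot yields the cross pair with tilt
#'   `dk(tilt_slot) - dk(ref_slot)`.
#' @return An `aberration_matrix`: complex matrix `entries` of dim
#'   (pupil pixels x groups), with `delta_k`, the pupil pixel index
#'   (`pupil_index`, linear indices into the grid), per-group `kin`
#'   (2 x groups), the `grid`, and `weight_state = "raw"`.
#' @export
build_aberration_matrix <- function(stack, tilt_slot, ref_slot = 1L) {
  if (tilt_slot == ref_slot) stop("tilt_slot must differ from ref_slot")
  grid <- stack$grid
  slot_dk <- function(g, s) {
    if (s == 1L) c(0, 0) else {
      if (s - 1L > length(g$tilt_offsets)) {
        stop(sprintf("a group is missing tilt slot %d", s))
      }
      g$tilt_offsets[[s - 1L]]
    }
  }
  dks <- lapply(stack$groups, function(g) {
    slot_dk(g, tilt_slot) - slot_dk(g, ref_slot)
  })
  dk0 <- dks[[1]]
  for (d in dks) {
    if (max(abs(d - dk0)) > 1e-6) {
      stop("heterogeneous Delta k across groups; one aberration matrix needs a common tilt")
    }
  }
  support <- pupil_mask(grid)
  pupil_index <- which(support)
  entries <- matrix(0i, length(pupil_index), n_groups(stack))
  for (g in seq_len(n_groups(stack))) {
    ec <- fft2_centered(stack_field(stack, g, ref_slot), grid)
    et <- shift_sample_kspace(stack_field(stack, g, tilt_slot), dk0, grid)
    entries[, g] <- (et * Conj(ec))[pupil_index]
  }
  kin <- vapply(seq_len(n_groups(stack)), function(g) {
    stack_kin(stack, g, ref_slot)
  }, numeric(2))
  structure(list(entries = entries, delta_k = dk0, pupil_index = pupil_index,
                 kin = kin, grid = grid, weight_state = "raw"),
            class = "aberration_matrix")
}

#' @export
print.aberration_matrix <- function(x, ...) {
  cat(sprintf("<aberration_matrix> %d pupil px x %d groups, |dk| = %.4g rad/um, %s\n",
              nrow(x$entries), ncol(x$entries), sqrt(sum(x$delta_k^2)),
              x$weight_state))
  invisible(x)
}

# k_out coordinates (2 x npupil) of the matrix rows.
aberration_matrix_kout <- function(A) {
  kc <- grid_coords(A$grid, "k")
  rbind(kc$x[A$pupil_index], kc$y[A$pupil_index])
}

#' Threshold and reweight an aberration matrix
#'
#' The phase signal-to-noise of each entry scales with its modulus, but in
#' transmission the narrow angular spectrum concentrates the modulus on the
#' diagonal, which spoils a modulus-weighted factorization. Entries above a
#' noise threshold are therefore replaced by their unit-modulus phase
#' `exp(i arg A)` and the rest zeroed.
#'
#' @param A An `aberration_matrix` in `"raw"` state.
#' @param threshold Either a numeric modulus threshold (strictly-greater
#'   survival, the default `0` keeps every nonzero entry), a string
#'   `"q:<frac>"`, or `list(q = frac)`: keep the top `ceiling((1-frac) * n)`
#'   entries by modulus among the nonzero entries.
#' @return The matrix with `weight_state = "thresholded"`; every surviving
#'   entry has unit modulus. Warns if more than 99 percent of entries were
#'   removed (ill-posed factorization).
#' @export
threshold_reweight <- function(A, threshold = list(q = 0.6)) {
  stopifnot(inherits(A, "aberration_matrix"))
  m <- Mod(A$entries)
  nz <- m > 0
  if (is.character(threshold)) {
    if (!grepl("^q:", threshold)) stop("string threshold must look like 'q:0.6'")
    threshold <- list(q = as.numeric(sub("^q:", "", threshold)))
  }
  if (is.list(threshold)) {
    q <- threshold$q
    if (is.null(q) || q < 0 || q >= 1) stop("quantile spec needs 0 <= q < 1")
    n_nz <- sum(nz)
    keep_n <- ceiling((1 - q) * n_nz)
    thr_val <- sort(m[nz], decreasing = TRUE)[keep_n]
    keep <- nz & m >= thr_val
  } else {
    stopifnot_scalar(threshold, "threshold", positive = FALSE)
    keep <- nz & m > threshold
  }
  out <- matrix(0i, nrow(A$entries), ncol(A$entries))
  out[keep] <- exp(1i * Arg(A$entries[keep]))
  if (sum(keep) < 0.01 * length(out)) {
    warning("threshold removed > 99% of entries; factorization may be ill-posed")
  }
  A$entries <- out
  A$weight_state <- "thresholded"
  A
}

#' Mask far-off-diagonal entries of an aberration matrix
#'
#' Zeroes entries with `|k_out - k_in| > 2 pi radius_na / lambda`. Used to
#' suppress illumination-side artefacts (e.g. spurious diffraction peaks)
#' that survive thresholding when the angular spectrum is narrow; radii of
#' 0.3-0.4 NA are typical for weakly scattering samples.
#'
#' @param A An `aberration_matrix`.
#' @param radius_na Masking radius in NA units, in `(0, na_det]`; a radius
#'   at or above the detection NA is a no-op.
#' @return The masked matrix (weight state unchanged).
#' @export
mask_offdiagonal <- function(A, radius_na) {
  stopifnot_scalar(radius_na, "radius_na")
  kout <- aberration_matrix_kout(A)
  r <- 2 * pi * radius_na / A$grid$wavelength
  for (g in seq_len(ncol(A$entries))) {
    d2 <- (kout[1, ] - A$kin[1, g])^2 + (kout[2, ] - A$kin[2, g])^2
    A$entries[d2 > r^2, g] <- 0i
  }
  A
}

# Shared gauge: rotate the factor pair so the outgoing differences have
# zero circular mean over the valid pupil pixels; the compensating
# constant moves to the incoming side. Averaging over the (many) pupil
# pixels rather than the (few) illumination groups keeps the split stable
# when the phase differences are spread over a large fraction of 2 pi; a
# residual constant only displaces the reconstructed image laterally.
fix_factor_gauge <- function(dphi_out, dphi_in, valid_out = NULL) {
  z <- exp(1i * dphi_out)
  if (!is.null(valid_out)) z <- z[valid_out]
  c0 <- Arg(mean(z))
  list(out = wrap_phase(dphi_out - c0), inn = wrap_phase(dphi_in + c0))
}

phase_difference_field <- function(values, direction, side,
                                   index = NULL, grid = NULL, valid = NULL) {
  structure(list(values = wrap_phase(values), direction = direction,
                 side = side, index = index, grid = grid,
                 valid = valid %||% rep(TRUE, length(values))),
            class = "phase_difference_field")
}

#' Factorize an aberration matrix by SVD
#'
#' Rank-1 factorization `A ~ exp(i dphi_out) exp(i dphi_in)^T` from the
#' first left/right singular vectors. The global-phase ambiguity is fixed
#' by zeroing the circular mean of the incoming differences.
#'
#' @param A A thresholded `aberration_matrix`.
#' @return List with `dphi_out` (a `phase_difference_field` over pupil
#'   pixels) and `dphi_in` (over groups).
#' @export
factorize_svd <- function(A) {
  stopifnot(inherits(A, "aberration_matrix"))
  if (all(A$entries == 0)) stop("cannot factorize an all-zero aberration matrix")
  sv <- svd(A$entries, nu = 1, nv = 1)
  dout <- Arg(sv$u[, 1])
  dinn <- -Arg(sv$v[, 1])
  valid <- rowSums(Mod(A$entries) > 0) > 0
  gg <- fix_factor_gauge(dout, dinn, valid)
  list(
    dphi_out = phase_difference_field(gg$out, A$delta_k, "outgoing",
                                      index = A$pupil_index, grid = A$grid,
                                      valid = valid),
    dphi_in = phase_difference_field(gg$inn, A$delta_k, "incoming",
                                     index = A$kin, grid = A$grid))
}

#' Factorize an aberration matrix by projection power iteration
#'
#' Solves the unimodular quadratic program `max v' M v` with `|v| = 1`
#' entrywise and `M = A' A` by the projection power iteration
#' `v <- exp(i arg(M v))` starting from the all-ones vector; the maximizer
#' is `v = exp(-i dphi_in)`. The outgoing differences follow in closed form
#' as `dphi_out(k_out) = arg( sum_kin A(k_out; k_in) exp(-i dphi_in) )`.
#' The quadratic objective is asserted to be non-decreasing across
#' iterations.
#'
#' @param A A thresholded `aberration_matrix`.
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the max wrapped phase update (rad).
#' @return As [factorize_svd()], plus attributes `iterations`, `objective`
#'   (trace of `Re(v' M v)`), and `converged` (FALSE triggers a warning and
#'   the best iterate is returned).
#' @export
factorize_projection_power <- function(A, max_iter = 100L, tol = 1e-10) {
  stopifnot(inherits(A, "aberration_matrix"))
  if (all(A$entries == 0)) stop("cannot factorize an all-zero aberration matrix")
  M <- crossprod(Conj(A$entries), A$entries)  # A^dagger A, groups x groups
  v <- rep(1 + 0i, ncol(M))
  obj <- Re(Conj(v) %*% M %*% v)[1]
  trace <- obj
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    vn <- exp(1i * Arg(M %*% v)[, 1])
    obj_n <- Re(Conj(vn) %*% M %*% vn)[1]
    if (obj_n < obj - 1e-9 * abs(obj)) {
      stop("projection power iteration decreased its objective; matrix may be corrupt")
    }
    step <- max(abs(wrap_phase(Arg(vn) - Arg(v))))
    v <- vn; obj <- obj_n
    trace <- c(trace, obj)
    if (step < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("projection power iteration did not converge in %d iterations", max_iter))
  }
  dinn <- wrap_phase(-Arg(v))            # v = exp(-i dphi_in)
  dout <- Arg(A$entries %*% v)[, 1]
  valid <- rowSums(Mod(A$entries) > 0) > 0
  gg <- fix_factor_gauge(dout, dinn, valid)
  res <- list(
    dphi_out = phase_difference_field(gg$out, A$delta_k, "outgoing",
                                      index = A$pupil_index, grid = A$grid,
                                      valid = valid),
    dphi_in = phase_difference_field(gg$inn, A$delta_k, "incoming",
                                     index = A$kin, grid = A$grid))
  attr(res, "iterations") <- iters
  attr(res, "objective") <- trace
  attr(res, "converged") <- converged
  res
}
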