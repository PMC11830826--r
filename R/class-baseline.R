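# CLASS / distortion-matrix baseline: the prior matrix-based AO method the
# aberration matrix is compared against. It assumes a thin (2D) target
# S(r), so that E~(k_out; k_in) = P~out(k_out) S~(k_out - k_in) P~in(k_in),
# and maximises the intensity of the synthesized 2D image by alternating
# unimodular phase optimisation over the two pupils.

# Integer lattice offsets of the group centres. The K-indexing of the
# CLASS model presupposes a common lattice, so off-grid k_in are rounded;
# the maximum rounding error (pixels) is reported once per call chain.
class_pixel_offsets <- function(stack, tol = 1e-3) {
  grid <- stack$grid
  off <- vapply(stack$groups, function(g) {
    c(g$k_center[1] / grid$dkx, g$k_center[2] / grid$dky)
  }, numeric(2))
  err <- max(abs(off - round(off)))
  out <- round(off)
  if (err > tol) {
    attr(out, "rounding_error_px") <- err
  }
  out
}

# Shift a centred k-space image by integer pixels with zero fill:
# out[i] = m[i + p] (samples the spectrum at k + p*dk).
roll_zero <- function(m, p) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(0i, n1, n2)
  sx <- seq_len(n1) + p[1]; sy <- seq_len(n2) + p[2]
  okx <- sx >= 1 & sx <= n1; oky <- sy >= 1 & sy <= n2
  out[okx, oky] <- m[sx[okx], sy[oky]]
  out
}

# Resolve a per-group incoming phase vector from various representations.
resolve_phi_in <- function(phi_in, stack) {
  if (is.null(phi_in)) return(rep(0, n_groups(stack)))
  if (inherits(phi_in, "aberration_function")) {
    return(vapply(seq_len(n_groups(stack)), function(g) {
      interp_phase(phi_in$phase, stack$grid, stack$groups[[g]]$k_center)
    }, numeric(1)))
  }
  stopifnot(length(phi_in) == n_groups(stack))
  as.numeric(phi_in)
}

resolve_phi_out <- function(phi_out, grid) {
  if (is.null(phi_out)) return(matrix(0, grid$nx, grid$ny))
  if (inherits(phi_out, "aberration_function")) phi_out$phase else phi_out
}

# Central-slot pupil spectra of a stack.
class_spectra <- function(stack) {
  grid <- stack$grid
  support <- pupil_mask(grid)
  lapply(seq_len(n_groups(stack)), function(g) {
    fft2_centered(stack_field(stack, g, 1L), grid) * support
  })
}

#' CLASS objective function
#'
#' \deqn{L(\phi_{out}, \phi_{in}) = \sum_K \Big|
#'   \sum_{k_{out}-k_{in}=K} e^{-i\phi_{out}} \tilde E\, e^{-i\phi_{in}}
#' \Big|^2,}
#' the intensity of the coherently synthesized 2D image (by Parseval). For
#' a thin target at the true phases it attains the incoherent upper bound
#' `sum_K (sum |E~|)^2`.
#'
#' @param stack A [field_stack()] with on-lattice group centres.
#' @param phi_out Outgoing pupil phase ([aberration_function()], matrix,
#'   or `NULL` for zero).
#' @param phi_in Incoming phases: numeric per group,
#'   [aberration_function()], or `NULL`.
#' @return The scalar objective.
#' @export
class_objective <- function(stack, phi_out = NULL, phi_in = NULL) {
  st <- class_synthesized_spectrum(stack, phi_out, phi_in)
  sum(Mod(st)^2)
}

# Coherent K-indexed sum of the corrected spectra.
class_synthesized_spectrum <- function(stack, phi_out, phi_in) {
  grid <- stack$grid
  pix <- class_pixel_offsets(stack)
  pout <- resolve_phi_out(phi_out, grid)
  pin <- resolve_phi_in(phi_in, stack)
  spectra <- class_spectra(stack)
  acc <- matrix(0i, grid$nx, grid$ny)
  for (g in seq_along(spectra)) {
    cg <- exp(-1i * pout) * spectra[[g]] * exp(-1i * pin[g])
    acc <- acc + roll_zero(cg, pix[, g])
  }
  acc
}

#' Synthesize the 2D image of the CLASS model
#'
#' Inverse transform of the K-indexed coherent sum; with the true pupil
#' phases on a thin noise-free target this reproduces the target
#' transmittance up to a global factor.
#'
#' @inheritParams class_objective
#' @return Complex image `S(r)` with attribute `"peak_intensity"`.
#' @export
synthesize_2d_image <- function(stack, phi_out = NULL, phi_in = NULL) {
  st <- class_synthesized_spectrum(stack, phi_out, phi_in)
  img <- ifft2_centered(st, stack$grid)
  attr(img, "peak_intensity") <- max(Mod(img)^2)
  img
}

#' Alternating CLASS/distortion-matrix optimisation
#'
#' Iteratively maximises [class_objective()] by alternating unimodular
#' quadratic programs over the incoming and outgoing phases, each solved
#' with one projection power step per half-iteration (which cannot
#' decrease the objective since both quadratic forms are positive
#' semidefinite). Initialisation `phi = 0`; the run aborts with a
#' diagnostic if the trace ever decreases beyond numerical tolerance.
#'
#' @param stack A [field_stack()] with on-lattice group centres (only the
#'   central slot of each group is used).
#' @param n_iter Iteration cap (50 by default; the problem is non-convex
#'   and the attained maximum depends on these pinned defaults).
#' @param tol Relative objective change for convergence.
#' @return List with `phi_out` ([aberration_function()]), `phi_in`
#'   (per-group phases), and `objective_trace`.
#' @export
class_iterate <- function(stack, n_iter = 50L, tol = 1e-9) {
  grid <- stack$grid
  pix <- class_pixel_offsets(stack)
  support <- pupil_mask(grid)
  spectra <- class_spectra(stack)
  ng <- length(spectra)
  v_out <- matrix(1 + 0i, grid$nx, grid$ny)  # e^{i phi_out}
  v_in <- rep(1 + 0i, ng)                    # e^{-i phi_in}
  objective <- function() {
    acc <- matrix(0i, grid$nx, grid$ny)
    for (g in seq_len(ng)) {
      acc <- acc + roll_zero(Conj(v_out) * spectra[[g]] * v_in[g], pix[, g])
    }
    sum(Mod(acc)^2)
  }
  trace <- objective()
  check <- function(L_new) {
    L_old <- trace[length(trace)]
    if (L_new < L_old * (1 - 1e-9) - 1e-12) {
      stop(sprintf("CLASS objective decreased (%.6g -> %.6g); aborting", L_old, L_new))
    }
    trace <<- c(trace, L_new)
  }
  for (it in seq_len(n_iter)) {
    # --- incoming half-step: one projection power step on M = D^H D
    D <- vapply(seq_len(ng), function(g) {
      as.vector(roll_zero(Conj(v_out) * spectra[[g]], pix[, g]))
    }, complex(grid$nx * grid$ny))
    M <- crossprod(Conj(D), D)
    v_in <- exp(1i * Arg(M %*% v_in)[, 1])
    check(objective())
    # --- outgoing half-step: matrix-free projection step on M = D D^H,
    # v = e^{i phi_out}; Mv(k) = sum_g c_g(k) S(k - k_in_g) with
    # c_g = v_in[g] * spectra_g and S(K) = sum_g aligned(conj(c_g) v)
    S <- matrix(0i, grid$nx, grid$ny)
    for (g in seq_len(ng)) {
      S <- S + roll_zero(Conj(v_in[g] * spectra[[g]]) * v_out, pix[, g])
    }
    Mv <- matrix(0i, grid$nx, grid$ny)
    for (g in seq_len(ng)) {
      Mv <- Mv + v_in[g] * spectra[[g]] * roll_zero(S, -pix[, g])
    }
    upd <- Mod(Mv) > 0 & support
    v_out[upd] <- exp(1i * Arg(Mv[upd]))
    check(objective())
    n <- length(trace)
    if (n >= 3 && abs(trace[n] - trace[n - 2]) <= tol * abs(trace[n - 2])) break
  }
  phase <- Arg(v_out)
  ci <- grid_center_index(grid)
  phase <- wrap_phase(phase - phase[ci[1], ci[2]])
  list(phi_out = aberration_function(phase, support, grid, "outgoing"),
       phi_in = wrap_phase(-Arg(v_in)),
       objective_trace = trace)
}
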