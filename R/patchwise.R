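#' Window specification for isoplanatic-patch selection
#'
#' @param kind `"gaussian"` or `"array"` (a supplied real-space window).
#' @param sigma Gaussian width in sample-plane um.
#' @param center Length-2 patch centre (um), inside the field of view.
#' @param values Window matrix for `kind = "array"`.
#' @return A `window_spec` object.
#' @export
window_spec <- function(kind = c("gaussian", "array"), sigma = NULL,
                        center = c(0, 0), values = NULL) {
  kind <- match.arg(kind)
  if (kind == "gaussian") stopifnot_scalar(sigma, "sigma")
  structure(list(kind = kind, sigma = sigma, center = center,
                 values = values), class = "window_spec")
}

window_values <- function(window, grid) {
  if (window$kind == "array") return(window$values)
  rc <- grid_coords(grid, "r")
  fov <- c(grid$nx, grid$ny) * grid$dx / 2
  if (any(abs(window$center) > fov)) stop("window centre outside the field of view")
  exp(-((rc$x - window$center[1])^2 + (rc$y - window$center[2])^2) /
        (2 * window$sigma^2))
}

#' Window the outgoing waves
#'
#' Pointwise real-space multiplication of every field by the window.
#'
#' @param stack A [field_stack()].
#' @param window A [window_spec()].
#' @return The windowed [field_stack()].
#' @export
window_outgoing <- function(stack, window) {
  w <- window_values(window, stack$grid)
  stack_map(stack, function(f, g, s) f * w)
}

#' Incoming-window synthesis coefficients
#'
#' Windowing the sparsely sampled incident plane waves is implemented by
#' additionally scanning each incidence over a 3 x 3 k-grid and coherently
#' superposing the outgoing fields. The coefficient moduli follow the
#' 4/2/1 rule for a Gaussian-like window: 4 at the centre offset, 2 on the
#' edge offsets (`|k| = dk_scan`), 1 on the corners
#' (`|k| = sqrt(2) dk_scan`); the phases are determined at application
#' time by matching the windowed waves at the patch centre.
#'
#' @param dk_scan Scan interval (rad/um); conventionally twice the tilt
#'   `Delta k` used for the aberration matrix.
#' @return An `incoming_window_synthesis`: list of `offsets` (nine
#'   length-2 vectors) and `moduli`.
#' @export
incoming_window_synthesis <- function(dk_scan) {
  stopifnot_scalar(dk_scan, "dk_scan")
  offs <- list(); mods <- numeric(0)
  for (ix in -1:1) for (iy in -1:1) {
    offs[[length(offs) + 1L]] <- c(ix, iy) * dk_scan
    mods <- c(mods, c(`0` = 4, `1` = 2, `2` = 1)[[as.character(ix^2 + iy^2)]])
  }
  structure(list(offsets = offs, moduli = mods, dk_scan = dk_scan),
            class = "incoming_window_synthesis")
}

#' Scanned acquisition: one field stack per scan offset
#'
#' @param stacks List of [field_stack()]s, one per offset of `synthesis`,
#'   each measured with every incidence shifted by that offset.
#' @param synthesis An [incoming_window_synthesis()].
#' @return A `scanned_stack` object.
#' @export
scanned_stack <- function(stacks, synthesis) {
  if (length(stacks) != length(synthesis$offsets)) {
    missing <- setdiff(seq_along(synthesis$offsets), seq_along(stacks))
    stop("missing scan offsets: ", paste(missing, collapse = ", "))
  }
  structure(list(stacks = stacks, synthesis = synthesis),
            class = "scanned_stack")
}

#' Apply an incoming window by scanned-beam synthesis
#'
#' For every (group, slot) the nine scan-offset fields are superposed with
#' the synthesis moduli and with phases chosen so that all contributions
#' share the phase of the central term at the patch centre `r_c`; the
#' effective illumination becomes a beam localised around `r_c`.
#'
#' @param scanned A [scanned_stack()].
#' @param r_c Length-2 patch centre (um).
#' @return A [field_stack()] of windowed fields (same group structure).
#' @export
window_incoming <- function(scanned, r_c) {
  syn <- scanned$synthesis
  base <- scanned$stacks[[which(vapply(syn$offsets, function(o) all(o == 0), TRUE))]]
  grid <- base$grid
  ci <- c(round(r_c[1] / grid$dx) + floor(grid$nx / 2) + 1,
          round(r_c[2] / grid$dx) + floor(grid$ny / 2) + 1)
  if (any(ci < 1) || ci[1] > grid$nx || ci[2] > grid$ny) {
    stop("r_c outside the field of view")
  }
  wsum <- sum(syn$moduli)
  stack_map(base, function(f0, g, s) {
    ref <- Arg(f0[ci[1], ci[2]])
    acc <- matrix(0i, grid$nx, grid$ny)
    for (o in seq_along(syn$offsets)) {
      fo <- scanned$stacks[[o]]$data[[g]][[s]]
      ph <- ref - Arg(fo[ci[1], ci[2]])
      acc <- acc + (syn$moduli[o] / wsum) * exp(1i * ph) * fo
    }
    acc
  })
}

#' Per-patch aberration detection
#'
#' Tiles the field of view with patch centres, windows the outgoing (and,
#' when scanned data are given, incoming) waves around each centre, and
#' runs the aberration-matrix pipeline per patch.
#'
#' @param stack A [field_stack()] or [scanned_stack()].
#' @param centers List of length-2 patch centres (um); e.g. a 5 x 5 grid.
#' @param window_sigma Outgoing Gaussian window width (um).
#' @param detector_config Arguments for [detect_aberration()].
#' @return List with `phi_out` (per-patch [aberration_function()]s, `NULL`
#'   where detection failed), `relative` (phase maps minus the central
#'   patch), `centers`, and `failures`.
#' @export
detect_per_patch <- function(stack, centers, window_sigma,
                             detector_config = list()) {
  results <- vector("list", length(centers))
  failures <- character(0)
  for (i in seq_along(centers)) {
    res <- tryCatch({
      base <- if (inherits(stack, "scanned_stack")) {
        window_incoming(stack, centers[[i]])
      } else stack
      ws <- window_outgoing(base, window_spec("gaussian", sigma = window_sigma,
                                              center = centers[[i]]))
      do.call(detect_aberration, c(list(ws), detector_config))$phi_out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("patch %d: %s", i, conditionMessage(res)))
      results[[i]] <- NULL
    } else {
      results[[i]] <- res
    }
  }
  mid <- ceiling(length(centers) / 2)
  central <- results[[mid]]
  relative <- lapply(results, function(p) {
    if (is.null(p) || is.null(central)) return(NULL)
    wrap_phase(p$phase - central$phase) * (p$support & central$support)
  })
  list(phi_out = results, relative = relative, centers = centers,
       failures = failures)
}

#' Stitch per-patch tomograms
#'
#' Per-patch constant RI offsets (from the global phase ambiguity of the
#' detected PSFs) are solved by least squares over pairwise overlap means
#' (gauge: central patch = 0), patches are blended with a cosine taper
#' across patch midlines, and the slowly varying background is removed
#' with a Gaussian high-pass.
#'
#' @param patch_tomograms List of [tomogram()]s on a shared voxel lattice.
#' @param centers List of patch centres (um) matching the tomograms.
#' @param overlap_margin Taper half-width (um) across midlines.
#' @param background_sigma High-pass Gaussian width in spatial frequency
#'   (um^-1); the default 1/4 removes the stitched low-frequency
#'   background. `0` disables the filter.
#' @return A [tomogram()]; recovered per-patch offsets in attribute
#'   `"patch_offsets"`.
#' @export
stitch_tomograms <- function(patch_tomograms, centers, overlap_margin = 2,
                             background_sigma = 0.25) {
  np <- length(patch_tomograms)
  stopifnot(np == length(centers), np >= 1)
  t0 <- patch_tomograms[[1]]
  grid <- t0$grid
  rc <- grid_coords(grid, "r")
  cx <- vapply(centers, `[`, 1, i = 1); cy <- vapply(centers, `[`, 2, i = 2)
  axis_half <- function(v) {
    u <- sort(unique(v))
    if (length(u) < 2) Inf else min(diff(u)) / 2
  }
  half_x <- axis_half(cx); half_y <- axis_half(cy)
  taper <- function(d, half) {
    # 1 inside the half-spacing box, cosine rolloff over the margin; an
    # axis along which the layout does not vary is fully covered
    if (!is.finite(half)) return(rep(1, length(d)))
    t <- rep(1, length(d))
    m <- pmax(overlap_margin, 1e-9)
    edge <- d - (half - m)
    roll <- edge > 0
    t[roll] <- 0.5 * (1 + cos(pi * pmin(edge[roll] / (2 * m), 1)))
    t
  }
  weights <- lapply(seq_len(np), function(p) {
    if (np == 1) return(matrix(1, grid$nx, grid$ny))
    wx <- taper(abs(rc$x - cx[p]), half_x)
    wy <- taper(abs(rc$y - cy[p]), half_y)
    matrix(wx * wy, grid$nx, grid$ny)
  })
  wsum <- Reduce(`+`, weights)
  if (any(wsum <= 0)) stop("patch layout leaves uncovered pixels; reduce spacing or enlarge margin")
  # pairwise offsets over overlaps
  offsets <- rep(0, np)
  if (np > 1) {
    rows <- list(); rhs <- numeric(0)
    for (i in seq_len(np - 1)) for (j in seq(i + 1, np)) {
      ov <- weights[[i]] > 0.05 & weights[[j]] > 0.05
      if (!any(ov)) next
      d_ij <- mean(vapply(seq_len(dim(t0$values)[3]), function(iz) {
        mean(patch_tomograms[[i]]$values[, , iz][ov] -
               patch_tomograms[[j]]$values[, , iz][ov])
      }, numeric(1)))
      row <- rep(0, np); row[i] <- 1; row[j] <- -1
      rows[[length(rows) + 1L]] <- row; rhs <- c(rhs, d_ij)
    }
    if (length(rows) < np - 1) stop("patch adjacency graph is disconnected")
    Amat <- do.call(rbind, rows)
    mid <- ceiling(np / 2)
    pinrow <- rep(0, np); pinrow[mid] <- 1
    Amat <- rbind(Amat, pinrow); rhs <- c(rhs, 0)
    offsets <- as.numeric(qr.coef(qr(Amat), rhs))
    offsets[is.na(offsets)] <- 0
  }
  nz <- dim(t0$values)[3]
  vals <- array(0, dim(t0$values))
  for (p in seq_len(np)) {
    w <- weights[[p]] / wsum
    for (iz in seq_len(nz)) {
      vals[, , iz] <- vals[, , iz] +
        w * (patch_tomograms[[p]]$values[, , iz] - offsets[p])
    }
  }
  if (background_sigma > 0) {
    kc <- grid_coords(grid, "k")
    u2 <- (kc$x^2 + kc$y^2) / (2 * pi)^2
    hp <- 1 - exp(-u2 / (2 * background_sigma^2))
    bg <- grid$n_medium
    for (iz in seq_len(nz)) {
      sl <- vals[, , iz]
      filt <- Re(ifft2_centered(fft2_centered(sl - bg, grid) * hp, grid))
      vals[, , iz] <- bg + filt
    }
  }
  out <- tomogram(vals, grid, t0$dz, t0$z0)
  attr(out, "patch_offsets") <- offsets
  out
}

#' Isoplanatic-patch correlation length of an anisotropic slab
#'
#' Small-angle estimate of the lateral correlation length of a wave
#' transmitted through a forward-scattering slab,
#' \deqn{l_c \approx \frac{\lambda}{\sqrt 2}\sqrt{l_t / L},}
#' from the directional-decorrelation identity
#' `<cos theta> = exp(-L / l_t)`. Valid in the anisotropic regime
#' `L << l_t` (warns otherwise).
#'
#' @param l_t Transport mean free path (um).
#' @param L Slab thickness (um).
#' @param wavelength_in_medium Wavelength in the medium (um).
#' @return Correlation length (um).
#' @export
correlation_length <- function(l_t, L, wavelength_in_medium) {
  stopifnot_scalar(l_t, "l_t"); stopifnot_scalar(L, "L")
  stopifnot_scalar(wavelength_in_medium, "wavelength_in_medium")
  if (L > l_t / 2) {
    warning("L is not small compared to l_t; the small-angle estimate is unreliable")
  }
  wavelength_in_medium / sqrt(2) * sqrt(l_t / L)
}
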