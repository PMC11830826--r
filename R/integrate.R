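#' Pupil aberration function
#'
#' Phase `phi(k)` of the pupil transfer function of an aberrating medium on
#' the detection-pupil support, zero-filled outside. The piston gauge is
#' fixed at the pupil-centre pixel; tip/tilt is retained by default because
#' it encodes a true image shift / refocus.
#'
#' @param phase Numeric matrix of dim `c(nx, ny)` (radians).
#' @param support Logical pupil mask of the same dim.
#' @param grid A [grid2d()].
#' @param side `"outgoing"` or `"incoming"`.
#' @param gauge List recording the gauge choices.
#' @return An `aberration_function` object.
#' @export
aberration_function <- function(phase, support, grid,
                                side = c("outgoing", "incoming"),
                                gauge = list(piston = "pupil-center")) {
  side <- match.arg(side)
  phase[!support] <- 0
  if (!all(is.finite(phase[support]))) stop("phase must be finite on support")
  structure(list(phase = phase, support = support, grid = grid, side = side,
                 gauge = gauge),
            class = "aberration_function")
}

#' @export
print.aberration_function <- function(x, ...) {
  cat(sprintf("<aberration_function> %s, RMS %.3f rad on %d pupil px\n",
              x$side, stats::sd(x$phase[x$support]), sum(x$support)))
  invisible(x)
}

#' Extend an aberration function to a larger support
#'
#' Fills pixels of `support` that lie outside the function's own support
#' by iterative dilation (each new pixel takes the mean of its already
#' filled 4-neighbours). Used to cover the thin pupil rim where tilt
#' pairs leave the detection pupil and no phase difference is measurable.
#'
#' @param phi An [aberration_function()].
#' @param support Logical target support (e.g. the full detection pupil).
#' @return An [aberration_function()] on the union support.
#' @export
extend_aberration <- function(phi, support) {
  grid <- phi$grid
  filled <- phi$support
  phase <- phi$phase
  target <- support | filled
  max_pass <- max(grid$nx, grid$ny)
  for (pass in seq_len(max_pass)) {
    todo <- target & !filled
    if (!any(todo)) break
    idx <- which(todo)
    ij <- arrayInd(idx, c(grid$nx, grid$ny))
    val <- numeric(length(idx)); cnt <- integer(length(idx))
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      i2 <- ij[, 1] + d[1]; j2 <- ij[, 2] + d[2]
      ok <- i2 >= 1 & i2 <= grid$nx & j2 >= 1 & j2 <= grid$ny
      nb <- cbind(i2[ok], j2[ok])
      has <- filled[nb]
      val[ok][has] <- val[ok][has] + phase[nb[has, , drop = FALSE]]
      cnt[ok][has] <- cnt[ok][has] + 1L
    }
    newly <- cnt > 0L
    if (!any(newly)) break
    phase[idx[newly]] <- val[newly] / cnt[newly]
    filled[idx[newly]] <- TRUE
  }
  aberration_function(phase, filled & target, grid, phi$side,
                      gauge = c(phi$gauge, list(extended = TRUE)))
}

#' Phase RMS of an aberration function over its support
#' @param phi An [aberration_function()].
#' @return RMS in radians (piston removed).
#' @export
phase_rms <- function(phi) {
  v <- phi$phase[phi$support]
  sqrt(mean((v - mean(v))^2))
}

#' Integrate two directional phase-difference fields into a pupil phase
#'
#' Recovers the pupil phase from differences
#' `d_m(k) = phi(k + dk_m) - phi(k)` measured along two linearly
#' independent tilt directions, by one masked least squares over the
#' support:
#' \deqn{\min_\phi \sum_m \sum_k |\phi(k + \Delta k_m) - \phi(k) - d_m(k)|^2}
#' with free (Neumann-like) boundaries. `phi(k + dk_m)` is expressed
#' exactly when the tilt is lattice-aligned and by bilinear interpolation
#' for sub-pixel tilts; the wrapped differences enter directly (no
#' unwrapping). The normal equations are solved exactly with a sparse
#' Cholesky factorization; the piston is pinned to zero at the
#' pupil-centre pixel.
#'
#' @param dphi_1,dphi_2 `phase_difference_field`s over the same pupil pixel
#'   set (as produced by the factorization functions), with linearly
#'   independent directions.
#' @param support Logical pupil mask; defaults to the pixels where both
#'   fields carry valid (surviving) data.
#' @param side Side label for the result.
#' @param remove_tilt If TRUE, the mean gradient (tip/tilt, from the
#'   per-pixel 2x2 direction system) is subtracted before integration and
#'   recorded in the gauge.
#' @param extra Optional list of further `phase_difference_field`s (e.g.
#'   the cross pair of the two tilt slots) joining the least squares.
#' @return An [aberration_function()].
#' @export
integrate_gradients <- function(dphi_1, dphi_2, support = NULL,
                                side = "outgoing", remove_tilt = FALSE,
                                extra = list()) {
  grid <- dphi_1$grid
  stopifnot(identical(dphi_1$index, dphi_2$index))
  dk1 <- dphi_1$direction; dk2 <- dphi_2$direction
  det_m <- dk1[1] * dk2[2] - dk1[2] * dk2[1]
  if (abs(det_m) < 1e-12 * sqrt(sum(dk1^2)) * sqrt(sum(dk2^2)) ||
      abs(det_m) == 0) {
    stop("tilt directions are (nearly) collinear; cannot form a 2D gradient")
  }
  if (is.null(support)) {
    valid <- dphi_1$valid & dphi_2$valid
    for (e in extra) valid <- valid & e$valid
    support <- matrix(FALSE, grid$nx, grid$ny)
    support[dphi_1$index[valid]] <- TRUE
  }
  idx <- which(support)
  pos <- match(idx, dphi_1$index)
  if (anyNA(pos)) stop("support contains pixels without phase-difference data")
  d1 <- dphi_1$values[pos]; d2 <- dphi_2$values[pos]
  gauge <- list(piston = "pupil-center", tilt_removed = remove_tilt)
  mean_grad <- c(0, 0)
  if (remove_tilt) {
    gx <- ( dk2[2] * d1 - dk1[2] * d2) / det_m
    gy <- (-dk2[1] * d1 + dk1[1] * d2) / det_m
    mean_grad <- c(mean(gx), mean(gy))
    gauge$mean_gradient <- mean_grad
    d1 <- d1 - sum(mean_grad * dk1)
    d2 <- d2 - sum(mean_grad * dk2)
  }
  constraints <- list(list(d = wrap_phase(d1), dk = dk1),
                      list(d = wrap_phase(d2), dk = dk2))
  for (e in extra) {
    stopifnot(identical(e$index, dphi_1$index))
    constraints[[length(constraints) + 1L]] <-
      list(d = wrap_phase(e$values[pos] - sum(mean_grad * e$direction)),
           dk = e$direction)
  }
  phi <- solve_difference_integration(constraints, support, grid)
  aberration_function(phi, support, grid, side, gauge)
}

# Masked least squares on wrapped difference constraints
# phi(k + dk) - phi(k) = d, with bilinear interpolation of the shifted
# sample (exact for lattice-aligned dk). Restricted to the connected
# component containing the pupil centre; piston pinned there.
solve_difference_integration <- function(constraints, support, grid) {
  idx <- which(support)
  n <- length(idx)
  id_of <- matrix(NA_integer_, grid$nx, grid$ny)
  id_of[idx] <- seq_len(n)
  ij <- arrayInd(idx, c(grid$nx, grid$ny))
  tri_i <- list(); tri_j <- list(); tri_x <- list(); rhs <- list()
  n_row <- 0L
  for (con in constraints) {
    fx <- con$dk[1] / grid$dkx; fy <- con$dk[2] / grid$dky
    ix <- floor(fx); iy <- floor(fy)
    wx <- fx - ix; wy <- fy - iy
    corners <- list(c(0L, 0L, (1 - wx) * (1 - wy)),
                    c(1L, 0L, wx * (1 - wy)),
                    c(0L, 1L, (1 - wx) * wy),
                    c(1L, 1L, wx * wy))
    corners <- Filter(function(cc) cc[3] > 1e-12, corners)
    corner_ids <- lapply(corners, function(cc) {
      i2 <- ij[, 1] + ix + cc[1]; j2 <- ij[, 2] + iy + cc[2]
      ok <- i2 >= 1 & i2 <= grid$nx & j2 >= 1 & j2 <= grid$ny
      out <- rep(NA_integer_, n)
      out[ok] <- id_of[cbind(i2[ok], j2[ok])]
      out
    })
    usable <- Reduce(`&`, lapply(corner_ids, function(v) !is.na(v)))
    if (!any(usable)) next
    rows <- n_row + seq_len(sum(usable))
    for (c_i in seq_along(corners)) {
      tri_i[[length(tri_i) + 1L]] <- rows
      tri_j[[length(tri_j) + 1L]] <- corner_ids[[c_i]][usable]
      tri_x[[length(tri_x) + 1L]] <- rep(corners[[c_i]][3], length(rows))
    }
    tri_i[[length(tri_i) + 1L]] <- rows
    tri_j[[length(tri_j) + 1L]] <- which(usable)
    tri_x[[length(tri_x) + 1L]] <- rep(-1, length(rows))
    rhs[[length(rhs) + 1L]] <- con$d[usable]
    n_row <- n_row + length(rows)
  }
  if (n_row == 0) stop("support has no usable difference constraints")
  D <- Matrix::sparseMatrix(i = unlist(tri_i), j = unlist(tri_j),
                            x = unlist(tri_x), dims = c(n_row, n))
  tv <- unlist(rhs)
  # connectivity: pixels linked by any constraint row
  links_from <- integer(0); links_to <- integer(0)
  Dt <- methods::as(D, "TsparseMatrix")
  row_first <- tapply(Dt@j + 1L, Dt@i, function(v) v, simplify = FALSE)
  for (v in row_first) {
    if (length(v) > 1) {
      links_from <- c(links_from, rep(v[1], length(v) - 1))
      links_to <- c(links_to, v[-1])
    }
  }
  comp <- connected_components(n, links_from, links_to)
  ci <- grid_center_index(grid)
  dist2 <- (ij[, 1] - ci[1])^2 + (ij[, 2] - ci[2])^2
  main <- comp[order(dist2)[1]]
  keep_n <- comp == main
  remap <- cumsum(keep_n)
  col_in <- keep_n[Dt@j + 1L]
  row_keep <- !(seq_len(n_row) %in% unique((Dt@i + 1L)[!col_in]))
  rmap <- cumsum(row_keep)
  tkeep <- row_keep[Dt@i + 1L] & col_in
  D2 <- Matrix::sparseMatrix(i = rmap[(Dt@i + 1L)[tkeep]],
                             j = remap[(Dt@j + 1L)[tkeep]],
                             x = Dt@x[tkeep],
                             dims = c(sum(row_keep), sum(keep_n)))
  L <- Matrix::crossprod(D2)
  b <- Matrix::crossprod(D2, tv[row_keep])
  pin <- remap[order(dist2)[1]]
  L[pin, pin] <- L[pin, pin] + 1
  phi_v <- as.numeric(Matrix::solve(L, b))
  phi_v <- phi_v - phi_v[pin]
  phi <- matrix(0, grid$nx, grid$ny)
  phi[idx[keep_n]] <- phi_v
  phi
}

# Least-squares integration of per-pixel gradients (rad per rad/um) on a
# mask; edge targets are wrapped. Returns a full-grid phase matrix.
solve_masked_integration <- function(gx, gy, support, grid) {
  idx <- which(support)
  n <- length(idx)
  id_of <- matrix(NA_integer_, grid$nx, grid$ny)
  id_of[idx] <- seq_len(n)
  ij <- arrayInd(idx, c(grid$nx, grid$ny))
  gx_full <- gy_full <- matrix(0, grid$nx, grid$ny)
  gx_full[idx] <- gx; gy_full[idx] <- gy

  edges <- function(di, dj, dk, gfull) {
    i2 <- ij[, 1] + di; j2 <- ij[, 2] + dj
    ok <- i2 >= 1 & i2 <= grid$nx & j2 >= 1 & j2 <= grid$ny
    to <- id_of[cbind(i2[ok], j2[ok])]
    from <- seq_len(n)[ok]
    keep <- !is.na(to)
    from <- from[keep]; to <- to[keep]
    t_edge <- wrap_phase(dk * (gfull[idx[from]] + gfull[idx[to]]) / 2)
    list(from = from, to = to, t = t_edge)
  }
  ex <- edges(1L, 0L, grid$dkx, gx_full)
  ey <- edges(0L, 1L, grid$dky, gy_full)
  from <- c(ex$from, ey$from); to <- c(ex$to, ey$to); tv <- c(ex$t, ey$t)
  if (length(from) == 0) stop("support has no interior edges to integrate over")
  # keep only the connected component containing the pupil centre (stray
  # isolated pixels would make the normal equations singular)
  comp <- connected_components(n, from, to)
  ci <- grid_center_index(grid)
  dist2 <- (ij[, 1] - ci[1])^2 + (ij[, 2] - ci[2])^2
  main <- comp[order(dist2)[1]]
  keep_n <- comp == main
  keep_e <- keep_n[from] & keep_n[to]
  remap <- cumsum(keep_n)
  from <- remap[from[keep_e]]; to <- remap[to[keep_e]]; tv <- tv[keep_e]
  n2 <- sum(keep_n)
  ne <- length(from)
  D <- Matrix::sparseMatrix(i = rep(seq_len(ne), 2L), j = c(to, from),
                            x = rep(c(1, -1), each = ne), dims = c(ne, n2))
  L <- Matrix::crossprod(D)
  b <- Matrix::crossprod(D, tv)
  pin <- remap[order(dist2)[1]]
  L[pin, pin] <- L[pin, pin] + 1
  phi_v <- as.numeric(Matrix::solve(L, b))
  phi_v <- phi_v - phi_v[pin]
  phi <- matrix(0, grid$nx, grid$ny)
  phi[idx[keep_n]] <- phi_v
  phi
}

# Union-find connected components over an edge list.
connected_components <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(from)) {
    a <- find(from[e]); b <- find(to[e])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

#' Zernike-style pupil phase
#'
#' Analytic low-order aberration phases on the pupil, as polynomials in the
#' normalised pupil radius `rho = |k| / k_NA` and azimuth. Used both as
#' simulation ground truth and in tests.
#'
#' @param grid A [grid2d()].
#' @param coefficients Named numeric vector; recognised names: `piston`,
#'   `tip`, `tilt`, `defocus`, `astig_oblique`, `astig_vertical`, `coma_x`,
#'   `coma_y`, `trefoil_x`, `trefoil_y`, `spherical`. Values are the peak
#'   coefficients (radians) of the standard (unnormalised) polynomials.
#' @param na Pupil NA defining `rho = 1`; defaults to the detection NA.
#' @return Numeric phase matrix (radians), zero outside the pupil.
#' @export
zernike_phase <- function(grid, coefficients, na = grid$na_det) {
  kc <- grid_coords(grid, "k")
  k_na <- 2 * pi * na / grid$wavelength
  rho <- sqrt(kc$x^2 + kc$y^2) / k_na
  th <- atan2(kc$y, kc$x)
  terms <- list(
    piston        = function() 1,
    tip           = function() rho * cos(th),
    tilt          = function() rho * sin(th),
    defocus       = function() 2 * rho^2 - 1,
    astig_oblique = function() rho^2 * sin(2 * th),
    astig_vertical= function() rho^2 * cos(2 * th),
    coma_x        = function() (3 * rho^3 - 2 * rho) * cos(th),
    coma_y        = function() (3 * rho^3 - 2 * rho) * sin(th),
    trefoil_x     = function() rho^3 * cos(3 * th),
    trefoil_y     = function() rho^3 * sin(3 * th),
    spherical     = function() 6 * rho^4 - 6 * rho^2 + 1)
  phase <- matrix(0, grid$nx, grid$ny)
  for (nm in names(coefficients)) {
    if (!nm %in% names(terms)) stop("unknown aberration term: ", nm)
    phase <- phase + coefficients[[nm]] * terms[[nm]]()
  }
  phase[rho > 1] <- 0
  phase
}

#' Point spread function of an aberration function
#'
#' Inverse Fourier transform of `exp(i phi(k))` on the pupil support,
#' normalised to unit discrete L2 norm. With `phi = 0` this is the
#' diffraction-limited (Airy-like) amplitude PSF of the pupil.
#'
#' @param phi An [aberration_function()].
#' @return Complex PSF matrix of grid shape, `sum(|PSF|^2) = 1`.
#' @export
retrieve_psf <- function(phi) {
  if (!any(phi$support)) stop("empty pupil support")
  p <- ifft2_centered(exp(1i * phi$phase) * phi$support, phi$grid)
  p / sqrt(sum(Mod(p)^2))
}
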