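#' Tilt group of illumination wave vectors
#'
#' One measurement group: a central incident wave vector plus one or more
#' slightly tilted incidences. Tilts must stay inside the illumination NA.
#'
#' @param k_center Length-2 numeric, central incident wave vector (rad/um).
#' @param tilt_offsets List of length-2 numerics, tilts `Delta k` (rad/um)
#'   for the extra slots of the group (slot 1 is always the centre).
#' @param grid Optional [grid2d()]; if given, offsets are validated against
#'   the illumination NA.
#' @return A `tilt_group` object.
#' @export
tilt_group <- function(k_center, tilt_offsets = list(), grid = NULL) {
  stopifnot(length(k_center) == 2)
  tilt_offsets <- lapply(tilt_offsets, function(d) {
    stopifnot(length(d) == 2); as.numeric(d)
  })
  if (!is.null(grid)) {
    k_ill <- 2 * pi * grid$na_ill / grid$wavelength
    for (d in tilt_offsets) {
      if (sqrt(sum((k_center + d)^2)) > k_ill + 1e-9) {
        stop("tilted incidence falls outside the illumination NA")
      }
    }
  }
  structure(list(k_center = as.numeric(k_center), tilt_offsets = tilt_offsets),
            class = "tilt_group")
}

#' Angle-resolved complex field stack
#'
#' Container for the fields `E_out(r; k_in)` measured under plane-wave
#' illumination, organised in tilt groups: slot 1 of each group holds the
#' central incidence and slot `s > 1` the incidence tilted by
#' `tilt_offsets[[s - 1]]`.
#'
#' @param grid A [grid2d()].
#' @param groups List of [tilt_group()]s.
#' @param data List (over groups) of lists (over slots) of complex matrices,
#'   all of dim `c(nx, ny)`; finite values required.
#' @param times Optional numeric vector of per-frame acquisition times (s),
#'   one per (group, slot) in group-major order.
#' @return A `field_stack` object.
#' @export
field_stack <- function(grid, groups, data, times = NULL) {
  stopifnot(inherits(grid, "grid2d"), length(groups) == length(data))
  for (g in seq_along(groups)) {
    nslot <- 1L + length(groups[[g]]$tilt_offsets)
    if (length(data[[g]]) != nslot) {
      stop(sprintf("group %d: expected %d slots, got %d", g, nslot,
                   length(data[[g]])))
    }
    for (f in data[[g]]) {
      if (nrow(f) != grid$nx || ncol(f) != grid$ny) {
        stop("all fields must share the grid shape")
      }
      if (!all(is.finite(Re(f))) || !all(is.finite(Im(f)))) {
        stop("fields must be finite (no NaN/Inf)")
      }
    }
  }
  structure(list(grid = grid, groups = groups, data = data, times = times),
            class = "field_stack")
}

#' @export
print.field_stack <- function(x, ...) {
  cat(sprintf("<field_stack> %d groups, %s slots, grid %d x %d\n",
              length(x$groups),
              paste(unique(vapply(x$data, length, 1L)), collapse = "/"),
              x$grid$nx, x$grid$ny))
  invisible(x)
}

n_groups <- function(stack) length(stack$groups)

# Field of (group, slot); slot 1 = central incidence.
stack_field <- function(stack, group, slot = 1L) stack$data[[group]][[slot]]

# Incident wave vector of (group, slot).
stack_kin <- function(stack, group, slot = 1L) {
  g <- stack$groups[[group]]
  if (slot == 1L) g$k_center else g$k_center + g$tilt_offsets[[slot - 1L]]
}

# Apply `fun(field, group, slot)` to every field, returning a new stack.
stack_map <- function(stack, fun) {
  data <- lapply(seq_along(stack$data), function(g) {
    lapply(seq_along(stack$data[[g]]), function(s) {
      fun(stack$data[[g]][[s]], g, s)
    })
  })
  field_stack(stack$grid, stack$groups, data, stack$times)
}

#' Write a field stack to a TIFF + YAML container
#'
#' On-disk interchange format: a multi-page 32-bit float TIFF holding the
#' real parts, a second one holding the imaginary parts (pages in
#' group-major, slot-minor order), and a YAML sidecar with the grid
#' attributes and the `k_in` table. Values are scaled to `[0, 1]` per file
#' with the affine parameters recorded in the sidecar.
#'
#' @param stack A [field_stack()].
#' @param path Base path; writes `<path>_real.tif`, `<path>_imag.tif`,
#'   `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_field_stack <- function(stack, path) {
  pages_re <- list(); pages_im <- list(); kin <- list(); slot_of <- list()
  i <- 0L
  for (g in seq_along(stack$groups)) {
    for (s in seq_along(stack$data[[g]])) {
      i <- i + 1L
      f <- stack$data[[g]][[s]]
      pages_re[[i]] <- Re(f); pages_im[[i]] <- Im(f)
      kin[[i]] <- as.numeric(stack_kin(stack, g, s))
      slot_of[[i]] <- c(g, s)
    }
  }
  scale_write <- function(pages, file) {
    lo <- min(vapply(pages, min, 1)); hi <- max(vapply(pages, max, 1))
    span <- if (hi > lo) hi - lo else 1
    tiff::writeTIFF(lapply(pages, function(p) (p - lo) / span), file,
                    bits.per.sample = 32L)
    c(lo = lo, span = span)
  }
  sre <- scale_write(pages_re, paste0(path, "_real.tif"))
  sim <- scale_write(pages_im, paste0(path, "_imag.tif"))
  g <- stack$grid
  meta <- list(
    grid = list(nx = g$nx, ny = g$ny, dx = g$dx, wavelength = g$wavelength,
                n_medium = g$n_medium, na_det = g$na_det, na_ill = g$na_ill),
    fourier_convention = "forward exp(-i k r), k = 0 at centre pixel",
    scale = list(real = as.list(sre), imag = as.list(sim)),
    k_in = lapply(kin, as.list),
    frame_index = lapply(slot_of, as.list),
    groups = lapply(stack$groups, function(gr) {
      list(k_center = as.list(gr$k_center),
           tilt_offsets = lapply(gr$tilt_offsets, as.list))
    }),
    times = stack$times)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a field stack written by [write_field_stack()]
#'
#' @param path Base path used at write time.
#' @return A [field_stack()].
#' @export
read_field_stack <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  gm <- meta$grid
  grid <- grid2d(gm$nx, gm$ny, dx = gm$dx, wavelength = gm$wavelength,
                 n_medium = gm$n_medium, na_det = gm$na_det,
                 na_ill = gm$na_ill)
  unscale <- function(pages, sc) {
    lapply(pages, function(p) p * sc$span + sc$lo)
  }
  pr <- unscale(tiff::readTIFF(paste0(path, "_real.tif"), all = TRUE),
                meta$scale$real)
  pi_ <- unscale(tiff::readTIFF(paste0(path, "_imag.tif"), all = TRUE),
                 meta$scale$imag)
  groups <- lapply(meta$groups, function(gr) {
    tilt_group(unlist(gr$k_center),
               lapply(gr$tilt_offsets, unlist))
  })
  data <- lapply(groups, function(gr) vector("list", 1L + length(gr$tilt_offsets)))
  for (i in seq_along(meta$frame_index)) {
    fi <- unlist(meta$frame_index[[i]])
    data[[fi[1]]][[fi[2]]] <- matrix(complex(real = pr[[i]], imaginary = pi_[[i]]),
                                     grid$nx, grid$ny)
  }
  field_stack(grid, groups, data, times = meta$times %||% NULL)
}
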