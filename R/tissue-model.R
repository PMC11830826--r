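# Multi-layer tissue model: the scattering medium is collapsed onto
# parallel phase screens (default spacing 10 um) whose statistics are
# calibrated to prescribed scattering (l_s) and transport (l_t) mean free
# paths; weak random reflection screens provide the backscatter for
# time-gated reflection imaging under a single-backscatter assumption.

#' Tissue model configuration
#'
#' Defaults follow typical soft-tissue optical parameters: scattering mean
#' free path `l_s = 53` um, transport mean free path `l_t = 1100` um
#' (anisotropy via the ratio), layers every 10 um.
#'
#' @param l_s Scattering mean free path (um).
#' @param l_t Transport mean free path (um).
#' @param n_layers Number of layers.
#' @param dz_layer Layer spacing (um).
#' @param reflectance_total Target total stack reflectance (must stay
#'   below 0.04, the regime where multiple inter-layer reflections are
#'   negligible).
#' @param deflection_rms RMS (rad) of the smooth surface-deflection phase
#'   added to the first layer (0 disables it); emulates refractive-index
#'   mismatch at the tissue boundary.
#' @param deflection_corr_um Correlation length (um) of the deflection.
#' @param deflection_rough_rms,deflection_rough_corr_um Optional second,
#'   finer-grained deflection component (boundary roughness); real
#'   interface deflections are multi-scale, and the fine component is what
#'   destroys the uncorrected focus rather than merely displacing it.
#' @return A `tissue_config` list.
#' @export
tissue_config <- function(l_s = 53, l_t = 1100, n_layers = 10L,
                          dz_layer = 10, reflectance_total = 0.02,
                          deflection_rms = 0, deflection_corr_um = 3,
                          deflection_rough_rms = 0,
                          deflection_rough_corr_um = 2) {
  stopifnot_scalar(l_s, "l_s"); stopifnot_scalar(l_t, "l_t")
  if (reflectance_total >= 0.04) {
    stop("total reflectance must stay < 0.04 for the single-backscatter model")
  }
  structure(list(l_s = l_s, l_t = l_t, n_layers = as.integer(n_layers),
                 dz_layer = dz_layer, reflectance_total = reflectance_total,
                 deflection_rms = deflection_rms,
                 deflection_corr_um = deflection_corr_um,
                 deflection_rough_rms = deflection_rough_rms,
                 deflection_rough_corr_um = deflection_rough_corr_um),
            class = "tissue_config")
}

#' Generate calibrated layer screens
#'
#' Each layer carries a Gaussian random phase with Gaussian
#' autocorrelation. The calibration is closed-form in the small-angle
#' regime: the per-layer phase variance follows from the ballistic
#' attenuation of the coherent component,
#' `<exp(i phi)> = exp(-sigma^2/2)`, giving `sigma^2 = dz / l_s`; the
#' autocorrelation length (ACF `sigma^2 exp(-r^2 / (2 l^2))`) follows from
#' the per-layer growth of the mean square scattering angle,
#' `sigma^2 * 2 / (l^2 k_m^2) = 2 dz / l_t`, giving
#' `l = sqrt(l_t / l_s) / k_m`. Transmission amplitudes are
#' `sqrt(1 - rho^2)` with per-layer reflectance `rho^2` splitting the
#' configured total; reflection screens have uniform modulus `rho` and
#' smooth random phase. A smooth deflection phase of the configured RMS is
#' added to the first layer.
#'
#' @param config A [tissue_config()].
#' @param grid A [grid2d()].
#' @param seed Integer seed; screens are reproducible from
#'   `(config, grid, seed)`.
#' @return A `layer_stack`: lists `t` (complex transmission screens,
#'   `|t| <= 1`), `r` (reflection screens), `dz_layer`, the deflection
#'   phase, and the calibration record.
#' @export
generate_layer_screens <- function(config, grid, seed = 1L) {
  sigma2 <- config$dz_layer / config$l_s
  corr_um <- sqrt(config$l_t / config$l_s) / grid$k_medium
  corr_px <- corr_um / grid$dx
  transparent <- sigma2 < 1e-6  # effectively scatter-free stack
  if (!transparent) {
    if (corr_px < 1) {
      stop(sprintf(
        "screen correlation length %.3g um is below one pixel (dx = %g); feasible l_t/l_s > %.3g on this grid",
        corr_um, grid$dx, (grid$dx * grid$k_medium)^2))
    }
    if (corr_px > grid$nx / 8) {
      stop("screen correlation length exceeds nx/8 pixels; enlarge the grid or reduce l_t/l_s")
    }
  }
  rho2 <- config$reflectance_total / config$n_layers
  phases <- with_seed(seed, {
    lapply(seq_len(config$n_layers), function(j) {
      if (transparent) return(matrix(0, grid$nx, grid$ny))
      w <- matrix(stats::rnorm(grid$nx * grid$ny), grid$nx, grid$ny)
      w <- gaussian_blur(w, corr_px / sqrt(2))
      (w - mean(w)) / stats::sd(w) * sqrt(sigma2)
    })
  })
  rphases <- with_seed(seed + 1000L, {
    lapply(seq_len(config$n_layers), function(j) {
      w <- matrix(stats::rnorm(grid$nx * grid$ny), grid$nx, grid$ny)
      w <- gaussian_blur(w, max(corr_px, 1.5) / sqrt(2))
      (w - mean(w)) / stats::sd(w) * pi / 2
    })
  })
  deflection <- matrix(0, grid$nx, grid$ny)
  smooth_component <- function(rms, corr_um, sd_offset) {
    d <- with_seed(seed + sd_offset, {
      w <- matrix(stats::rnorm(grid$nx * grid$ny), grid$nx, grid$ny)
      gaussian_blur(w, corr_um / grid$dx / sqrt(2))
    })
    (d - mean(d)) / stats::sd(d) * rms
  }
  if (config$deflection_rms > 0) {
    deflection <- smooth_component(config$deflection_rms,
                                   config$deflection_corr_um, 2000L)
  }
  if ((config$deflection_rough_rms %||% 0) > 0) {
    deflection <- deflection +
      smooth_component(config$deflection_rough_rms,
                       config$deflection_rough_corr_um, 3000L)
  }
  phases[[1]] <- phases[[1]] + deflection
  amp <- sqrt(1 - rho2)
  structure(list(
    t = lapply(phases, function(p) amp * exp(1i * p)),
    r = lapply(rphases, function(p) sqrt(rho2) * exp(1i * p)),
    phases = phases, deflection = deflection,
    dz_layer = config$dz_layer, config = config, grid = grid, seed = seed),
    class = "layer_stack")
}

# Per-wavelength screen: the phase scales with the wavenumber ratio.
layer_screen_at <- function(layers, j, wavelength) {
  if (wavelength == layers$grid$wavelength) return(layers$t[[j]])
  scale <- layers$grid$wavelength / wavelength
  Mod(layers$t[[j]]) * exp(1i * Arg(layers$t[[j]]) * scale)
}

#' Beam propagation through a layer stack
#'
#' Split-step sequence: the field incident on each layer is multiplied by
#' the layer's transmission screen and propagated to the next layer by the
#' angular-spectrum method. Layer `j` sits at depth `(j - 1) * dz_layer`
#' (layer 1 at the surface). The `"backward"` direction runs the stack in
#' reverse with the conjugate-direction propagator. Multiple inter-layer
#' reflections are outside this model by construction.
#'
#' @param field Complex input field (at the surface for `"forward"`, at
#'   the deepest layer for `"backward"`).
#' @param layers A [generate_layer_screens()] stack.
#' @param direction `"forward"` (+z) or `"backward"` (-z).
#' @param grid A [grid2d()].
#' @param wavelength Vacuum wavelength (defaults to the grid's).
#' @return List: `incident` (field arriving at each layer, before its
#'   screen), `exit` (field after the last layer plus one spacing of
#'   propagation), and `power` (input, exit, clipped evanescent power).
#' @export
bpm_propagate <- function(field, layers, direction = c("forward", "backward"),
                          grid = layers$grid,
                          wavelength = grid$wavelength) {
  direction <- match.arg(direction)
  kz <- propagator_kz(grid, wavelength)
  valid <- !is.na(kz)
  kz0 <- ifelse(valid, kz, 0)
  step <- exp(1i * kz0 * layers$dz_layer) * valid
  order_j <- if (direction == "forward") seq_len(length(layers$t)) else
    rev(seq_len(length(layers$t)))
  p_in <- sum(Mod(field)^2)
  clipped <- 0
  incident <- vector("list", length(layers$t))
  e <- field
  npx <- grid$nx * grid$ny
  for (j in order_j) {
    incident[[j]] <- e
    e <- e * layer_screen_at(layers, j, wavelength)
    spec <- fft2_centered(e, grid)
    # DFT Parseval: sum_r |f|^2 = sum_k |spec|^2 / (N dx^4)
    clipped <- clipped + sum(Mod(spec[!valid])^2) / (npx * grid$dx^4)
    e <- ifft2_centered(spec * step, grid)
  }
  list(incident = incident, exit = e,
       power = c(input = p_in, exit = sum(Mod(e)^2), clipped = clipped))
}

#' Time-gating spectrum
#'
#' Gaussian spectral weights over `n_wavelengths` wavenumbers chosen so
#' the coherence-gated axial intensity response has the requested FWHM;
#' the sampling is dense enough that gate replicas fall outside the
#' simulated depth range.
#'
#' @param grid A [grid2d()] (provides centre wavelength and medium index).
#' @param n_wavelengths Number of spectral samples (40 by default).
#' @param fwhm_um Axial intensity FWHM of the gate (um).
#' @param span_sigma Half-range of the wavenumber sampling in units of the
#'   spectral standard deviation.
#' @return A `time_gate`: `wavelengths`, `weights` (sum 1), `k_medium`
#'   values, and the analytic `sigma_k`.
#' @export
time_gate_spec <- function(grid, n_wavelengths = 40L, fwhm_um = 11,
                           span_sigma = 2.5) {
  sigma_k <- sqrt(log(2)) / fwhm_um
  km0 <- grid$k_medium
  km <- km0 + seq(-span_sigma, span_sigma,
                  length.out = n_wavelengths) * sigma_k
  w <- exp(-(km - km0)^2 / (2 * sigma_k^2))
  structure(list(wavelengths = 2 * pi * grid$n_medium / km,
                 weights = w / sum(w), k_medium = km, sigma_k = sigma_k,
                 fwhm_um = fwhm_um),
            class = "time_gate")
}

#' Axial response of a time gate
#'
#' @param gate A [time_gate_spec()].
#' @param z Offsets from the reference depth (um).
#' @return Normalised gated intensity `|sum_l w_l exp(2 i k_l z)|^2`.
#' @export
gate_axial_response <- function(gate, z) {
  g <- vapply(z, function(zz) {
    Mod(sum(gate$weights * exp(2i * gate$k_medium * zz)))^2
  }, numeric(1))
  g / max(g)
}

#' Time-gated reflection imaging through the tissue model
#'
#' For every illumination and spectral sample the incident plane wave is
#' propagated forward by BPM; the target reflectivity at `target_depth`
#' and the layer reflection screens generate backward sources which are
#' propagated back to the surface (accumulated in one backward sweep,
#' single-backscatter). The surface field is numerically refocused to the
#' target depth, referenced against a mirror at the target depth, and
#' summed over wavelengths with the gate weights.
#'
#' @param groups Illumination [tilt_group()]s.
#' @param layers A [generate_layer_screens()] stack.
#' @param target Complex reflectivity matrix of the embedded target
#'   (e.g. a letter phantom), or `NULL` for layer backscatter only.
#' @param target_depth Depth of the target and of the focal/reference
#'   plane (um); conventionally `2 l_s`.
#' @param gate A [time_gate_spec()].
#' @param grid A [grid2d()].
#' @param illum_window Optional [window_spec()]: each incident plane wave
#'   is pre-windowed *at the target plane* (the windowed wave is formed at
#'   depth `target_depth` and numerically back-propagated to the surface
#'   for launch, which compensates the oblique walk-off), confining the
#'   illuminated target region to one isoplanatic patch. This mirrors how
#'   windowed incident waves are realised experimentally by scanned-beam
#'   synthesis, at a fraction of the cost.
#' @return A [field_stack()] of gated complex fields referenced to the
#'   target plane.
#' @export
time_gated_reflection <- function(groups, layers, target, target_depth,
                                  gate, grid = layers$grid,
                                  illum_window = NULL) {
  nl <- length(layers$t)
  z_last <- (nl - 1) * layers$dz_layer
  if (target_depth < z_last) stop("target must sit at or below the deepest layer")
  rc <- grid_coords(grid, "r")
  n_wl <- length(gate$wavelengths)
  # per-wavelength propagator tables
  prop <- lapply(seq_len(n_wl), function(l) {
    kz <- propagator_kz(grid, gate$wavelengths[l])
    valid <- !is.na(kz)
    kz0 <- ifelse(valid, kz, 0)
    list(step = exp(1i * kz0 * layers$dz_layer) * valid,
         tail = exp(1i * kz0 * (target_depth - z_last)) * valid,
         refocus = exp(-1i * kz0 * target_depth) * valid,
         focus = exp(1i * kz0 * target_depth) * valid,
         km = gate$k_medium[l])
  })
  w_in <- if (is.null(illum_window)) NULL else window_values(illum_window, grid)
  gated_one <- function(kin) {
    acc <- matrix(0i, grid$nx, grid$ny)
    carrier <- exp(1i * (kin[1] * rc$x + kin[2] * rc$y))
    for (l in seq_len(n_wl)) {
      pp <- prop[[l]]
      wl <- gate$wavelengths[l]
      # illumination referenced to the focal plane at the target depth
      # (path-matched coherence gate): the wave is defined at z = z_t and
      # numerically back-propagated to the surface for launch, per
      # wavelength; with a window this also compensates oblique walk-off
      e <- if (is.null(w_in)) {
        kz_in <- sqrt(pp$km^2 - sum(kin^2))
        carrier * exp(-1i * kz_in * target_depth)
      } else {
        ifft2_centered(fft2_centered(w_in * carrier, grid) * Conj(pp$focus),
                       grid)
      }
      incident <- vector("list", nl)
      for (j in seq_len(nl)) {
        incident[[j]] <- e
        e <- e * layer_screen_at(layers, j, wl)
        # one spacing between layers; the last hop reaches the target plane
        hop <- if (j < nl) pp$step else pp$tail
        e <- ifft2_centered(fft2_centered(e, grid) * hop, grid)
      }
      # backward sweep: target source, then the layer reflections on the
      # way up (single backscatter; backward waves re-traverse the screens)
      b <- if (is.null(target)) matrix(0i, grid$nx, grid$ny) else target * e
      b <- ifft2_centered(fft2_centered(b, grid) * pp$tail, grid)
      for (j in rev(seq_len(nl))) {
        b <- b * layer_screen_at(layers, j, wl) + layers$r[[j]] * incident[[j]]
        if (j > 1) b <- ifft2_centered(fft2_centered(b, grid) * pp$step, grid)
      }
      # collection also referenced to the focal plane at the target depth
      b <- ifft2_centered(fft2_centered(b, grid) * pp$refocus, grid)
      acc <- acc + gate$weights[l] * b
    }
    acc
  }
  data <- lapply(groups, function(gr) {
    slots <- c(list(c(0, 0)), gr$tilt_offsets)
    lapply(slots, function(d) gated_one(gr$k_center + d))
  })
  field_stack(grid, groups, data)
}

# Forward sweep of one field from the surface to the target plane.
forward_to_target <- function(field, layers, target_depth,
                              grid = layers$grid,
                              wavelength = grid$wavelength) {
  nl <- length(layers$t)
  z_last <- (nl - 1) * layers$dz_layer
  kz <- propagator_kz(grid, wavelength)
  valid <- !is.na(kz)
  kz0 <- ifelse(valid, kz, 0)
  step <- exp(1i * kz0 * layers$dz_layer) * valid
  tail <- exp(1i * kz0 * (target_depth - z_last)) * valid
  e <- field
  for (j in seq_len(nl)) {
    e <- e * layers$t[[j]]
    hop <- if (j < nl) step else tail
    e <- ifft2_centered(fft2_centered(e, grid) * hop, grid)
  }
  e
}

#' Wavefront-shaping focus through the tissue model
#'
#' Focuses a converging beam at `target_depth` through the layer stack,
#' optionally pre-corrected with an incoming pupil phase (e.g. from
#' time-reversal symmetry `phi_in(k) = phi_out(-k)` of the detected
#' outgoing aberration). The ideal reference focus phase-conjugates the
#' field of a guide star (point source) at the target propagated to the
#' surface, clipped to the illumination pupil. All input beams carry unit
#' power, so peak ratios are Strehl ratios.
#'
#' @param layers A [generate_layer_screens()] stack.
#' @param target_depth Focus depth (um).
#' @param phi_in Incoming [aberration_function()] or `NULL` (uncorrected).
#' @param grid A [grid2d()].
#' @return List with complex target-plane fields `focus` and `ideal`, and
#'   `strehl = strehl_ratio(focus, ideal)`.
#' @export
focusing_experiment <- function(layers, target_depth, phi_in = NULL,
                                grid = layers$grid) {
  kz <- propagator_kz(grid)
  valid <- !is.na(kz)
  kz0 <- ifelse(valid, kz, 0)
  ill <- pupil_mask(grid, grid$na_ill)
  norm_field <- function(f) f / sqrt(sum(Mod(f)^2))
  # test beam: diffraction-limited convergence to (0, 0, target_depth)
  spec <- ill * exp(-1i * kz0 * target_depth)
  if (!is.null(phi_in)) spec <- spec * exp(-1i * phi_in$phase)
  f0 <- norm_field(ifft2_centered(spec, grid))
  focus <- forward_to_target(f0, layers, target_depth, grid)
  # guide star: point source at the target, propagated up through the
  # stack, phase-conjugated, clipped to the illumination pupil
  src <- matrix(0i, grid$nx, grid$ny)
  ci <- grid_center_index(grid)
  src[ci[1], ci[2]] <- 1
  nl <- length(layers$t)
  z_last <- (nl - 1) * layers$dz_layer
  step <- exp(1i * kz0 * layers$dz_layer) * valid
  tail <- exp(1i * kz0 * (target_depth - z_last)) * valid
  b <- ifft2_centered(fft2_centered(src, grid) * tail, grid)
  for (j in rev(seq_len(nl))) {
    b <- b * layers$t[[j]]
    if (j > 1) b <- ifft2_centered(fft2_centered(b, grid) * step, grid)
  }
  spec_pc <- fft2_centered(Conj(b), grid) * ill
  ideal0 <- norm_field(ifft2_centered(spec_pc, grid))
  ideal <- forward_to_target(ideal0, layers, target_depth, grid)
  list(focus = focus, ideal = ideal, strehl = strehl_ratio(focus, ideal))
}

#' Fit the scattering lengths realised by a layer stack
#'
#' Propagates a normally incident plane wave by BPM and measures, after
#' every layer, (i) the power remaining in the unscattered k-component
#' and (ii) the intensity-weighted mean cosine of the propagation angle
#' from the angular spectrum. Linear fits of the log of each quantity
#' against depth yield the realised scattering mean free path `l_s` and
#' transport mean free path `l_t` (via `<cos theta> = exp(-z / l_t)`).
#'
#' @param config A [tissue_config()] (surface deflection is disabled for
#'   the fit).
#' @param grid A [grid2d()]; its Nyquist limit should exceed `k_medium`
#'   so no propagating scattering order is clipped.
#' @param seeds Integer vector of screen seeds to average over.
#' @return List with `l_s`, `l_t` (mean fitted lengths, um) and a
#'   `per_seed` data frame.
#' @export
fit_scattering_lengths <- function(config, grid, seeds = 1:5) {
  cfg <- config
  cfg$deflection_rms <- 0
  kz <- propagator_kz(grid)
  valid <- !is.na(kz)
  cosm <- ifelse(valid, kz, 0) / grid$k_medium
  per_seed <- lapply(seeds, function(sd) {
    layers <- generate_layer_screens(cfg, grid, seed = sd)
    bp <- bpm_propagate(matrix(1 + 0i, grid$nx, grid$ny), layers, "forward",
                        grid)
    planes <- c(bp$incident[-1], list(bp$exit))
    z <- seq_along(planes) * cfg$dz_layer
    pb <- vapply(planes, function(e) Mod(mean(e))^2, numeric(1))
    ct <- vapply(planes, function(e) {
      p <- Mod(fft2_centered(e, grid))^2
      sum(p[valid] * cosm[valid]) / sum(p[valid])
    }, numeric(1))
    c(l_s = -1 / stats::coef(stats::lm(log(pb) ~ z))[["z"]],
      l_t = -1 / stats::coef(stats::lm(log(ct) ~ z))[["z"]])
  })
  m <- do.call(rbind, per_seed)
  list(l_s = mean(m[, "l_s"]), l_t = mean(m[, "l_t"]),
       per_seed = data.frame(seed = seeds, m))
}

#' Total reflectance of a layer stack (single-backscatter model)
#'
#' Forward-propagates a plane wave and sums the power of every layer's
#' reflected source relative to the input power. The power split at each
#' layer is exact (`|t|^2 + |r|^2 = 1` pointwise), so input power equals
#' exit + reflected + evanescent-clipped power.
#'
#' @param layers A [generate_layer_screens()] stack.
#' @param grid A [grid2d()].
#' @return List with `reflectance`, and the `audit` vector
#'   (input, exit, reflected, clipped powers).
#' @export
stack_reflectance <- function(layers, grid = layers$grid) {
  bp <- bpm_propagate(matrix(1 + 0i, grid$nx, grid$ny), layers, "forward",
                      grid)
  refl <- sum(vapply(seq_along(layers$r), function(j) {
    sum(Mod(layers$r[[j]] * bp$incident[[j]])^2)
  }, numeric(1)))
  audit <- c(input = bp$power[["input"]], exit = bp$power[["exit"]],
             reflected = refl, clipped = bp$power[["clipped"]])
  list(reflectance = refl / bp$power[["input"]], audit = audit)
}

#' Reflectivity target phantom
#'
#' Letter-"A" amplitude pattern with, by default, a random per-pixel phase
#' (optically rough surface). The roughness matters: diffuse backscatter
#' fills the detection pupil, so the aberration-matrix columns of
#' different illuminations overlap in k-space — a smooth (specular)
#' target would confine each column to a small disc around its own `k_in`
#' and leave the factorization uncoupled.
#'
#' @param grid A [grid2d()].
#' @param base Background reflectivity amplitude.
#' @param contrast Additional amplitude on the letter strokes.
#' @param rough Apply a random phase per pixel.
#' @param seed Seed for the roughness.
#' @return Complex reflectivity matrix.
#' @export
reflectivity_target <- function(grid, base = 0.1, contrast = 0.6,
                                rough = TRUE, seed = 99L) {
  m <- matrix(base + 0i, grid$nx, grid$ny)
  m[rasterize_letter_a(grid$nx, grid$ny)] <- base + contrast
  if (rough) {
    m <- m * with_seed(seed, matrix(exp(2i * pi * stats::runif(grid$nx * grid$ny)),
                                    grid$nx, grid$ny))
  }
  m
}

#' Brownian bead sequence with cycling tilted illumination
#'
#' Generates the time-resolved acquisition the tilt-group detection uses
#' on moving samples: beads diffuse between consecutive frames while the
#' illumination cycles through (centre, tilt 1, tilt 2) for each group, so
#' each tilt group spans three consecutive frames. Fields are thin-target
#' forward models of the projected bead phase through the outgoing screen.
#'
#' @param grid A [grid2d()].
#' @param groups Illumination [tilt_group()]s (each must have two tilts).
#' @param n_beads Number of beads.
#' @param bead_radius Bead radius (um); 1 um matches 2-um silica beads.
#' @param bead_delta_n RI contrast of the beads over the medium.
#' @param diffusion Diffusion coefficient (um^2/s).
#' @param frame_interval Time between frames (s); 1/60 s by default.
#' @param screen_out Outgoing aberration screen (or `NULL`).
#' @param seed Seed for positions and steps.
#' @return A [field_stack()] with `times`; warns when the RMS per-frame
#'   displacement exceeds the diffraction limit `lambda / (2 NA)`, the
#'   stated validity bound of consecutive-frame detection.
#' @export
brownian_bead_sequence <- function(grid, groups, n_beads = 12,
                                   bead_radius = 1, bead_delta_n = 0.05,
                                   diffusion = 0.1, frame_interval = 1 / 60,
                                   screen_out = NULL, seed = 1L) {
  step_sd <- sqrt(2 * diffusion * frame_interval)
  dlim <- grid$wavelength / (2 * grid$na_det)
  if (step_sd * sqrt(2) > dlim) {
    warning(sprintf(
      "RMS per-frame displacement %.3g um exceeds the diffraction limit %.3g um; aberration recovery will degrade",
      step_sd * sqrt(2), dlim))
  }
  fov <- c(grid$nx, grid$ny) * grid$dx
  rc <- grid_coords(grid, "r")
  k0 <- 2 * pi / grid$wavelength
  bead_field <- function(pos) {
    ph <- matrix(0, grid$nx, grid$ny)
    for (b in seq_len(nrow(pos))) {
      d2 <- (rc$x - pos[b, 1])^2 + (rc$y - pos[b, 2])^2
      inside <- d2 < bead_radius^2
      ph[inside] <- ph[inside] +
        k0 * bead_delta_n * 2 * sqrt(bead_radius^2 - d2[inside])
    }
    exp(1i * ph)
  }
  n_frames <- 3L * length(groups)
  sim <- with_seed(seed, {
    pos <- cbind(stats::runif(n_beads, -fov[1] / 3, fov[1] / 3),
                 stats::runif(n_beads, -fov[2] / 3, fov[2] / 3))
    frames <- vector("list", n_frames)
    kins <- vector("list", n_frames)
    f <- 0L
    for (g in seq_along(groups)) {
      slots <- c(list(c(0, 0)), groups[[g]]$tilt_offsets)
      for (s in seq_along(slots)) {
        f <- f + 1L
        kins[[f]] <- groups[[g]]$k_center + slots[[s]]
        frames[[f]] <- bead_field(pos)
        pos <- pos + matrix(stats::rnorm(2 * n_beads, sd = step_sd),
                            n_beads, 2)
      }
    }
    list(frames = frames, kins = kins)
  })
  phi_out <- screen_phase(screen_out, grid)
  support <- pupil_mask(grid)
  out_filter <- exp(1i * phi_out) * support
  data <- vector("list", length(groups))
  f <- 0L
  for (g in seq_along(groups)) {
    nslot <- 1L + length(groups[[g]]$tilt_offsets)
    data[[g]] <- vector("list", nslot)
    for (s in seq_len(nslot)) {
      f <- f + 1L
      kin <- sim$kins[[f]]
      e_ill <- exp(1i * (kin[1] * rc$x + kin[2] * rc$y))
      spec <- fft2_centered(e_ill * sim$frames[[f]], grid) * out_filter
      data[[g]][[s]] <- ifft2_centered(spec, grid)
    }
  }
  field_stack(grid, groups, data,
              times = (seq_len(n_frames) - 1) * frame_interval)
}
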