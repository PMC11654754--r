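new_projection_stack <- function(images, geom, ref_signal, mode,
                                 is_log_normalized = FALSE, exposure = NULL,
                                 seed_record = list()) {
  s <- acquisition_schedule(geom)
  structure(list(images = images,
                 view_angles_deg = s$view_center_angles_deg,
                 view_times_s = s$view_center_times_s,
                 geometry = geom, exposure = exposure,
                 is_log_normalized = is_log_normalized,
                 ref_signal = ref_signal, mode = mode,
                 seed_record = seed_record),
            class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf(
    "<projection_stack> %d views of %dx%d px (%s, %s)\n",
    d[3L], d[1L], d[2L], x$mode,
    if (x$is_log_normalized) "log-normalized" else "intensity"))
  invisible(x)
}

# Source sample positions (matrix S x 3) for one view: focal-spot extent
# crossed with pulse-time offsets. With FFS the time samples collapse.
source_samples <- function(geom, view_index, n_spot, n_time) {
  s <- acquisition_schedule(geom)
  alpha <- s$view_center_angles_deg[view_index + 1L]
  taus <- if (geom$focal_spot$ffs_enabled || n_time <= 1L) 0 else
    ((seq_len(n_time) - 0.5) / n_time - 0.5)
  # FFS deflection amplitude over the pulse (for the shrink model)
  defl <- if (geom$focal_spot$ffs_enabled)
    s$angular_speed_deg_s * geom$pulse_length_ms / 2000 else 0
  sp <- focal_spot_offsets(geom, defl, n_spot)
  out <- matrix(0, length(taus) * length(sp$dx), 3L)
  r <- 0L
  for (tau in taus) {
    pos <- source_position(geom, view_index, tau)
    a <- if (geom$focal_spot$ffs_enabled) alpha else
      alpha + s$angular_speed_deg_s * tau * geom$pulse_length_ms / 1000
    ar <- a * pi / 180
    tangent <- c(cos(ar), 0, -sin(ar))     # tube-travel direction on the arc
    for (dx in sp$dx) {
      r <- r + 1L
      out[r, ] <- pos + dx * tangent
    }
  }
  out
}

#' Cone-beam forward projection of a voxel phantom
#'
#' Computes the noise-free expected detector signal for every view of a scan.
#' Each detector pixel is the mean over `n_spot_samples` focal-spot positions
#' and `n_time_samples` pulse-time offsets (collapsing to one time sample
#' when FFS is enabled, since the deflection cancels gantry motion) of the
#' Beer--Lambert transmission along the ray, with the pixel aperture
#' integrated by `n_det_sub` sub-samples along the tube-travel direction.
#' Ray integrals use incremental traversal with trilinear interpolation
#' (Joseph-style), step = half the smallest voxel dimension by default.
#'
#' @param phantom a `voxel_phantom`.
#' @param geom an [make_geometry()] object.
#' @param spectrum either a single effective energy in keV (fast default) or
#'   an `xray_spectrum` for polychromatic projection.
#' @param n_spot_samples samples across the focal-spot extent (default 5).
#' @param n_time_samples samples across the pulse (default 5; forced to 1
#'   with FFS on).
#' @param n_det_sub detector-aperture sub-samples along x (default 5).
#' @param step_mm ray sampling step; default `min(voxel)/2`.
#' @param mAs tube load (scales the polychromatic signal; ignored in
#'   effective-energy mode, where the air signal is 1).
#' @param energy_stride use every k-th energy bin in polychromatic mode
#'   (default 2, i.e. 1 keV resolution).
#' @return a `projection_stack` (intensity domain).
#' @export
forward_project <- function(phantom, geom, spectrum = 20,
                            n_spot_samples = 5L, n_time_samples = 5L,
                            n_det_sub = 5L, step_mm = NULL, mAs = 1,
                            energy_stride = 2L) {
  stopifnot(inherits(phantom, "voxel_phantom"),
            inherits(geom, "acquisition_geometry"))
  if (n_spot_samples < 1L || n_time_samples < 1L) {
    tb_stop("n_spot_samples and n_time_samples must be >= 1")
  }
  if (geom$source_to_detector_mm <= phantom$thickness_mm) {
    tb_stop("degenerate geometry: SID must exceed the phantom thickness")
  }
  step <- step_mm %||% (min(phantom$voxel_size_mm) / 2)
  ax <- detector_axes(geom)
  dims <- dim(phantom$material_ids)
  nv <- geom$n_projections
  poly <- inherits(spectrum, "xray_spectrum")

  if (!poly) {
    vol <- mu_volume(phantom, energy_keV = spectrum)
    img <- array(0, dim = c(length(ax$y), length(ax$x), nv))
    for (k in seq_len(nv) - 1L) {
      src <- source_samples(geom, k, n_spot_samples, n_time_samples)
      tr <- cpp_project(as.numeric(vol), as.integer(dims),
                        as.numeric(phantom$voxel_size_mm),
                        as.numeric(phantom$origin_mm), src,
                        ax$x, ax$y, geom$detector_pixel_pitch_mm,
                        as.integer(n_det_sub), step, 0L)
      dim(tr) <- c(length(ax$x), length(ax$y), nrow(src))
      img[, , k + 1L] <- t(apply(tr, c(1L, 2L), mean))
    }
    return(new_projection_stack(img, geom, ref_signal = 1,
                                mode = sprintf("effective_%gkeV", spectrum)))
  }

  # polychromatic: per-material path lengths, then spectral weighting
  sel <- seq(1L, length(spectrum$energy_bins_keV), by = energy_stride)
  E <- spectrum$energy_bins_keV[sel]
  phi <- spectrum$fluence_per_mAs[sel] * energy_stride * mAs *
    geom$detector_pixel_pitch_mm^2
  w <- phi * E * detector_efficiency(E)
  ref <- sum(w)
  mats <- setdiff(phantom$materials, "air")
  mus <- lapply(mats, function(m) mu_of(m, E))
  img <- array(0, dim = c(length(ax$y), length(ax$x), nv))
  for (k in seq_len(nv) - 1L) {
    src <- source_samples(geom, k, n_spot_samples, n_time_samples)
    S <- nrow(src)
    paths <- lapply(mats, function(m) {
      p <- cpp_project(as.numeric(material_indicator(phantom, m)),
                       as.integer(dims),
                       as.numeric(phantom$voxel_size_mm),
                       as.numeric(phantom$origin_mm), src,
                       ax$x, ax$y, geom$detector_pixel_pitch_mm, 1L, step, 1L)
      dim(p) <- c(length(ax$x) * length(ax$y), S)
      p
    })
    acc <- 0
    for (s_i in seq_len(S)) {
      sig <- 0
      for (e_i in seq_along(E)) {
        att <- 0
        for (m_i in seq_along(mats)) {
          att <- att + mus[[m_i]][e_i] * paths[[m_i]][, s_i]
        }
        sig <- sig + w[e_i] * exp(-att)
      }
      acc <- acc + sig
    }
    m <- acc / S
    dim(m) <- c(length(ax$x), length(ax$y))
    img[, , k + 1L] <- t(m)
  }
  new_projection_stack(img, geom, ref_signal = ref, mode = "polychromatic",
                       exposure = exposure_setting(spectrum$kvp, mAs))
}

#' Apply Poisson counting noise to a projection stack
#'
#' Each pixel is replaced by `Poisson(gain * value) / gain`: `gain` is the
#' number of photons corresponding to one signal unit, so the mean is
#' preserved in expectation and the relative noise shrinks as `1/sqrt(gain)`.
#' Deterministic given `seed`.
#'
#' @param stack intensity-domain `projection_stack`.
#' @param gain photons per signal unit (> 0).
#' @param seed RNG seed.
#' @return the noisy stack (seed recorded in `seed_record`).
#' @export
add_counting_noise <- function(stack, gain, seed = 1L) {
  stopifnot(inherits(stack, "projection_stack"))
  if (stack$is_log_normalized) tb_stop("stack is log-normalized; noise must be added in the intensity domain")
  if (gain <= 0) tb_stop("gain must be > 0")
  if (any(stack$images < 0)) tb_stop("negative pixel values: not pre-noise intensities")
  set.seed(seed)
  lam <- stack$images * gain
  # rpois is limited to lambda < ~2^31; use normal approximation above 1e7
  big <- lam > 1e7
  counts <- lam
  counts[!big] <- rpois(sum(!big), lam[!big])
  if (any(big)) counts[big] <- round(lam[big] + sqrt(lam[big]) * rnorm(sum(big)))
  stack$images <- counts / gain
  dim(stack$images) <- dim(lam)
  stack$seed_record <- c(stack$seed_record,
                         list(counting_noise = list(seed = seed, gain = gain)))
  stack
}

#' Log-normalize a stack to line integrals
#'
#' `p = -ln(I / I0)` per pixel, with `I0` the air-calibration reference
#' stored in the stack. Non-positive pixels are clamped to `floor_frac * I0`
#' and counted.
#'
#' @param stack intensity-domain `projection_stack`.
#' @param floor_frac clamp floor as a fraction of `I0` (default 1e-9).
#' @return log-normalized stack; attribute `n_clamped` reports clamping.
#' @export
to_line_integrals <- function(stack, floor_frac = 1e-9) {
  stopifnot(inherits(stack, "projection_stack"))
  if (stack$is_log_normalized) tb_stop("stack already log-normalized")
  i0 <- stack$ref_signal
  floorv <- floor_frac * i0
  n_clamped <- sum(stack$images < floorv)
  if (n_clamped > 0) {
    message(n_clamped, " non-positive/underflow pixels clamped before log")
  }
  stack$images <- -log(pmax(stack$images, floorv) / i0)
  stack$is_log_normalized <- TRUE
  attr(stack, "n_clamped") <- n_clamped
  stack
}
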