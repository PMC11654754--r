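# Shared small fixtures, built in code. Heavy experiment fixtures used by
# several tests are memoized within the session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# coarse-pitch desk-scale geometry for reconstruction experiments
coarse_geom <- function(rows = 96L, cols = 160L, pitch = 0.4, ffs = TRUE,
                        ...) {
  make_geometry(list(detector_shape = c(rows, cols),
                     detector_pixel_pitch_mm = pitch,
                     focal_spot = list(ffs_enabled = ffs), ...))
}

# wire projection stack for eMTF experiments; detector x-extent adapts to the
# parallax sweep at the wire height.
wire_stack <- function(h, ffs, n_proj = 25L, wire_len = 8, tilt = 3,
                       n_spot = 5L, n_time = 5L, n_sub = 5L) {
  sweep <- 650 * sin(25 * pi / 180) * h / (650 - h) + 6
  nx_det <- 2L * as.integer(ceiling(sweep / 0.085))
  ny <- as.integer(wire_len / 0.2)
  geom <- make_geometry(list(n_projections = as.integer(n_proj),
                             detector_shape = c(110L, nx_det),
                             focal_spot = list(ffs_enabled = ffs)))
  ph <- build_air_phantom(c(300L, ny, 3L), c(0.02, 0.2, 0.05),
                          origin_mm = c(-3 + 0.01, -(ny - 1) / 2 * 0.2,
                                        h - 0.05))
  ph <- add_insert(ph, insert_spec("wire", c(0, 0, h), tilt_deg = tilt))
  st <- forward_project(ph, geom, n_spot_samples = n_spot,
                        n_time_samples = if (ffs) 1L else n_time,
                        n_det_sub = n_sub)
  st
}

# reference clip phantom experiment: uniform 60-mm slab + titanium clip at
# z = 30 mm, reconstructed with and without artifact reduction.
clip_experiment <- function() memo("clip_experiment", {
  geom <- coarse_geom()
  # slab wider than the detector FOV: no breast border in the projections
  ph <- build_slab_phantom(60, glandularity = 0, shape = c(170L, 100L, 60L),
                           voxel_size_mm = c(0.4, 0.4, 1), texture_beta = 0,
                           seed = 11L)
  clip <- insert_spec("clip", c(0, 0, 30))
  ph <- add_insert(ph, clip)
  st <- forward_project(ph, geom, spectrum = 20, n_spot_samples = 1L,
                        n_time_samples = 1L, n_det_sub = 1L)
  lg <- to_line_integrals(st)
  masks <- segment_objects(lg)
  rem <- remove_objects(lg, masks)
  fp <- ramp_filter(lg, rP = rem)
  z <- seq(5, 55, by = 2.5)
  vol_base <- backproject_perspective(fp, geom, z)
  vol_ar <- masked_backproject(fp, masks, geom, z)
  list(geom = geom, phantom = ph, clip = clip, stack = st, lg = lg,
       masks = masks, fp = fp, z = z, vol_base = vol_base, vol_ar = vol_ar)
})

# single point-like microcalcification phantom, projections and perspective
# reconstruction (criterion 8 and SM geometry tests)
calc_experiment <- function() memo("calc_experiment", {
  geom <- coarse_geom(rows = 72L, cols = 120L, pitch = 0.3)
  # slab extends past the detector FOV so no slab edge enters the views
  ph <- build_slab_phantom(50, glandularity = 0, shape = c(160L, 90L, 50L),
                           voxel_size_mm = c(0.3, 0.3, 1), texture_beta = 0,
                           seed = 5L)
  calc <- insert_spec("microcalc_cluster", c(10, -2.1, 30),
                      size_mm = c(0.9, 0.9), count = 1L, density_factor = 8)
  ph <- add_insert(ph, calc)
  st <- forward_project(ph, geom, spectrum = 20, n_spot_samples = 1L,
                        n_time_samples = 1L, n_det_sub = 1L)
  lg <- to_line_integrals(st)
  fp <- ramp_filter(lg)
  vol <- backproject_perspective(fp, geom, seq(5, 45, by = 2.5))
  list(geom = geom, phantom = ph, calc = calc, stack = st, lg = lg, vol = vol)
})

# brute-force backprojection oracle: per-voxel, per-view loops, independent
# of the vectorized implementation.
oracle_backproject <- function(fp, geom, z_planes) {
  ax <- tomobreast:::detector_axes(geom)
  sid <- geom$source_to_detector_mm
  nr <- length(ax$y); nc <- length(ax$x)
  nviews <- dim(fp$oP)[3L]
  out <- array(0, dim = c(nr, nc, length(z_planes)))
  pitch <- geom$detector_pixel_pitch_mm
  for (zi in seq_along(z_planes)) {
    z <- z_planes[zi]
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      X <- ax$x[cc] * (sid - z) / sid
      Y <- ax$y[r] * (sid - z) / sid
      acc <- 0; n <- 0
      for (k in seq_len(nviews)) {
        s <- source_position(geom, k - 1L, 0)
        t <- s[3L] / (s[3L] - z)
        u <- s[1L] + t * (X - s[1L])
        v <- s[2L] + t * (Y - s[2L])
        gx <- (u - ax$x[1L]) / pitch
        gy <- (v - ax$y[1L]) / pitch
        if (gx < 0 || gx > nc - 1L || gy < 0 || gy > nr - 1L) next
        j0 <- min(floor(gx), nc - 2L); i0 <- min(floor(gy), nr - 2L)
        fx <- gx - j0; fy <- gy - i0
        img <- fp$oP[, , k]
        val <- (1 - fx) * (1 - fy) * img[i0 + 1L, j0 + 1L] +
               fx * (1 - fy) * img[i0 + 1L, j0 + 2L] +
               (1 - fx) * fy * img[i0 + 2L, j0 + 1L] +
               fx * fy * img[i0 + 2L, j0 + 2L]
        acc <- acc + val; n <- n + 1L
      }
      out[r, cc, zi] <- if (n > 0) acc / n else 0
    }
  }
  out
}

# radially averaged log-log spectral slope of a 3-D field (texture oracle)
spectral_slope <- function(field, voxel) {
  d <- dim(field)
  fax <- function(n, dd) {
    c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / (n * dd)
  }
  f2 <- outer(outer(fax(d[1], voxel[1])^2, fax(d[2], voxel[2])^2, `+`),
              fax(d[3], voxel[3])^2, `+`)
  P <- Mod(fft(field))^2
  f <- sqrt(f2)
  sel <- f > quantile(f[f > 0], 0.05) & f < quantile(f, 0.6)
  bins <- cut(log(f[sel]), breaks = 24)
  lp <- tapply(log(P[sel]), bins, mean)
  lf <- tapply(log(f[sel]), bins, mean)
  ok <- is.finite(lp) & is.finite(lf)
  unname(coef(stats::lm(lp[ok] ~ lf[ok]))[2L])
}
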