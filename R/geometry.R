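#' Acquisition geometry for a DBT scan mode
#'
#' Builds and validates an `acquisition_geometry` object describing the source
#' trajectory, detector, timing schedule, and flying-focal-spot (FFS) model of
#' one tomosynthesis scan mode. Unspecified values are filled from the
#' fast-mode defaults (25 projections over 50 deg in 4.8 s, 40 ms maximum
#' pulse, 150 ms detector readout, 85 um pixel pitch); `mode_name =
#' "moderate_fast"` switches the timing defaults to the slower mode (8.1 s,
#' 68 ms pulses).
#'
#' Coordinate frame: x is the tube-travel direction, y runs chest wall to
#' nipple, z is height above the breast support table; the detector lies in
#' the plane z = 0 and is stationary; the source moves on a circular arc of
#' radius `source_to_detector_mm - rotation_center_height_mm` about the
#' rotation center. Units are millimeters and degrees at the API.
#'
#' @param config named list overriding any of: `n_projections`,
#'   `angular_range_deg`, `acquisition_time_s`, `pulse_length_ms`,
#'   `readout_time_ms`, `source_to_detector_mm`, `rotation_center_height_mm`,
#'   `detector_pixel_pitch_mm`, `detector_shape` (rows, cols), `mode_name`,
#'   `focal_spot` (list: `nominal_size_mm`, `ffs_enabled`,
#'   `deflection_shrink_coeff`). Unknown keys are rejected.
#' @return An object of class `acquisition_geometry`.
#' @export
make_geometry <- function(config = list()) {
  if (length(config) && (is.null(names(config)) || any(names(config) == ""))) {
    tb_config_error("(unnamed)", "all config entries must be named")
  }
  known <- c("n_projections", "angular_range_deg", "acquisition_time_s",
             "pulse_length_ms", "readout_time_ms", "source_to_detector_mm",
             "rotation_center_height_mm", "detector_pixel_pitch_mm",
             "detector_shape", "mode_name", "focal_spot")
  bad <- setdiff(names(config), known)
  if (length(bad)) tb_config_error(bad[1L], "unknown configuration key")

  mode <- config$mode_name %||% "fast"
  if (!mode %in% c("fast", "moderate_fast")) {
    tb_config_error("mode_name", "must be 'fast' or 'moderate_fast'")
  }
  defaults <- list(
    n_projections = 25L,
    angular_range_deg = 50,
    acquisition_time_s = if (mode == "fast") 4.8 else 8.1,
    pulse_length_ms = if (mode == "fast") 40 else 68,
    readout_time_ms = 150,
    source_to_detector_mm = 650,
    rotation_center_height_mm = 0,
    detector_pixel_pitch_mm = 0.085,
    detector_shape = c(96L, 256L),
    mode_name = mode,
    focal_spot = list()
  )
  g <- modifyList(defaults, config)
  fs_defaults <- list(nominal_size_mm = 0.3, ffs_enabled = TRUE,
                      deflection_shrink_coeff = 0)
  bad <- setdiff(names(g$focal_spot), names(fs_defaults))
  if (length(bad)) tb_config_error(paste0("focal_spot$", bad[1L]),
                                   "unknown configuration key")
  g$focal_spot <- modifyList(fs_defaults, g$focal_spot)

  # --- invariants ---
  chk <- function(ok, field, msg) if (!isTRUE(ok)) tb_config_error(field, msg)
  g$n_projections <- as.integer(g$n_projections)
  chk(g$n_projections >= 1L, "n_projections", "must be >= 1")
  chk(g$angular_range_deg > 0 && g$angular_range_deg < 180,
      "angular_range_deg", "must lie in (0, 180)")
  chk(g$acquisition_time_s > 0, "acquisition_time_s", "must be > 0")
  max_pulse <- 1000 * g$acquisition_time_s / max(g$n_projections - 1L, 1L)
  chk(g$pulse_length_ms > 0 && g$pulse_length_ms <= max_pulse,
      "pulse_length_ms",
      sprintf("must be in (0, %.3f] ms for this schedule", max_pulse))
  chk(g$detector_pixel_pitch_mm > 0, "detector_pixel_pitch_mm", "must be > 0")
  chk(g$rotation_center_height_mm >= 0, "rotation_center_height_mm",
      "must be >= 0")
  chk(g$source_to_detector_mm > g$rotation_center_height_mm,
      "source_to_detector_mm", "SID must exceed rotation_center_height_mm")
  chk(length(g$detector_shape) == 2L && all(g$detector_shape >= 1),
      "detector_shape", "must be (rows, cols) with both >= 1")
  g$detector_shape <- as.integer(g$detector_shape)
  chk(g$focal_spot$nominal_size_mm > 0, "focal_spot$nominal_size_mm",
      "must be > 0")
  chk(g$focal_spot$deflection_shrink_coeff >= 0,
      "focal_spot$deflection_shrink_coeff", "must be >= 0")
  if (g$n_projections > 1L) {
    frame_ms <- 1000 * g$acquisition_time_s / (g$n_projections - 1L)
    if (g$pulse_length_ms + g$readout_time_ms > frame_ms) {
      warning(sprintf(
        "pulse (%g ms) + readout (%g ms) exceed the %.1f ms frame period",
        g$pulse_length_ms, g$readout_time_ms, frame_ms))
    }
  }
  class(g) <- "acquisition_geometry"
  g
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  s <- acquisition_schedule(x)
  cat(sprintf(
    paste0("<acquisition_geometry '%s'>\n",
           "  %d projections over %g deg in %g s ",
           "(%.3g fps, %.4g deg/s)\n",
           "  pulse %g ms, readout %g ms, SID %g mm, pitch %g mm, ",
           "detector %dx%d\n  focal spot %g mm, FFS %s\n"),
    x$mode_name, x$n_projections, x$angular_range_deg, x$acquisition_time_s,
    s$frames_per_second, s$angular_speed_deg_s,
    x$pulse_length_ms, x$readout_time_ms, x$source_to_detector_mm,
    x$detector_pixel_pitch_mm, x$detector_shape[1L], x$detector_shape[2L],
    x$focal_spot$nominal_size_mm,
    if (x$focal_spot$ffs_enabled) "on" else "off"))
  invisible(x)
}

#' Timing and angle schedule of a scan
#'
#' Frames per second is defined over the sweep, `(n_projections - 1) /
#' acquisition_time_s`, so that `fps * time = n - 1` exactly; the tube
#' traveling speed is `angular_range_deg / acquisition_time_s`. View centers
#' are evenly spaced in time starting at 0 and evenly spaced in angle spanning
#' `[-theta/2, +theta/2]` (antisymmetric about the central view).
#'
#' @param geom an [make_geometry()] object.
#' @return A list of class `schedule_summary` with `frames_per_second`,
#'   `angular_speed_deg_s`, `angular_spacing_deg`, `view_center_times_s`,
#'   `view_center_angles_deg`.
#' @export
acquisition_schedule <- function(geom) {
  stopifnot(inherits(geom, "acquisition_geometry"))
  n <- geom$n_projections
  if (n == 1L) {
    out <- list(frames_per_second = 0, angular_speed_deg_s = 0,
                angular_spacing_deg = 0, view_center_times_s = 0,
                view_center_angles_deg = 0)
  } else {
    th <- geom$angular_range_deg
    out <- list(
      frames_per_second = (n - 1) / geom$acquisition_time_s,
      angular_speed_deg_s = th / geom$acquisition_time_s,
      angular_spacing_deg = th / (n - 1),
      view_center_times_s = seq(0, geom$acquisition_time_s, length.out = n),
      view_center_angles_deg = seq(-th / 2, th / 2, length.out = n))
  }
  class(out) <- "schedule_summary"
  out
}

#' Source position during a pulse
#'
#' Returns the 3-D focal-spot position (mm) for view `view_index` at pulse
#' phase `tau` (fraction of the pulse window, in \[-0.5, 0.5\], 0 = pulse
#' center). With FFS enabled, the electromagnetic deflection exactly cancels
#' gantry motion within the pulse, so the position is constant over `tau`;
#' with FFS disabled, the source advances along the arc at the tube traveling
#' speed.
#'
#' @param geom geometry.
#' @param view_index 0-based view index.
#' @param tau pulse phase in \[-0.5, 0.5\].
#' @return numeric length-3 vector (x, y, z) in mm.
#' @export
source_position <- function(geom, view_index, tau = 0) {
  stopifnot(inherits(geom, "acquisition_geometry"))
  if (view_index < 0 || view_index >= geom$n_projections) {
    tb_stop("view_index ", view_index, " outside [0, ",
            geom$n_projections - 1L, "]")
  }
  if (tau < -0.5 || tau > 0.5) {
    tb_stop("tau must lie in [-0.5, 0.5], got ", tau)
  }
  s <- acquisition_schedule(geom)
  alpha <- s$view_center_angles_deg[view_index + 1L]
  if (!geom$focal_spot$ffs_enabled) {
    alpha <- alpha + s$angular_speed_deg_s * tau * geom$pulse_length_ms / 1000
  }
  a <- alpha * pi / 180
  R <- geom$source_to_detector_mm - geom$rotation_center_height_mm
  hc <- geom$rotation_center_height_mm
  c(R * sin(a), 0, hc + R * cos(a))
}

#' Geometric magnification at a height
#'
#' `M(h) = SID / (SID - h)` for the central view: an object at height `h`
#' above the detector casts a shadow magnified by this factor.
#'
#' @param geom geometry.
#' @param height_mm height above the detector plane, `0 <= h < SID`.
#' @return dimensionless magnification factor (vectorized over `height_mm`).
#' @export
magnification <- function(geom, height_mm) {
  stopifnot(inherits(geom, "acquisition_geometry"))
  sid <- geom$source_to_detector_mm
  if (any(height_mm < 0) || any(height_mm >= sid)) {
    tb_stop("height_mm must lie in [0, SID); SID = ", sid, " mm")
  }
  sid / (sid - height_mm)
}

#' Serialize / deserialize a geometry as JSON
#' @param geom geometry object.
#' @param path file path; if `NULL`, the JSON string is returned.
#' @export
geometry_to_json <- function(geom, path = NULL) {
  stopifnot(inherits(geom, "acquisition_geometry"))
  js <- jsonlite::toJSON(unclass(geom), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname geometry_to_json
#' @param json JSON string or file path produced by [geometry_to_json()].
#' @export
geometry_from_json <- function(json) {
  lst <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  make_geometry(lst)
}

# Detector pixel center coordinates (mm), centered on the origin.
# Columns index x (tube travel), rows index y.
detector_axes <- function(geom) {
  p <- geom$detector_pixel_pitch_mm
  nr <- geom$detector_shape[1L]; nc <- geom$detector_shape[2L]
  list(x = (seq_len(nc) - (nc + 1) / 2) * p,
       y = (seq_len(nr) - (nr + 1) / 2) * p)
}

# Focal-spot sample offsets (mm along x) and weights for one view.
# n = 1 collapses to the spot center. The deflected spot shrinks by
# (1 - shrink * |deflection_deg|), floored at 10% of nominal.
focal_spot_offsets <- function(geom, deflection_deg = 0, n = 5L) {
  size <- geom$focal_spot$nominal_size_mm *
    max(1 - geom$focal_spot$deflection_shrink_coeff * abs(deflection_deg), 0.1)
  if (n <= 1L) return(list(dx = 0, w = 1))
  # midpoints of n equal sub-intervals across the spot extent
  dx <- ((seq_len(n) - 0.5) / n - 0.5) * size
  list(dx = dx, w = rep(1 / n, n))
}
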