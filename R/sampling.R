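#' Native slice thickness of a tomosynthesis scan
#'
#' The minimum reconstructed slice separation at which two adjacent slices can
#' carry different content at in-plane frequency `f` is
#' `d(f) = 1 / (2 f tan(theta/2))` for a scan of angular range `theta`:
#' wider scans and finer structures localize better in depth.
#'
#' @param f_lpmm in-plane spatial frequency in lp/mm, `> 0` (vectorized).
#' @param theta_deg angular scan range in degrees, in (0, 180).
#' @return native slice thickness in mm.
#' @seealso [z_frequency_coverage()] for the reciprocal quantity.
#' @export
native_slice_thickness <- function(f_lpmm, theta_deg) {
  check_sampling_args(f_lpmm, theta_deg)
  1 / (2 * f_lpmm * tan(theta_deg * pi / 360))
}

#' Depth-frequency coverage of a tomosynthesis scan
#'
#' The maximum frequency sampled in the depth (z) direction at in-plane
#' frequency `f` is `F_z = f tan(theta/2)`; identically `1 / (2 d(f))` with
#' `d` the native slice thickness.
#'
#' @inheritParams native_slice_thickness
#' @return z-direction Nyquist frequency in lp/mm.
#' @export
z_frequency_coverage <- function(f_lpmm, theta_deg) {
  check_sampling_args(f_lpmm, theta_deg)
  f_lpmm * tan(theta_deg * pi / 360)
}

check_sampling_args <- function(f_lpmm, theta_deg) {
  if (any(f_lpmm <= 0)) {
    tb_stop("f_lpmm must be > 0 (d is unbounded as f -> 0)")
  }
  if (any(theta_deg <= 0) || any(theta_deg >= 180)) {
    tb_stop("theta_deg must lie in (0, 180)")
  }
  invisible(TRUE)
}

#' Sampling summary for a scan
#'
#' @param geom geometry (provides theta and n_projections), or pass
#'   `theta_deg`/`n_projections` directly.
#' @param f_lpmm in-plane frequency of interest.
#' @inheritParams native_slice_thickness
#' @param n_projections number of projections.
#' @return list with `angular_range_deg`, `n_projections`,
#'   `in_plane_frequency_lpmm`, `native_slice_thickness_mm`,
#'   `z_frequency_extent_lpmm`.
#' @export
sampling_spec <- function(f_lpmm, theta_deg = NULL, n_projections = NULL,
                          geom = NULL) {
  if (!is.null(geom)) {
    theta_deg <- geom$angular_range_deg
    n_projections <- geom$n_projections
  }
  list(angular_range_deg = theta_deg,
       n_projections = n_projections,
       in_plane_frequency_lpmm = f_lpmm,
       native_slice_thickness_mm = native_slice_thickness(f_lpmm, theta_deg),
       z_frequency_extent_lpmm = z_frequency_coverage(f_lpmm, theta_deg))
}

#' k-space fill mask of a projection set
#'
#' Marks the Fourier-domain (f_x, f_z) cells sampled by `n_projections`
#' central-slice lines through the origin at the evenly spaced view angles of
#' a scan of range `theta_deg`. Each line has a thickness of one cell by
#' default. This is a pedagogical/QC artifact illustrating why wide scan
#' angles fill more of k-space; the reconstructor does not use it.
#'
#' @param theta_deg angular range in degrees.
#' @param n_projections number of projections (>= 1).
#' @param grid integer (n_fx, n_fz) grid dimensions, each >= 3.
#' @param f_max_lpmm half-extent of the frequency axes in lp/mm.
#' @param line_thickness_cells thickness of each line in cells (default 1).
#' @return logical matrix `grid[1] x grid[2]`; attribute `fill_fraction`.
#' @export
kspace_mask <- function(theta_deg, n_projections, grid = c(512L, 512L),
                        f_max_lpmm = 5, line_thickness_cells = 1) {
  if (any(grid < 3)) tb_stop("grid dims must be >= 3")
  if (n_projections < 1) tb_stop("n_projections must be >= 1")
  check_sampling_args(1, theta_deg)
  nfx <- grid[1L]; nfz <- grid[2L]
  fx <- seq(-f_max_lpmm, f_max_lpmm, length.out = nfx)
  fz <- seq(-f_max_lpmm, f_max_lpmm, length.out = nfz)
  cell <- line_thickness_cells *
    max(fx[2L] - fx[1L], fz[2L] - fz[1L])
  angles <- if (n_projections == 1L) 0 else
    seq(-theta_deg / 2, theta_deg / 2, length.out = n_projections) * pi / 180
  FX <- matrix(fx, nfx, nfz)
  FZ <- matrix(fz, nfx, nfz, byrow = TRUE)
  mask <- matrix(FALSE, nfx, nfz)
  for (a in angles) {
    # central-slice line tilted by the view angle from the f_x axis:
    # perpendicular distance |fx sin a - fz cos a| ... line along (cos a, sin a)
    dist <- abs(FX * sin(a) - FZ * cos(a))
    mask <- mask | (dist <= cell / 2)
  }
  structure(mask, fill_fraction = mean(mask))
}
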