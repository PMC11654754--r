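#' Synthetic compressed-breast slab phantom with power-law texture
#'
#' Generates a voxel phantom of a compressed breast: a slab of glandular /
#' adipose tissue whose mixing field is isotropic `1/f^beta` power-law noise
#' (the standard model of anatomical texture) thresholded so that the mean
#' glandular fraction matches the request. Deterministic given `seed`.
#'
#' @param thickness_mm compressed thickness in \[20, 90\] mm.
#' @param glandularity target mean glandular fraction in \[0, 1\].
#' @param shape integer (nx, ny, nz) voxel counts; x is tube travel.
#' @param voxel_size_mm numeric (dx, dy, dz) in mm.
#' @param texture_beta power-law exponent `beta >= 0` of the power spectrum
#'   (`beta = 0` is white noise; literature-typical breast texture ~ 3).
#' @param seed RNG seed.
#' @return object of class `voxel_phantom`: `material_ids` (3-D integer
#'   array), `materials` (labels, id indexes into it), `voxel_size_mm`,
#'   `origin_mm` (center of voxel \[1,1,1\]), `thickness_mm`,
#'   `density_scale` (3-D array or NULL), `inserts` (list).
#' @export
build_slab_phantom <- function(thickness_mm, glandularity = 0.5,
                               shape = c(64L, 64L, 32L),
                               voxel_size_mm = c(0.1, 0.1, 0.5),
                               texture_beta = 3, seed = 1L) {
  if (thickness_mm < 20 || thickness_mm > 90) {
    tb_stop("thickness_mm must lie in [20, 90]")
  }
  if (texture_beta < 0) tb_stop("texture_beta must be >= 0")
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) tb_stop("shape must be (nx,ny,nz)")
  nz_slab <- thickness_mm / voxel_size_mm[3L]
  if (shape[3L] * voxel_size_mm[3L] < thickness_mm - 1e-9) {
    tb_stop("shape too small for thickness: need >= ",
            ceiling(nz_slab), " z-voxels of ", voxel_size_mm[3L], " mm")
  }
  field <- powerlaw_field(shape, voxel_size_mm, texture_beta, seed)
  thr <- quantile(field, probs = 1 - glandularity, names = FALSE, type = 7)
  materials <- c("air", "adipose", "glandular")
  ids <- array(2L, dim = shape)
  ids[field >= thr] <- 3L
  if (glandularity == 0) ids[] <- 2L
  if (glandularity == 1) ids[] <- 3L
  # voxels above the compressed thickness are air
  zc <- (seq_len(shape[3L]) - 0.5) * voxel_size_mm[3L]
  air <- which(zc > thickness_mm)
  if (length(air)) ids[, , air] <- 1L
  structure(list(material_ids = ids, materials = materials,
                 voxel_size_mm = voxel_size_mm,
                 origin_mm = c(-(shape[1L] - 1) / 2 * voxel_size_mm[1L],
                               -(shape[2L] - 1) / 2 * voxel_size_mm[2L],
                               voxel_size_mm[3L] / 2),
                 thickness_mm = thickness_mm,
                 density_scale = NULL, inserts = list(), seed = seed,
                 texture_beta = texture_beta, glandularity = glandularity),
            class = "voxel_phantom")
}

# isotropic 1/f^beta random field on an (anisotropic-voxel) grid
powerlaw_field <- function(shape, voxel_size_mm, beta, seed) {
  set.seed(seed)
  w <- array(rnorm(prod(shape)), dim = shape)
  if (beta == 0) return(w)
  fax <- function(n, d) {
    k <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / (n * d)
    k
  }
  fx <- fax(shape[1L], voxel_size_mm[1L])
  fy <- fax(shape[2L], voxel_size_mm[2L])
  fz <- fax(shape[3L], voxel_size_mm[3L])
  f2 <- outer(outer(fx^2, fy^2, `+`), fz^2, `+`)
  amp <- f2^(-beta / 4)
  amp[1L, 1L, 1L] <- 0                        # zero DC; mean set by threshold
  wh <- fft(w) * amp
  out <- Re(fft(wh, inverse = TRUE)) / prod(shape)
  out
}

#' Empty (air) phantom
#'
#' Convenience constructor for projector tests and wire-only phantoms.
#' @inheritParams build_slab_phantom
#' @param origin_mm optional origin override (center of voxel \[1,1,1\]).
#' @export
build_air_phantom <- function(shape, voxel_size_mm, origin_mm = NULL) {
  shape <- as.integer(shape)
  structure(list(material_ids = array(1L, dim = shape),
                 materials = c("air"),
                 voxel_size_mm = voxel_size_mm,
                 origin_mm = origin_mm %||%
                   c(-(shape[1L] - 1) / 2 * voxel_size_mm[1L],
                     -(shape[2L] - 1) / 2 * voxel_size_mm[2L],
                     voxel_size_mm[3L] / 2),
                 thickness_mm = shape[3L] * voxel_size_mm[3L],
                 density_scale = NULL, inserts = list()),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$material_ids)
  cat(sprintf(
    "<voxel_phantom> %dx%dx%d voxels of %gx%gx%g mm, thickness %g mm, %d insert(s)\n",
    d[1L], d[2L], d[3L], x$voxel_size_mm[1L], x$voxel_size_mm[2L],
    x$voxel_size_mm[3L], x$thickness_mm, length(x$inserts)))
  invisible(x)
}

#' Insert specification
#'
#' @param kind one of `"microcalc_cluster"`, `"clip"`, `"wire"`, `"al_sheet"`.
#' @param position_mm 3-D center position (mm) in phantom world coordinates.
#' @param size_mm extent: cluster = sphere-diameter range (min, max) in mm;
#'   clip = (lx, ly, lz) block (default 3 x 1 x 1 mm); wire = diameter
#'   (default 0.025 mm); al_sheet = thickness.
#' @param material material label (defaults: calcium for clusters, titanium
#'   for clips and wires, Al for sheets).
#' @param count number of microcalcifications in a cluster.
#' @param spacing_mm spacing between cluster members.
#' @param tilt_deg in-plane wire tilt in (0.5, 10) degrees.
#' @param density_factor multiplier on the material's attenuation (used to
#'   mimic hydroxyapatite with the calcium table; default 2 for clusters).
#' @return list of class `insert_spec`.
#' @export
insert_spec <- function(kind, position_mm, size_mm = NULL, material = NULL,
                        count = 5L, spacing_mm = 2, tilt_deg = 3,
                        density_factor = NULL) {
  kinds <- c("microcalc_cluster", "clip", "wire", "al_sheet")
  if (!kind %in% kinds) tb_stop("kind must be one of ",
                                paste(kinds, collapse = ", "))
  if (kind == "wire" && (tilt_deg <= 0.5 || tilt_deg >= 10)) {
    tb_stop("wire tilt_deg must lie in (0.5, 10)")
  }
  defaults <- switch(kind,
    microcalc_cluster = list(size = c(0.2, 0.5), mat = "calcium", dens = 2),
    clip = list(size = c(3, 1, 1), mat = "titanium", dens = 1),
    wire = list(size = 0.025, mat = "titanium", dens = 1),
    al_sheet = list(size = 0.5, mat = "Al", dens = 1))
  structure(list(kind = kind, position_mm = position_mm,
                 size_mm = size_mm %||% defaults$size,
                 material = material %||% defaults$mat,
                 count = as.integer(count), spacing_mm = spacing_mm,
                 tilt_deg = tilt_deg,
                 density_factor = density_factor %||% defaults$dens),
            class = "insert_spec")
}

phantom_axes <- function(phantom) {
  d <- dim(phantom$material_ids)
  v <- phantom$voxel_size_mm; o <- phantom$origin_mm
  list(x = o[1L] + (seq_len(d[1L]) - 1L) * v[1L],
       y = o[2L] + (seq_len(d[2L]) - 1L) * v[2L],
       z = o[3L] + (seq_len(d[3L]) - 1L) * v[3L])
}

ensure_material <- function(phantom, material) {
  mu_of(material, 20)  # validates the label
  idx <- match(material, phantom$materials)
  if (is.na(idx)) {
    phantom$materials <- c(phantom$materials, material)
    idx <- length(phantom$materials)
  }
  list(phantom = phantom, id = idx)
}

ensure_density <- function(phantom) {
  if (is.null(phantom$density_scale)) {
    phantom$density_scale <- array(1, dim = dim(phantom$material_ids))
  }
  phantom
}

#' Add an insert to a voxel phantom
#'
#' Microcalcification clusters place `count` calcium spheres (diameters
#' cycling through the `size_mm` range) on a jittered ring of radius
#' `spacing_mm`; clips are rectangular metal blocks; wires are thin in-plane
#' tilted cylinders voxelized with sub-voxel (area-fraction) weighting so
#' they act as a line stimulus; `al_sheet` spans the whole field at the
#' stated height. Out-of-bounds inserts error, listing the overhang.
#'
#' @param phantom a `voxel_phantom`.
#' @param spec an [insert_spec()].
#' @return the modified phantom.
#' @export
add_insert <- function(phantom, spec) {
  stopifnot(inherits(phantom, "voxel_phantom"), inherits(spec, "insert_spec"))
  ax <- phantom_axes(phantom)
  v <- phantom$voxel_size_mm
  bounds <- c(min(ax$x) - v[1L] / 2, max(ax$x) + v[1L] / 2,
              min(ax$y) - v[2L] / 2, max(ax$y) + v[2L] / 2,
              min(ax$z) - v[3L] / 2, max(ax$z) + v[3L] / 2)
  check_bounds <- function(lo, hi) {
    over <- c(x_low = bounds[1L] - lo[1L], x_high = hi[1L] - bounds[2L],
              y_low = bounds[3L] - lo[2L], y_high = hi[2L] - bounds[4L],
              z_low = bounds[5L] - lo[3L], z_high = hi[3L] - bounds[6L])
    bad <- over[over > 1e-9]
    if (length(bad)) {
      tb_stop("insert out of bounds; overhang (mm): ",
              paste(names(bad), signif(bad, 3), sep = "=", collapse = ", "))
    }
  }
  em <- ensure_material(phantom, spec$material)
  phantom <- em$phantom; mid <- em$id
  p <- spec$position_mm

  if (spec$kind == "clip") {
    half <- spec$size_mm / 2
    check_bounds(p - half, p + half)
    ix <- which(abs(ax$x - p[1L]) <= half[1L])
    iy <- which(abs(ax$y - p[2L]) <= half[2L])
    iz <- which(abs(ax$z - p[3L]) <= half[3L])
    phantom$material_ids[ix, iy, iz] <- mid
  } else if (spec$kind == "al_sheet") {
    half <- spec$size_mm[1L] / 2
    iz <- which(abs(ax$z - p[3L]) <= half)
    if (!length(iz)) tb_stop("al_sheet height misses every voxel layer")
    phantom$material_ids[, , iz] <- mid
  } else if (spec$kind == "microcalc_cluster") {
    if (spec$count > 0L) {
      ang <- 2 * pi * (seq_len(spec$count) - 1L) / spec$count
      cx <- p[1L] + spec$spacing_mm * cos(ang)
      cy <- p[2L] + spec$spacing_mm * sin(ang)
      dia <- rep(seq(spec$size_mm[1L], spec$size_mm[length(spec$size_mm)],
                     length.out = max(spec$count, 2L)),
                 length.out = spec$count)
      if (spec$count == 1L) { cx <- p[1L]; cy <- p[2L] }
      phantom <- ensure_density(phantom)
      for (k in seq_len(spec$count)) {
        r <- dia[k] / 2
        check_bounds(c(cx[k] - r, cy[k] - r, p[3L] - r),
                     c(cx[k] + r, cy[k] + r, p[3L] + r))
        ix <- which(abs(ax$x - cx[k]) <= r + v[1L] / 2)
        iy <- which(abs(ax$y - cy[k]) <= r + v[2L] / 2)
        iz <- which(abs(ax$z - p[3L]) <= r + v[3L] / 2)
        # partial-volume voxelization: occupancy by 3x3x3 sub-sampling, so
        # spheres smaller than a voxel still deposit their mass
        sub <- (seq_len(3L) - 2) / 3
        for (i in ix) for (j in iy) for (l in iz) {
          dx2 <- (ax$x[i] + sub * v[1L] - cx[k])^2
          dy2 <- (ax$y[j] + sub * v[2L] - cy[k])^2
          dz2 <- (ax$z[l] + sub * v[3L] - p[3L])^2
          frac <- mean(outer(outer(dx2, dy2, `+`), dz2, `+`) <= r^2)
          if (frac > 0) {
            phantom$material_ids[i, j, l] <- mid
            phantom$density_scale[i, j, l] <- frac * spec$density_factor
          }
        }
      }
    }
  } else if (spec$kind == "wire") {
    # thin cylinder along y, tilted in-plane: x(y) = x0 + tan(tilt) * (y - y0)
    phantom <- ensure_density(phantom)
    r <- spec$size_mm[1L] / 2
    slope <- tan(spec$tilt_deg * pi / 180)
    xs <- p[1L] + slope * (ax$y - p[2L])
    check_bounds(c(min(xs) - r, min(ax$y), p[3L] - r),
                 c(max(xs) + r, max(ax$y), p[3L] + r))
    # cross-section area fraction, split bilinearly over 2x2 (x,z) voxels
    area_frac <- pi * r^2 / (v[1L] * v[3L])
    for (j in seq_along(ax$y)) {
      fx <- (xs[j] - ax$x[1L]) / v[1L]
      fz <- (p[3L] - ax$z[1L]) / v[3L]
      i0 <- floor(fx); l0 <- floor(fz)
      wx <- fx - i0; wz <- fz - l0
      for (di in 0:1) for (dl in 0:1) {
        i <- i0 + di + 1L; l <- l0 + dl + 1L
        if (i < 1L || i > length(ax$x) || l < 1L || l > length(ax$z)) next
        wgt <- (if (di == 0) 1 - wx else wx) * (if (dl == 0) 1 - wz else wz)
        if (wgt <= 0) next
        phantom$material_ids[i, j, l] <- mid
        phantom$density_scale[i, j, l] <- wgt * area_frac * spec$density_factor
      }
    }
  }
  phantom$inserts <- c(phantom$inserts, list(spec))
  phantom
}

#' One-dimensional material stack for the 1-D CNR model
#'
#' @param layers list of `(material, thickness_mm)` pairs; must be nonempty
#'   and all materials known.
#' @return list of class `one_d_stack` with `layers` and `total_thickness_mm`.
#' @export
one_d_stack <- function(layers) {
  if (!length(layers)) tb_stop("empty stack")
  for (l in layers) {
    mu_of(as.character(l[[1L]]), 20)  # validates material
    if (as.numeric(l[[2L]]) < 0) tb_stop("layer thickness must be >= 0")
  }
  structure(list(layers = layers,
                 total_thickness_mm = sum(vapply(layers, function(l)
                   as.numeric(l[[2L]]), 0))),
            class = "one_d_stack")
}

#' Transmit a spectrum through a 1-D stack
#' @param spectrum an `xray_spectrum`.
#' @param stack a [one_d_stack()].
#' @export
transmit_stack <- function(spectrum, stack) {
  stopifnot(inherits(stack, "one_d_stack"))
  for (l in stack$layers) {
    spectrum <- attenuate(spectrum, as.character(l[[1L]]),
                          as.numeric(l[[2L]]))
  }
  spectrum
}

#' Linear-attenuation volume of a phantom
#'
#' Maps material ids (and the optional per-voxel density scale) to a 3-D
#' array of mu (1/mm) at a single energy.
#'
#' @param phantom a `voxel_phantom`.
#' @param energy_keV energy at which to evaluate mu.
#' @return 3-D numeric array, same dims as the phantom grid.
#' @export
mu_volume <- function(phantom, energy_keV = 20) {
  mus <- vapply(phantom$materials, function(m) mu_of(m, energy_keV), 0)
  vol <- array(mus[phantom$material_ids], dim = dim(phantom$material_ids))
  if (!is.null(phantom$density_scale)) vol <- vol * phantom$density_scale
  vol
}

# per-material indicator volume (path-length projection support)
material_indicator <- function(phantom, material) {
  idx <- match(material, phantom$materials)
  if (is.na(idx)) return(NULL)
  vol <- array(0, dim = dim(phantom$material_ids))
  sel <- phantom$material_ids == idx
  if (!is.null(phantom$density_scale)) {
    vol[sel] <- phantom$density_scale[sel]
  } else vol[sel] <- 1
  vol
}
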