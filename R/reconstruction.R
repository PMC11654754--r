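new_recon_volume <- function(slices, coordinate_system, slice_heights_mm,
                             geom, slice_thickness_mm = NULL,
                             slice_spacing_mm = NULL) {
  sp <- if (length(slice_heights_mm) > 1L)
    slice_heights_mm[2L] - slice_heights_mm[1L] else NA_real_
  structure(list(slices = slices,
                 coordinate_system = coordinate_system,
                 slice_heights_mm = slice_heights_mm,
                 slice_thickness_mm = slice_thickness_mm %||% sp,
                 slice_spacing_mm = slice_spacing_mm %||% sp,
                 geometry = geom),
            class = "recon_volume")
}

#' @export
print.recon_volume <- function(x, ...) {
  d <- dim(x$slices)
  cat(sprintf(
    "<recon_volume> %d slices of %dx%d (%s coords), z %g..%g mm, thickness %g / spacing %g mm\n",
    d[3L], d[1L], d[2L], x$coordinate_system,
    min(x$slice_heights_mm), max(x$slice_heights_mm),
    x$slice_thickness_mm, x$slice_spacing_mm))
  invisible(x)
}

# vectorized bilinear sampling of one image; coordinates in detector mm.
# Returns list(val, inside); outside samples give val 0, inside FALSE.
bilinear_view <- function(img, xq, yq, ax) {
  p_x <- ax$x[2L] - ax$x[1L]
  p_y <- if (length(ax$y) > 1L) ax$y[2L] - ax$y[1L] else p_x
  gx <- (xq - ax$x[1L]) / p_x            # 0-based fractional column
  gy <- (yq - ax$y[1L]) / p_y            # 0-based fractional row
  nc <- ncol(img); nr <- nrow(img)
  inside <- gx >= 0 & gx <= nc - 1L & gy >= 0 & gy <= nr - 1L
  gx <- pmin(pmax(gx, 0), nc - 1L)
  gy <- pmin(pmax(gy, 0), nr - 1L)
  j0 <- pmin(floor(gx), nc - 2L); i0 <- pmin(floor(gy), nr - 2L)
  j0 <- pmax(j0, 0); i0 <- pmax(i0, 0)
  fx <- gx - j0; fy <- gy - i0
  i0 <- i0 + 1L; j0 <- j0 + 1L            # to 1-based
  idx <- function(i, j) img[cbind(as.vector(i), as.vector(j))]
  v <- (1 - fx) * (1 - fy) * idx(i0, j0) +
       fx * (1 - fy) * idx(i0, j0 + 1L) +
       (1 - fx) * fy * idx(i0 + 1L, j0) +
       fx * fy * idx(i0 + 1L, j0 + 1L)
  dim(v) <- dim(xq)
  v[!inside] <- 0
  list(val = v, inside = inside)
}

nearest_view <- function(img, xq, yq, ax) {
  p_x <- ax$x[2L] - ax$x[1L]
  p_y <- if (length(ax$y) > 1L) ax$y[2L] - ax$y[1L] else p_x
  j <- round((xq - ax$x[1L]) / p_x) + 1L
  i <- round((yq - ax$y[1L]) / p_y) + 1L
  ok <- i >= 1L & i <= nrow(img) & j >= 1L & j <= ncol(img)
  out <- array(FALSE, dim = dim(xq))
  out[ok] <- img[cbind(i[ok], j[ok])] != 0
  out
}

ramp_response <- function(n, pitch, window) {
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / (n * pitch)
  fny <- 1 / (2 * pitch)
  H <- abs(f)
  w <- switch(window,
    none = rep(1, n),
    hann = 0.5 * (1 + cos(pi * f / fny)),
    hamming = 0.54 + 0.46 * cos(pi * f / fny),
    tb_stop("unknown window '", window, "' (none | hann | hamming)"))
  H * w
}

#' Ramp-filter a projection stack
#'
#' Applies the 1-D frequency-domain ramp `|f|`, apodized by the chosen
#' window, row-wise along the tube-travel direction (image columns).
#' Projections are zero-padded to twice the next power of two to suppress
#' wraparound. The zero-frequency response is exactly 0 and the operator is
#' linear.
#'
#' @param stack log-normalized `projection_stack` (or, for artifact
#'   reduction, an object-removed stack).
#' @param window `"none"`, `"hann"` (default) or `"hamming"`.
#' @param rP optional second log-normalized stack (object-removed) filtered
#'   identically and stored alongside.
#' @return object of class `filtered_projections` with `oP` (array rows x
#'   cols x views), optional `rP`, `filter_window`, `geometry`.
#' @export
ramp_filter <- function(stack, window = "hann", rP = NULL) {
  stopifnot(inherits(stack, "projection_stack"))
  if (!stack$is_log_normalized) tb_stop("ramp_filter needs a log-normalized stack")
  geom <- stack$geometry
  pitch <- geom$detector_pixel_pitch_mm
  filt_one <- function(imgs) {
    d <- dim(imgs)
    nx <- d[2L]
    npad <- 2L * 2L^ceiling(log2(nx))
    H <- ramp_response(npad, pitch, window)
    out <- array(0, dim = d)
    nfill <- npad - nx
    n1 <- nfill %/% 2L
    for (k in seq_len(d[3L])) {
      A <- t(imgs[, , k])                       # x runs down columns
      # edge-replicate padding (circularly continuous): a constant image
      # filters to exactly zero, and border ringing is suppressed
      Ap <- rbind(A,
                  matrix(A[nx, ], n1, ncol(A), byrow = TRUE),
                  matrix(A[1L, ], nfill - n1, ncol(A), byrow = TRUE))
      Fh <- mvfft(Ap) * H
      out[, , k] <- t(Re(mvfft(Fh, inverse = TRUE))[seq_len(nx), ] / npad)
    }
    out
  }
  structure(list(oP = filt_one(stack$images),
                 rP = if (!is.null(rP)) filt_one(rP$images),
                 filter_window = window, geometry = geom),
            class = "filtered_projections")
}

#' Backproject filtered projections into the perspective coordinate system
#'
#' The reconstruction grid follows the rays of the central projection: voxel
#' `(z, r, c)` sits where central-view detector ray `(r, c)` pierces height
#' `z`, so a structure keeps its in-plane index across slices. Each voxel
#' value is the unweighted mean over views of the filtered projection
#' sampled (bilinear) where that view's ray through the voxel hits the
#' detector; views whose sample falls off the detector are excluded and the
#' mean renormalized.
#'
#' When `masks` is supplied (artifact reduction), per (voxel, view) samples
#' whose detector location falls inside the view's object mask are read from
#' the object-removed projections `fp$rP` instead of `fp$oP`; views are
#' never dropped.
#'
#' @param fp a [ramp_filter()] result.
#' @param geom geometry (defaults to the one recorded in `fp`).
#' @param z_planes_mm slice heights, strictly increasing, within (0, SID).
#' @param masks optional `object_masks` (requires `fp$rP`).
#' @return a perspective-coordinate `recon_volume`.
#' @export
backproject_perspective <- function(fp, geom = fp$geometry, z_planes_mm,
                                    masks = NULL) {
  stopifnot(inherits(fp, "filtered_projections"))
  if (is.unsorted(z_planes_mm, strictly = TRUE)) {
    tb_stop("z_planes_mm must be strictly increasing")
  }
  sid <- geom$source_to_detector_mm
  if (any(z_planes_mm <= 0) || any(z_planes_mm >= sid)) {
    tb_stop("z_planes_mm must lie in (0, SID)")
  }
  if (!is.null(masks) && is.null(fp$rP)) {
    tb_stop("masked backprojection requires fp$rP (filter the object-removed stack)")
  }
  ax <- detector_axes(geom)
  nr <- length(ax$y); nc <- length(ax$x)
  nviews <- dim(fp$oP)[3L]
  U <- matrix(ax$x, nr, nc, byrow = TRUE)
  V <- matrix(ax$y, nr, nc)
  vol <- array(0, dim = c(nr, nc, length(z_planes_mm)))
  consensus <- attr(masks, "object_consensus") %||% 0.9
  for (zi in seq_along(z_planes_mm)) {
    z <- z_planes_mm[zi]
    scale <- (sid - z) / sid
    X <- U * scale; Y <- V * scale
    acc <- matrix(0, nr, nc); wsum <- matrix(0, nr, nc)
    acc_o <- matrix(0, nr, nc); nmask <- matrix(0, nr, nc)
    for (k in seq_len(nviews)) {
      s <- source_position(geom, k - 1L, 0)
      t <- s[3L] / (s[3L] - z)
      xq <- s[1L] + t * (X - s[1L])
      yq <- s[2L] + t * (Y - s[2L])
      bi <- bilinear_view(fp$oP[, , k], xq, yq, ax)
      val <- bi$val
      if (!is.null(masks)) {
        inmask <- nearest_view(masks$masks[, , k], xq, yq, ax)
        acc_o <- acc_o + val
        # object consensus is judged on the pre-dilation core mask, so the
        # conservative margin never widens the reverted region
        incore <- nearest_view((masks$core %||% masks$masks)[, , k],
                               xq, yq, ax)
        nmask <- nmask + (incore & bi$inside)
        if (any(inmask)) {
          br <- bilinear_view(fp$rP[, , k], xq, yq, ax)
          val[inmask] <- br$val[inmask]
        }
      }
      acc <- acc + val
      wsum <- wsum + bi$inside
    }
    if (!is.null(masks)) {
      # voxels masked in (nearly) every contributing view are the
      # high-contrast object itself, not artifact: keep the original data
      obj <- wsum > 0 & nmask >= consensus * wsum
      acc[obj] <- acc_o[obj]
    }
    slice <- acc / wsum
    slice[wsum == 0] <- 0
    vol[, , zi] <- slice
  }
  new_recon_volume(vol, "perspective", z_planes_mm, geom)
}

#' Resample a perspective volume onto a Cartesian grid
#'
#' The fixed (x, y) grid equals the detector pixel grid in world millimeters;
#' the mapping is the identity at the detector plane (z = 0) and a pure
#' in-plane scaling by `(SID - z)/SID` elsewhere. Bilinear interpolation per
#' slice; points outside the perspective field of view are set to 0.
#'
#' @param vol perspective `recon_volume`.
#' @return Cartesian `recon_volume` of the same shape.
#' @export
resample_cartesian <- function(vol) {
  stopifnot(inherits(vol, "recon_volume"))
  if (vol$coordinate_system != "perspective") {
    tb_stop("resample_cartesian expects a perspective volume")
  }
  geom <- vol$geometry
  sid <- geom$source_to_detector_mm
  ax <- detector_axes(geom)
  nr <- length(ax$y); nc <- length(ax$x)
  U <- matrix(ax$x, nr, nc, byrow = TRUE)
  V <- matrix(ax$y, nr, nc)
  out <- vol
  for (zi in seq_along(vol$slice_heights_mm)) {
    z <- vol$slice_heights_mm[zi]
    m <- sid / (sid - z)
    # world (x,y) = detector grid; perspective index coordinate = x * M(z)
    bi <- bilinear_view(vol$slices[, , zi], U * m, V * m, ax)
    out$slices[, , zi] <- bi$val
  }
  out$coordinate_system <- "cartesian"
  out
}

#' Merge native slices into thicker slabs
#'
#' `mode = "mean"` averages constituent slices. `mode =
#' "contrast_preserving"` blends the mean with the signed extremum (the
#' constituent value deviating most from the slab mean, per pixel):
#' `(1 - lambda) * mean + lambda * extremum`, preserving the contrast of
#' small high-contrast objects such as microcalcifications in thick slabs.
#'
#' @param vol a `recon_volume`.
#' @param out_thickness_mm slab thickness, `>= slice_spacing_mm`.
#' @param mode `"contrast_preserving"` (default) or `"mean"`.
#' @param lambda_blend blend fraction in \[0, 1\] (default 0.5).
#' @return slab `recon_volume`.
#' @export
merge_slabs <- function(vol, out_thickness_mm, mode = "contrast_preserving",
                        lambda_blend = 0.5) {
  stopifnot(inherits(vol, "recon_volume"))
  if (!mode %in% c("contrast_preserving", "mean")) {
    tb_stop("unknown mode '", mode, "'")
  }
  sp <- vol$slice_spacing_mm
  if (is.na(sp)) sp <- out_thickness_mm
  if (out_thickness_mm < sp) tb_stop("out_thickness_mm must be >= slice spacing")
  per <- max(1L, round(out_thickness_mm / sp))
  nz <- dim(vol$slices)[3L]
  starts <- seq(1L, nz, by = per)
  slabs <- array(0, dim = c(dim(vol$slices)[1:2], length(starts)))
  hts <- numeric(length(starts))
  for (g in seq_along(starts)) {
    idx <- starts[g]:min(starts[g] + per - 1L, nz)
    sub <- vol$slices[, , idx, drop = FALSE]
    m <- apply(sub, c(1L, 2L), mean)
    if (mode == "contrast_preserving" && length(idx) > 1L && lambda_blend > 0) {
      best <- sub[, , 1L]; bdev <- abs(best - m)
      for (k in seq_along(idx)[-1L]) {
        s <- sub[, , k]; d <- abs(s - m)
        upd <- d > bdev
        best[upd] <- s[upd]; bdev[upd] <- d[upd]
      }
      slabs[, , g] <- (1 - lambda_blend) * m + lambda_blend * best
    } else {
      slabs[, , g] <- m
    }
    hts[g] <- mean(vol$slice_heights_mm[idx])
  }
  new_recon_volume(slabs, vol$coordinate_system, hts, vol$geometry,
                   slice_thickness_mm = out_thickness_mm,
                   slice_spacing_mm = if (length(hts) > 1L)
                     hts[2L] - hts[1L] else out_thickness_mm)
}
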