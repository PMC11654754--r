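#' Effective MTF from a tilted-wire projection stack
#'
#' Per view, the wire's line-spread function (LSF) is extracted by projecting
#' pixel offsets onto the wire normal (the small in-plane tilt provides
#' sub-pixel phase diversity), binned into `bin_px`-pixel sub-bins, Fourier
#' transformed, and normalized to 1 at zero frequency; curves are averaged
#' across all views and reported in the tube-travel direction.
#'
#' Frequency convention: the detector-plane frequency axis is divided by the
#' magnification `M(h)` at the wire height, i.e. the curve is referenced to
#' the plane of the wire; an object-plane frequency `f` on this axis
#' corresponds to detector frequency `f * M(h)`. The same convention is used
#' for every setting compared, so FFS-on/off and height comparisons are
#' internally consistent.
#'
#' @param stack wire `projection_stack` (intensity or log domain).
#' @param geom geometry (defaults to the stack's).
#' @param wire_height_mm wire height above the detector (mm).
#' @param wire_tilt_deg in-plane tilt used when building the phantom.
#' @param bin_px sub-pixel bin width in pixels (default 0.1).
#' @param window_mm half-width of the LSF window around the wire (default 3).
#' @param f_max_lpmm cap on reported frequencies (default: detector Nyquist
#'   on the rescaled axis).
#' @return object of class `mtf_curve`: `frequencies_lpmm`, `modulation`,
#'   `height_mm`, `direction`, `n_views_averaged`.
#' @export
emtf_from_wire <- function(stack, geom = stack$geometry, wire_height_mm,
                           wire_tilt_deg, bin_px = 0.1, window_mm = 3,
                           f_max_lpmm = NULL) {
  stopifnot(inherits(stack, "projection_stack"))
  pitch <- geom$detector_pixel_pitch_mm
  imgs <- if (stack$is_log_normalized) stack$images else {
    -log(pmax(stack$images, 1e-9 * stack$ref_signal) / stack$ref_signal)
  }
  d <- dim(imgs)
  ax <- detector_axes(geom)
  binw <- bin_px * pitch
  nbin <- 2L * round(window_mm / binw)
  edges <- (seq_len(nbin + 1L) - 1L - nbin / 2) * binw
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  mtf_sum <- NULL
  for (k in seq_len(d[3L])) {
    img <- imgs[, , k]
    if (max(img) < max(10 * mad(img), 1e-6)) {
      tb_stop("wire not detected in view ", k, " (peak below noise floor)")
    }
    # wire line fit: per-row intensity centroid around the row maximum
    rows <- seq_len(d[1L])
    cx <- rep(NA_real_, d[1L])
    for (i in rows) {
      j0 <- which.max(img[i, ])
      win <- max(1L, j0 - 25L):min(d[2L], j0 + 25L)
      w <- pmax(img[i, win], 0)
      if (sum(w) <= 0) next
      cx[i] <- sum(w * ax$x[win]) / sum(w)
    }
    ok <- !is.na(cx)
    fit <- stats::lm.fit(cbind(1, ax$y[ok]), cx[ok])
    a <- fit$coefficients[1L]; b <- fit$coefficients[2L]
    # signed perpendicular distance of every pixel to the wire line
    X <- matrix(ax$x, d[1L], d[2L], byrow = TRUE)
    Y <- matrix(ax$y, d[1L], d[2L])
    dist <- (X - a - b * Y) / sqrt(1 + b^2)
    sel <- abs(dist) <= window_mm
    bin <- findInterval(dist[sel], edges, all.inside = TRUE)
    lsf <- vapply(seq_len(nbin), function(bb) {
      v <- img[sel][bin == bb]
      if (length(v)) mean(v) else NA_real_
    }, 0)
    miss <- is.na(lsf)
    if (any(miss)) {
      lsf[miss] <- approx(centers[!miss], lsf[!miss], xout = centers[miss],
                          rule = 2)$y
    }
    # linear detrend using the LSF tails
    tails <- abs(centers) > 0.7 * window_mm
    tf <- stats::lm.fit(cbind(1, centers[tails]), lsf[tails])
    lsf <- lsf - (tf$coefficients[1L] + tf$coefficients[2L] * centers)
    mt <- Mod(fft(lsf))
    mtf_sum <- if (is.null(mtf_sum)) mt else mtf_sum + mt
  }
  mtf <- mtf_sum / d[3L]
  if (mtf[1L] <= 0) tb_stop("degenerate LSF: zero area")
  mtf <- mtf / mtf[1L]
  freq_det <- (seq_len(nbin) - 1L) / (nbin * binw)
  m <- magnification(geom, wire_height_mm)
  freq <- freq_det / m
  fcap <- f_max_lpmm %||% (1 / (2 * pitch) / m)
  keep <- freq <= fcap + 1e-9
  structure(list(frequencies_lpmm = freq[keep], modulation = mtf[keep],
                 height_mm = wire_height_mm, direction = "tube_travel",
                 n_views_averaged = d[3L]),
            class = "mtf_curve")
}

#' @export
print.mtf_curve <- function(x, ...) {
  probe <- c(1, 2, 3, 4, 5)
  v <- approx(x$frequencies_lpmm, x$modulation, xout = probe, rule = 2)$y
  cat(sprintf("<mtf_curve> height %g mm, %s, %d views\n",
              x$height_mm, x$direction, x$n_views_averaged))
  cat(paste(sprintf("  %g lp/mm: %.3f", probe, v), collapse = "\n"), "\n")
  invisible(x)
}

#' Interpolate an MTF curve at given frequencies
#' @param curve an `mtf_curve`.
#' @param f_lpmm frequencies (lp/mm).
#' @export
mtf_at <- function(curve, f_lpmm) {
  approx(curve$frequencies_lpmm, curve$modulation, xout = f_lpmm, rule = 2)$y
}

# perspective in-plane index (row, col) of a world point, via the central ray
perspective_index <- function(geom, position_mm) {
  sid <- geom$source_to_detector_mm
  m <- sid / (sid - position_mm[3L])
  ax <- detector_axes(geom)
  pitch <- geom$detector_pixel_pitch_mm
  c(row = (position_mm[2L] * m - ax$y[1L]) / pitch + 1,
    col = (position_mm[1L] * m - ax$x[1L]) / pitch + 1)
}

#' Artifact metrics for a clip reconstruction pair
#'
#' Quantifies the two artifact families of large high-contrast objects:
#' (a) out-of-plane bright-trace energy, the mean positive excess over local
#' background inside the clip footprint (dilated to twice its size) in
#' slices at least `exclude_mm` from the clip plane; (b) in-plane shadow
#' depth, background minus the minimum in an annulus around the clip at its
#' focus slice. Both are background-relative, hence invariant to adding a
#' constant. Ratios AR/base < 1 indicate artifact suppression.
#'
#' @param vol_ar artifact-reduced `recon_volume`.
#' @param vol_base baseline `recon_volume` from the same projections.
#' @param clip_spec the [insert_spec()] of the clip.
#' @param exclude_mm out-of-plane distance threshold (default 5 mm).
#' @return list with `bright_trace` and `shadow_depth` records (`ar`,
#'   `base`, `ratio`) and the footprint used.
#' @export
artifact_metrics <- function(vol_ar, vol_base, clip_spec, exclude_mm = 5) {
  stopifnot(inherits(vol_ar, "recon_volume"), inherits(vol_base, "recon_volume"))
  if (!identical(dim(vol_ar$slices), dim(vol_base$slices)) ||
      !isTRUE(all.equal(vol_ar$slice_heights_mm, vol_base$slice_heights_mm))) {
    tb_stop("volumes are misaligned")
  }
  geom <- vol_ar$geometry
  d <- dim(vol_ar$slices)
  ctr <- perspective_index(geom, clip_spec$position_mm)
  m <- magnification(geom, clip_spec$position_mm[3L])
  pitch <- geom$detector_pixel_pitch_mm
  half_px <- clip_spec$size_mm[1:2] * m / pitch / 2   # (x->col, y->row)
  R <- matrix(seq_len(d[1L]), d[1L], d[2L])
  C <- matrix(seq_len(d[2L]), d[1L], d[2L], byrow = TRUE)
  inbox <- function(fac) {
    abs(C - ctr["col"]) <= half_px[1L] * fac &
      abs(R - ctr["row"]) <= half_px[2L] * fac
  }
  foot <- inbox(2)                       # clip footprint dilated x2
  ring <- inbox(4) & !foot               # local background ring
  annulus <- inbox(3) & !inbox(1)        # in-plane shadow annulus
  z <- vol_ar$slice_heights_mm
  zi_focus <- which.min(abs(z - clip_spec$position_mm[3L]))
  far <- which(abs(z - clip_spec$position_mm[3L]) >= exclude_mm)
  trace_energy <- function(vol) {
    if (!length(far)) return(0)
    mean(vapply(far, function(zi) {
      s <- vol$slices[, , zi]
      bg <- median(s[ring])
      mean(pmax(s[foot] - bg, 0))
    }, 0))
  }
  shadow_depth <- function(vol) {
    s <- vol$slices[, , zi_focus]
    bg <- median(s[ring])
    bg - min(s[annulus])
  }
  bt_ar <- trace_energy(vol_ar); bt_b <- trace_energy(vol_base)
  sdp_ar <- shadow_depth(vol_ar); sdp_b <- shadow_depth(vol_base)
  list(bright_trace = list(ar = bt_ar, base = bt_b,
                           ratio = if (bt_b != 0) bt_ar / bt_b else 1),
       shadow_depth = list(ar = sdp_ar, base = sdp_b,
                           ratio = if (sdp_b != 0) sdp_ar / sdp_b else 1),
       focus_slice = zi_focus, footprint = foot)
}

#' Region-of-interest contrast-to-noise ratio
#'
#' `CNR = |mean(obj) - mean(bg)| / sd(bg)` over two disjoint ROIs of at
#' least 25 pixels each.
#'
#' @param image 2-D matrix (slice or SM).
#' @param obj_roi,bg_roi logical masks over `image`.
#' @return dimensionless CNR.
#' @export
cnr_roi <- function(image, obj_roi, bg_roi) {
  if (sum(obj_roi) < 25 || sum(bg_roi) < 25) tb_stop("each ROI needs >= 25 px")
  if (any(obj_roi & bg_roi)) tb_stop("ROIs must be disjoint")
  s <- sd(image[bg_roi])
  if (!is.finite(s) || s == 0) tb_stop("degenerate background sd")
  abs(mean(image[obj_roi]) - mean(image[bg_roi])) / s
}
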