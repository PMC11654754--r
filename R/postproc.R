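# Gaussian blur along matrix columns via FFT; sigma in pixels. Zero-padded
# (no wraparound) and renormalized by the blurred indicator, so the mean is
# preserved and constants are exact up to the border.
blur_axis <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  n <- nrow(mat)
  kr <- min(ceiling(4 * sigma), 4 * n)
  npad <- n + 2L * kr
  idx <- 0:(npad - 1)
  off <- pmin(idx, npad - idx)          # circular distance from 0
  k <- exp(-0.5 * (off / sigma)^2)
  k[off > kr] <- 0
  k <- k / sum(k)
  kf <- fft(k)
  P <- rbind(mat, matrix(0, npad - n, ncol(mat)))
  out <- Re(mvfft(mvfft(P) * kf, inverse = TRUE))[seq_len(n), ,
                                                  drop = FALSE] / npad
  ones <- c(rep(1, n), rep(0, npad - n))
  norm <- Re(fft(fft(ones) * kf, inverse = TRUE))[seq_len(n)] / npad
  out / norm
}

gauss_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  t(blur_axis(t(blur_axis(img, sigma_px)), sigma_px))
}

#' Flavoring configuration
#'
#' @param n_bands number of octave frequency bands (>= 2; default 4).
#' @param band_gains per-band multipliers (finest first; default all 1).
#' @param overshoot_clamp fraction in \[0, 1\] that negative fine-band
#'   excursions next to high-contrast edges are scaled by; `NULL` disables
#'   clamping.
#' @param baseline_sigma_mm low-pass scale of the thickness-equalization
#'   baseline (default 20 mm).
#' @param edge_k edge detection threshold in robust sigmas of the band
#'   (default 4).
#' @param n_clamp_bands how many of the finest bands are clamped (default 2).
#' @return list of class `flavor_config`.
#' @export
flavor_config <- function(n_bands = 4L, band_gains = rep(1, n_bands),
                          overshoot_clamp = NULL, baseline_sigma_mm = 20,
                          edge_k = 4, n_clamp_bands = 2L) {
  if (n_bands < 2L) tb_stop("n_bands must be >= 2")
  if (length(band_gains) != n_bands) tb_stop("need one gain per band")
  if (any(band_gains <= 0)) tb_stop("band gains must be > 0")
  if (!is.null(overshoot_clamp) &&
      (overshoot_clamp < 0 || overshoot_clamp > 1)) {
    tb_stop("overshoot_clamp must lie in [0, 1]")
  }
  structure(list(n_bands = as.integer(n_bands), band_gains = band_gains,
                 overshoot_clamp = overshoot_clamp,
                 baseline_sigma_mm = baseline_sigma_mm, edge_k = edge_k,
                 n_clamp_bands = as.integer(n_clamp_bands)),
            class = "flavor_config")
}

#' Baseline (breast-thickness) equalization
#'
#' Step one of flavoring: removes widespread gray-level variation caused by
#' breast thickness/density differences, particularly at the breast border.
#' Per slice, a heavy low-pass baseline (Gaussian scale `baseline_sigma_mm`,
#' computed within the breast mask by normalized convolution so the border
#' does not bleed) is subtracted and the masked mean restored; pixels outside
#' the mask are untouched.
#'
#' @param vol a `recon_volume`.
#' @param breast_mask logical matrix (rows x cols) marking the breast; must
#'   be nonempty.
#' @param baseline_sigma_mm Gaussian scale in mm (default 20).
#' @return the equalized `recon_volume`.
#' @export
equalize_baseline <- function(vol, breast_mask = NULL,
                              baseline_sigma_mm = 20) {
  stopifnot(inherits(vol, "recon_volume"))
  d <- dim(vol$slices)
  if (is.null(breast_mask)) breast_mask <- matrix(TRUE, d[1L], d[2L])
  if (!any(breast_mask)) tb_stop("empty breast mask")
  if (baseline_sigma_mm <= 0) tb_stop("baseline_sigma_mm must be > 0")
  sigma_px <- baseline_sigma_mm / vol$geometry$detector_pixel_pitch_mm
  m <- breast_mask * 1.0
  bm <- gauss_blur(m, sigma_px)
  out <- vol
  for (zi in seq_len(d[3L])) {
    img <- vol$slices[, , zi]
    base <- gauss_blur(img * m, sigma_px) / pmax(bm, 1e-12)
    mu <- mean(img[breast_mask])
    res <- img
    res[breast_mask] <- img[breast_mask] - base[breast_mask] + mu
    out$slices[, , zi] <- res
  }
  out
}

# perfect-reconstruction octave decomposition: band b = G_{s[b-1]} - G_{s[b]}
# with s = (0, 1, 2, 4, ...) pixels; residual = G_{s[n]}.
decompose_bands <- function(img, n_bands) {
  sigmas <- c(0, 2^(seq_len(n_bands) - 1))
  g_prev <- img
  bands <- vector("list", n_bands)
  for (b in seq_len(n_bands)) {
    g <- gauss_blur(img, sigmas[b + 1L])
    bands[[b]] <- g_prev - g
    g_prev <- g
  }
  list(bands = bands, residual = g_prev)
}

#' Multifrequency ("flavoring") enhancement of DBT slices
#'
#' Step two of flavoring: each slice is decomposed into `n_bands` octave
#' bands plus a residual (a difference-of-Gaussians pyramid at full
#' resolution, exact reconstruction by summation); band `b` is scaled by
#' `band_gains[b]`. Dark overshoot artifacts are suppressed by scaling
#' negative excursions of the finest bands adjacent to high-contrast edges
#' by `overshoot_clamp`. With all gains 1 and clamping disabled the operator
#' is the identity to machine precision.
#'
#' @param vol a `recon_volume`.
#' @param cfg a [flavor_config()].
#' @return the enhanced `recon_volume`.
#' @export
multiband_enhance <- function(vol, cfg = flavor_config()) {
  stopifnot(inherits(vol, "recon_volume"), inherits(cfg, "flavor_config"))
  out <- vol
  for (zi in seq_len(dim(vol$slices)[3L])) {
    img <- vol$slices[, , zi]
    dec <- decompose_bands(img, cfg$n_bands)
    acc <- dec$residual
    for (b in seq_len(cfg$n_bands)) {
      band <- dec$bands[[b]]
      if (!is.null(cfg$overshoot_clamp) && b <= cfg$n_clamp_bands) {
        sc <- mad(band)
        if (sc > 0) {
          edges <- binary_dilate(abs(band) > cfg$edge_k * sc, 2)
          sel <- edges & band < 0
          band[sel] <- band[sel] * cfg$overshoot_clamp
        }
      }
      acc <- acc + cfg$band_gains[b] * band
    }
    out$slices[, , zi] <- acc
  }
  out
}

#' Noise model for physics-constrained denoising
#'
#' @param gain photons per signal unit (> 0).
#' @param clamp_k plausibility bound in multiples of the physical quantum
#'   noise sigma `sqrt(value / gain)` (default 2; 0 forbids any subtraction).
#' @param denoiser `"vst_soft"` (variance-stabilizing transform + fine-band
#'   soft threshold; the default, no trained weights) or a function
#'   `(image_matrix, gain) -> denoised matrix` plugging in any estimator.
#' @param vst_threshold soft threshold in VST noise sigmas (default 2).
#' @return list of class `noise_model`.
#' @export
noise_model <- function(gain, clamp_k = 2, denoiser = "vst_soft",
                        vst_threshold = 2) {
  if (gain <= 0) tb_stop("gain must be > 0")
  if (clamp_k < 0) tb_stop("clamp_k must be >= 0")
  structure(list(gain = gain, clamp_k = clamp_k, denoiser = denoiser,
                 vst_threshold = vst_threshold),
            class = "noise_model")
}

vst_soft_denoise <- function(img, gain, thr = 2, sigma_px = 1) {
  # Anscombe transform: unit noise variance in the transformed domain
  a <- 2 * sqrt(pmax(img * gain + 3 / 8, 0))
  low <- gauss_blur(a, sigma_px)
  fine <- a - low
  fine <- sign(fine) * pmax(abs(fine) - thr, 0)
  ad <- low + fine
  # first-order unbiased inverse Anscombe (-1/8, not -3/8): keeps flat-field
  # means within 0.1%
  pmax((ad / 2)^2 - 1 / 8, 0) / gain
}

#' Physics-constrained denoising of projection images
#'
#' A pluggable estimator produces a per-pixel noise estimate; a plausibility
#' filter then clamps that estimate to `± clamp_k * sigma_phys`, with
#' `sigma_phys = sqrt(value / gain)` the quantum-noise prediction, before it
#' is subtracted. The subtraction can therefore never exceed what Poisson
#' statistics makes plausible: statistically relevant structure is not
#' removed and pseudo-structures cannot be hallucinated beyond the bound.
#' `clamp_k = 0` is the identity.
#'
#' @param stack intensity-domain `projection_stack` with nonnegative values.
#' @param nm a [noise_model()].
#' @return the denoised stack.
#' @export
constrained_denoise <- function(stack, nm) {
  stopifnot(inherits(stack, "projection_stack"), inherits(nm, "noise_model"))
  if (stack$is_log_normalized) tb_stop("denoise operates on the intensity domain")
  if (any(stack$images < 0)) tb_stop("negative pixel values")
  out <- stack
  est <- if (is.function(nm$denoiser)) nm$denoiser else
    function(img, gain) vst_soft_denoise(img, gain, nm$vst_threshold)
  for (k in seq_len(dim(stack$images)[3L])) {
    img <- stack$images[, , k]
    if (nm$clamp_k == 0) next
    nhat <- img - est(img, nm$gain)
    bound <- nm$clamp_k * sqrt(img / nm$gain)
    nhat <- pmin(pmax(nhat, -bound), bound)
    out$images[, , k] <- img - nhat
  }
  out$seed_record <- c(stack$seed_record,
                       list(denoise = list(clamp_k = nm$clamp_k,
                                           gain = nm$gain)))
  out
}

#' Synthesize a 2-D mammogram (SM) from projections and the DBT stack
#'
#' Simplified SM: `background + detail_weight * detail`. The background is a
#' weighted mean of the central `2k + 1` denoised projections, each mapped to
#' central-view coordinates through a reference plane at the volume's
#' mid-height (triangular view weights); the detail term is the per-pixel
#' signed extremum across slices of the fine band of the perspective volume,
#' which shares in-plane indexing with the central projection by
#' construction. Both terms are computed in the attenuation (log) domain.
#'
#' This is a property-level stand-in for product SM algorithms: calcification
#' positions and contrast behave correctly; appearance is not modeled.
#'
#' @param stack denoised `projection_stack` (intensity or log domain).
#' @param vol perspective `recon_volume` from the same scan.
#' @param k half-width of the central view window (default 2).
#' @param detail_weight blend weight of the stack detail term (default 0.5).
#' @param fine_sigma_px fine-band scale in pixels (default 1).
#' @return matrix (rows x cols) of class `synthetic_mammogram`.
#' @export
synthesize_sm <- function(stack, vol, k = 2L, detail_weight = 0.5,
                          fine_sigma_px = 1) {
  stopifnot(inherits(stack, "projection_stack"), inherits(vol, "recon_volume"))
  if (vol$coordinate_system != "perspective") {
    tb_stop("synthesize_sm requires a perspective volume; ",
            "pass the reconstruction before resample_cartesian()")
  }
  geom <- stack$geometry
  n <- dim(stack$images)[3L]
  cidx <- (n + 1L) %/% 2L
  if (k < 0 || cidx - k < 1L || cidx + k > n) tb_stop("k too large for stack")
  imgs <- if (stack$is_log_normalized) stack$images else {
    i0 <- stack$ref_signal
    -log(pmax(stack$images, 1e-9 * i0) / i0)
  }
  ax <- detector_axes(geom)
  nr <- length(ax$y); nc <- length(ax$x)
  U <- matrix(ax$x, nr, nc, byrow = TRUE)
  V <- matrix(ax$y, nr, nc)
  sid <- geom$source_to_detector_mm
  zref <- mean(vol$slice_heights_mm)
  scale <- (sid - zref) / sid
  X <- U * scale; Y <- V * scale
  acc <- matrix(0, nr, nc); wsum <- 0
  for (j in (cidx - k):(cidx + k)) {
    w <- k + 1 - abs(j - cidx)
    if (j == cidx) {
      smp <- imgs[, , j]
    } else {
      s <- source_position(geom, j - 1L, 0)
      t <- s[3L] / (s[3L] - zref)
      smp <- bilinear_view(imgs[, , j], s[1L] + t * (X - s[1L]),
                           s[2L] + t * (Y - s[2L]), ax)$val
    }
    acc <- acc + w * smp
    wsum <- wsum + w
  }
  background <- acc / wsum
  detail <- matrix(0, nr, nc); bdev <- matrix(-1, nr, nc)
  if (detail_weight > 0) {
    for (zi in seq_len(dim(vol$slices)[3L])) {
      fine <- vol$slices[, , zi] - gauss_blur(vol$slices[, , zi], fine_sigma_px)
      upd <- abs(fine) > bdev
      detail[upd] <- fine[upd]
      bdev[upd] <- abs(fine[upd])
    }
  }
  structure(background + detail_weight * detail,
            class = c("synthetic_mammogram", "matrix", "array"))
}
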