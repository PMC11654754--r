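disk_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(i = -r:r, j = -r:r)
  g <- g[g$i^2 + g$j^2 <= radius^2 + 1e-9, ]
  as.matrix(g)
}

gray_open <- function(img, radius) {
  off <- disk_offsets(radius)
  cpp_gray_morph(cpp_gray_morph(img, off, 0L), off, 1L)
}

binary_dilate <- function(mask, radius) {
  if (radius <= 0) return(mask)
  off <- disk_offsets(radius)
  cpp_gray_morph(mask * 1.0, off, 1L) > 0.5
}

#' Segment large high-contrast objects in the projections
#'
#' Per view: the background is estimated by grayscale morphological opening
#' with a disk; pixels whose residual (projection minus background) exceeds
#' `k_threshold` robust (MAD-based) scales are candidate object shadows.
#' Components smaller than `min_size_px` are dropped (very small
#' high-contrast elements do not create reconstruction artifacts) and
#' components larger than `max_size_frac` of the view are dropped (implants
#' are deliberately not segmented, to avoid over-correction). Surviving
#' components are dilated by `dilation_px` as a conservative margin.
#'
#' @param stack log-normalized `projection_stack`.
#' @param struct_radius_px opening-disk radius in pixels (default 15).
#' @param k_threshold threshold in robust sigmas of the residual (default 4).
#' @param min_size_px minimum component size (default 5 px).
#' @param max_size_frac maximum component size as a fraction of the view
#'   area (default 0.25).
#' @param dilation_px mask dilation radius (default 2).
#' @return object of class `object_masks`: `masks` (logical array rows x
#'   cols x views), `component_sizes` (list per view), `dilation_px`.
#' @export
segment_objects <- function(stack, struct_radius_px = 15, k_threshold = 4,
                            min_size_px = 5, max_size_frac = 0.25,
                            dilation_px = 2) {
  stopifnot(inherits(stack, "projection_stack"))
  if (!stack$is_log_normalized) tb_stop("segment_objects needs a log-normalized stack")
  d <- dim(stack$images)
  masks <- array(FALSE, dim = d)
  core <- array(FALSE, dim = d)
  bg <- array(0, dim = d)
  sizes <- vector("list", d[3L])
  max_size_px <- max_size_frac * d[1L] * d[2L]
  for (k in seq_len(d[3L])) {
    img <- stack$images[, , k]
    b <- gray_open(img, struct_radius_px)
    res <- img - b
    scale <- mad(res, center = median(res))
    if (scale <= 0) scale <- sd(res)
    m <- res > median(res) + k_threshold * max(scale, 1e-12)
    if (any(m)) {
      lab <- cpp_label_components(m)
      ncomp <- attr(lab, "n_components")
      if (ncomp > 0) {
        cs <- tabulate(lab[lab > 0], nbins = ncomp)
        keep <- which(cs >= min_size_px & cs <= max_size_px)
        m <- array(lab %in% keep, dim = dim(m))
        sizes[[k]] <- cs[keep]
      }
      core[, , k] <- m
      m <- binary_dilate(m, dilation_px)
    }
    if (mean(m) > 0.5) {
      tb_stop("view ", k, ": more than half the view segmented; ",
              "check struct_radius_px / k_threshold configuration")
    }
    masks[, , k] <- m
    bg[, , k] <- b
  }
  structure(list(masks = masks, core = core, background = bg,
                 component_sizes = sizes, dilation_px = dilation_px),
            class = "object_masks")
}

#' Virtually remove segmented objects from the projections
#'
#' Masked pixels are replaced by the morphological background estimate
#' (inpainting by background fill); unmasked pixels are untouched. The
#' result is the source of the object-removed filtered projections (rP).
#'
#' @param stack log-normalized `projection_stack`.
#' @param masks an [segment_objects()] result aligned with `stack`.
#' @return the object-removed `projection_stack`.
#' @export
remove_objects <- function(stack, masks) {
  stopifnot(inherits(stack, "projection_stack"),
            inherits(masks, "object_masks"))
  if (!identical(dim(stack$images), dim(masks$masks))) {
    tb_stop("mask / stack shape mismatch")
  }
  out <- stack
  sel <- masks$masks
  out$images[sel] <- masks$background[sel]
  out
}

#' Reconstruction with selective (mask-driven) backprojection
#'
#' Identical to [backproject_perspective()] except that, for each
#' (voxel, view) sample whose detector location falls inside that view's
#' object mask, the sample is read from the ramp-filtered object-removed
#' projections (rP) instead of the originals (oP). Views are never dropped,
#' and voxels whose rays avoid every mask are bit-identical to the standard
#' reconstruction.
#'
#' Voxels masked in at least 90% of their contributing views (the
#' `object_consensus` attribute of `masks`, default 0.9) are the
#' high-contrast object itself, in focus: these keep the original data, so
#' that artifact reduction removes the object's artifacts but never the
#' object.
#'
#' @param fp [ramp_filter()] result carrying both `oP` and `rP`.
#' @param masks an [segment_objects()] result.
#' @param geom geometry.
#' @param z_planes_mm slice heights.
#' @return perspective `recon_volume`.
#' @export
masked_backproject <- function(fp, masks, geom = fp$geometry, z_planes_mm) {
  stopifnot(inherits(masks, "object_masks"))
  if (is.null(fp$rP)) tb_stop("fp must carry rP: call ramp_filter(stack, rP = removed)")
  if (!identical(dim(fp$oP), dim(masks$masks))) {
    tb_stop("mask / projection shape mismatch")
  }
  backproject_perspective(fp, geom, z_planes_mm, masks = masks)
}
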