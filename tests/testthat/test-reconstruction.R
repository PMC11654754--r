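fake_log_stack <- function(imgs, geom) {
  st <- tomobreast:::new_projection_stack(imgs, geom, ref_signal = 1,
                                          mode = "synthetic")
  st$is_log_normalized <- TRUE
  st
}

test_that("ramp filter: DC removal, impulse kernel oracle, linearity", {
  geom <- coarse_geom(rows = 4L, cols = 64L, pitch = 0.1, n_projections = 1L)
  const <- array(3, dim = c(4L, 64L, 1L))
  fc <- ramp_filter(fake_log_stack(const, geom), window = "none")
  expect_lt(max(abs(fc$oP)), 1e-6)
  # impulse response equals the directly computed discrete ramp kernel
  imp <- array(0, dim = c(4L, 64L, 1L)); imp[2L, 33L, 1L] <- 1
  fi <- ramp_filter(fake_log_stack(imp, geom), window = "none")
  npad <- 128L                                     # 2 x next power of two
  f <- c(seq(0, 64), seq(-63, -1)) / (npad * 0.1)
  kern <- Re(fft(abs(f), inverse = TRUE)) / npad   # oracle kernel
  expect_equal(fi$oP[2L, , 1L], kern[c(97:128, 1:32)], tolerance = 1e-9)
  # linearity
  set.seed(9)
  a <- array(rnorm(4 * 64), dim = c(4L, 64L, 1L))
  b <- array(rnorm(4 * 64), dim = c(4L, 64L, 1L))
  fa <- ramp_filter(fake_log_stack(a, geom), window = "hann")$oP
  fb <- ramp_filter(fake_log_stack(b, geom), window = "hann")$oP
  fab <- ramp_filter(fake_log_stack(a + b, geom), window = "hann")$oP
  expect_equal(fab, fa + fb, tolerance = 1e-10)
  expect_error(ramp_filter(fake_log_stack(a, geom), window = "boxcar"),
               "window")
})

test_that("perspective backprojection matches the brute-force oracle", {
  geom <- coarse_geom(rows = 12L, cols = 16L, pitch = 0.5,
                      n_projections = 7L)
  set.seed(17)
  fp <- structure(list(oP = array(rnorm(12 * 16 * 7), dim = c(12L, 16L, 7L)),
                       rP = NULL, filter_window = "none", geometry = geom),
                  class = "filtered_projections")
  z <- c(8, 20, 33, 47)
  got <- backproject_perspective(fp, geom, z)
  ref <- oracle_backproject(fp, geom, z)
  rng <- diff(range(ref))
  expect_lt(max(abs(got$slices - ref)), 1e-6 * rng)
})

test_that("single view at a near-zero plane reproduces the projection", {
  geom <- coarse_geom(rows = 16L, cols = 20L, pitch = 0.5,
                      n_projections = 1L)
  set.seed(2)
  img <- array(rnorm(16 * 20), dim = c(16L, 20L, 1L))
  fp <- structure(list(oP = img, rP = NULL, filter_window = "none",
                       geometry = geom), class = "filtered_projections")
  vol <- backproject_perspective(fp, geom, 1e-6)
  expect_equal(vol$slices[, , 1L], img[, , 1L], tolerance = 1e-6)
})

test_that("point structure stays static in-plane in perspective coords", {
  ce <- calc_experiment()
  vol <- ce$vol
  pred <- tomobreast:::perspective_index(ce$geom, ce$calc$position_mm)
  # row argmax is identical in every slice (no source motion along y)
  rows <- apply(vol$slices, 3L, function(s)
    which(s == max(s), arr.ind = TRUE)[1L, 1L])
  expect_true(all(rows == rows[1L]))
  expect_lt(abs(rows[1L] - pred["row"]), 1.5)
  # the out-of-focus trace of the point is a comb of view spikes; its
  # (positive-part) centroid stays on the central-ray column in every slice
  cols <- round(pred["col"]) + (-15:15)
  centroid <- function(s) {
    prof <- pmax(colSums(pmax(s[rows[1L] + (-2:2), cols], 0)), 0)
    sum(prof * cols) / sum(prof)
  }
  cen <- apply(vol$slices, 3L, centroid)
  z <- vol$slice_heights_mm
  # static location: averaged over the stack the trace center sits on the
  # central-ray column (discrete view spikes jitter, but do not move), and
  # around the focus it is on that column to within a pixel
  expect_lt(abs(mean(cen) - pred["col"]), 1)
  focus <- abs(z - 30) <= 2.5
  expect_lt(max(abs(cen[focus] - pred["col"])), 1.2)
  # a Cartesian volume places the structure at its demagnified world
  # position instead, offset from the projection-domain index
  cart <- resample_cartesian(vol)
  cen_c <- apply(cart$slices, 3L, centroid)
  ax <- tomobreast:::detector_axes(ce$geom)
  pitch <- ce$geom$detector_pixel_pitch_mm
  world_col <- (ce$calc$position_mm[1L] - ax$x[1L]) / pitch + 1
  expect_gt(pred["col"] - world_col, 1.5)    # the offset is > a pixel here
  expect_lt(abs(mean(cen_c[focus]) - world_col), 0.6)
})

test_that("Cartesian resampling: constants exact, analytic map on smooth field", {
  geom <- coarse_geom(rows = 40L, cols = 48L, pitch = 0.5)
  ax <- tomobreast:::detector_axes(geom)
  sid <- 650; z <- 60
  # uniform slice stays uniform inside the perspective footprint (points
  # outside the field of view resample to 0 by design)
  u <- array(2.5, dim = c(40L, 48L, 1L))
  vu <- tomobreast:::new_recon_volume(u, "perspective", z, geom)
  ru <- resample_cartesian(vu)$slices[, , 1L]
  Uw <- matrix(ax$x, 40L, 48L, byrow = TRUE)
  Vw <- matrix(ax$y, 40L, 48L)
  infov <- abs(Uw) * sid / (sid - z) <= max(ax$x) &
    abs(Vw) * sid / (sid - z) <= max(ax$y)
  expect_equal(ru[infov], u[, , 1L][infov], tolerance = 1e-12)
  expect_true(all(ru[!infov] == 0))
  # smooth quadratic in world coordinates: compare to analytic mapping
  U <- matrix(ax$x, 40L, 48L, byrow = TRUE)
  V <- matrix(ax$y, 40L, 48L)
  scale <- (sid - z) / sid
  fworld <- function(x, y) 1 + 0.02 * x^2 + 0.01 * y^2 - 0.015 * x * y
  persp <- array(fworld(U * scale, V * scale), dim = c(40L, 48L, 1L))
  vp <- tomobreast:::new_recon_volume(persp, "perspective", z, geom)
  cart <- resample_cartesian(vp)$slices[, , 1L]
  truth <- fworld(U, V)
  # interior only: border pixels fall outside the perspective footprint
  interior <- abs(U) < max(ax$x) * scale * 0.9 & abs(V) < max(ax$y) * scale * 0.9
  err <- abs(cart - truth)[interior]
  expect_lt(max(err) / diff(range(truth)), 1e-3)
  expect_error(resample_cartesian(resample_cartesian(vp)), "perspective")
})

test_that("slab merging preserves microcalc contrast", {
  geom <- coarse_geom(rows = 20L, cols = 20L)
  set.seed(4)
  nz <- 8L
  sl <- array(rnorm(20 * 20 * nz, sd = 0.01), dim = c(20L, 20L, nz))
  sl[10L, 10L, 3L] <- sl[10L, 10L, 3L] + 1      # calc in one native slice
  vol <- tomobreast:::new_recon_volume(sl, "perspective",
                                       seq(10, 10 + nz - 1), geom)
  m0 <- merge_slabs(vol, 4, mode = "mean")
  m1 <- merge_slabs(vol, 4, lambda_blend = 0)
  expect_equal(m1$slices, m0$slices, tolerance = 1e-12)
  mc <- merge_slabs(vol, 4, lambda_blend = 0.5)
  contrast <- function(v) v$slices[10L, 10L, 1L] -
    median(v$slices[, , 1L])
  expect_gt(contrast(mc), contrast(m0))
  # single constituent slice: output equals input for any lambda
  v1 <- tomobreast:::new_recon_volume(sl[, , 3L, drop = FALSE], "perspective",
                                      12, geom)
  v1$slice_spacing_mm <- 1
  expect_equal(merge_slabs(v1, 1, lambda_blend = 0.7)$slices,
               v1$slices, tolerance = 1e-12)
  expect_error(merge_slabs(vol, 4, mode = "sharpest"), "mode")
})
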