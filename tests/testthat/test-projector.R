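test_that("air phantom projects to the unattenuated reference signal", {
  geom <- coarse_geom(rows = 16L, cols = 24L)
  ph <- build_air_phantom(c(20L, 20L, 10L), c(1, 1, 1))
  st <- forward_project(ph, geom, n_spot_samples = 2L, n_det_sub = 2L)
  expect_equal(max(abs(st$images - st$ref_signal)), 0, tolerance = 1e-9)
})

test_that("uniform PMMA slab follows Beer-Lambert with ray obliquity", {
  geom <- coarse_geom(rows = 11L, cols = 11L, pitch = 0.2)
  ph <- build_air_phantom(c(60L, 60L, 20L), c(1, 1, 2))
  ph$materials <- c("PMMA")          # whole grid becomes PMMA
  T <- 40
  st <- forward_project(ph, geom, spectrum = 20, n_spot_samples = 1L,
                        n_time_samples = 1L, n_det_sub = 1L,
                        step_mm = 0.05)
  # central view is element 13; central pixel ray is vertical. The trilinear
  # volume model tapers over the boundary half-voxel, so the hand value
  # mu * T is met at the 2% level (in the attenuation domain).
  mu <- mu_of("PMMA", 20)
  p_center <- -log(st$images[6L, 6L, 13L])
  expect_equal(p_center, mu * T, tolerance = 0.02)
  # off-center pixel: path lengthened by exactly 1/cos(incidence)
  xoff <- tomobreast:::detector_axes(geom)$x[11L]
  cosang <- 650 / sqrt(650^2 + xoff^2)
  p_edge <- -log(st$images[6L, 11L, 13L])
  expect_equal(p_edge / p_center, 1 / cosang, tolerance = 1e-3)
})

test_that("ray integrals match a brute-force dense-sampling oracle", {
  set.seed(3)
  vol <- array(runif(8 * 7 * 6), dim = c(8L, 7L, 6L))
  vox <- c(0.7, 1.1, 0.9); orig <- c(-2, -3, 0.45)
  src <- matrix(c(5, -4, 200), 1L)
  detx <- c(-3, 0, 2.5); dety <- c(-2, 1)
  got <- tomobreast:::cpp_project(as.numeric(vol), dim(vol), vox, orig, src,
                                  detx, dety, 0.1, 1L, 0.02, 1L)
  dim(got) <- c(3L, 2L)
  # the default step (half the smallest voxel) is within 3% of converged
  coarse <- tomobreast:::cpp_project(as.numeric(vol), dim(vol), vox, orig,
                                     src, detx, dety, 0.1, 1L, 0.35, 1L)
  dim(coarse) <- c(3L, 2L)
  expect_lt(max(abs(coarse - got)) / max(got), 0.03)
  tri <- function(p) {
    g <- (p - orig) / vox
    if (any(g <= -1) || any(g >= dim(vol))) return(0)
    i0 <- floor(g); f <- g - i0
    acc <- 0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      ii <- i0 + c(dx, dy, dz) + 1
      if (any(ii < 1) || any(ii > dim(vol))) next
      w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
      acc <- acc + w * vol[ii[1L], ii[2L], ii[3L]]
    }
    acc
  }
  for (i in 1:3) for (j in 1:2) {
    d <- c(detx[i], dety[j], 0)
    n <- 40000L
    ts <- (seq_len(n) - 0.5) / n
    L <- sqrt(sum((d - src[1L, ])^2))
    ref <- sum(vapply(ts, function(t) tri(src[1L, ] + t * (d - src[1L, ])),
                      0)) * L / n
    expect_equal(got[i, j], ref, tolerance = 2e-3)
  }
})

test_that("point insert parallax is consistent with the magnification model", {
  h <- 30
  geom <- coarse_geom(rows = 21L, cols = 81L, pitch = 0.4, ffs = TRUE)
  ph <- build_air_phantom(c(40L, 20L, 46L), c(0.4, 0.4, 1))
  ph <- add_insert(ph, insert_spec("microcalc_cluster", c(0, 0, h),
                                   size_mm = c(1.1, 1.1), count = 1L,
                                   density_factor = 6))
  st <- forward_project(ph, geom, n_spot_samples = 1L, n_time_samples = 1L,
                        n_det_sub = 1L)
  p <- -log(st$images / st$ref_signal)
  ax <- tomobreast:::detector_axes(geom)
  pos <- vapply(seq_len(25L), function(k) {
    img <- p[, , k]
    sum(img * matrix(ax$x, nrow(img), ncol(img), byrow = TRUE)) / sum(img)
  }, 0)
  # shadow x-position: u(k) = s_x * (1 - t) with t = s_z/(s_z - h)
  expected <- vapply(seq_len(25L) - 1L, function(k) {
    s <- source_position(geom, k, 0)
    t <- s[3L] / (s[3L] - h)
    s[1L] * (1 - t)
  }, 0)
  expect_equal(pos, expected, tolerance = 0.2)  # within half a pixel
})

test_that("FFS makes projections independent of pulse length", {
  ph <- build_air_phantom(c(30L, 10L, 10L), c(0.4, 0.4, 1))
  ph <- add_insert(ph, insert_spec("clip", c(0, 0, 5), size_mm = c(2, 2, 2)))
  g1 <- coarse_geom(rows = 12L, cols = 40L, pitch = 0.4, ffs = TRUE)
  g2 <- coarse_geom(rows = 12L, cols = 40L, pitch = 0.4, ffs = TRUE,
                    pulse_length_ms = 10)
  s1 <- forward_project(ph, g1, n_spot_samples = 1L, n_time_samples = 5L,
                        n_det_sub = 1L)
  s2 <- forward_project(ph, g2, n_spot_samples = 1L, n_time_samples = 5L,
                        n_det_sub = 1L)
  expect_identical(s1$images, s2$images)
  # without FFS the pulse sweep widens the shadow of an elevated object:
  # the intensity-deficit profile is linear in the pulse average, so motion
  # blur adds its variance to the profile's second moment
  g3 <- coarse_geom(rows = 12L, cols = 80L, pitch = 0.2, ffs = FALSE)
  g4 <- coarse_geom(rows = 12L, cols = 80L, pitch = 0.2, ffs = TRUE)
  ph2 <- build_air_phantom(c(60L, 10L, 61L), c(0.2, 0.4, 1))
  ph2 <- add_insert(ph2, insert_spec("clip", c(0, 0, 55),
                                     size_mm = c(0.8, 2, 2)))
  son <- forward_project(ph2, g4, n_spot_samples = 1L, n_time_samples = 5L,
                         n_det_sub = 5L)
  soff <- forward_project(ph2, g3, n_spot_samples = 1L, n_time_samples = 5L,
                          n_det_sub = 5L)
  w_of <- function(st) {
    prof <- colSums(1 - st$images[, , 13L] / st$ref_signal)
    x <- seq_along(prof)
    mu <- sum(prof * x) / sum(prof)
    sum(prof * (x - mu)^2) / sum(prof)
  }
  # variance gain matches the sampled-pulse sweep within 30%
  shift_px <- 4.727 * 55 / (650 - 55) / 0.2   # full-pulse sweep in pixels
  pred_gain <- shift_px^2 * 0.08              # var of the 5-point tau comb
  expect_gt(w_of(soff) - w_of(son), 0.7 * pred_gain)
  expect_lt(w_of(soff) - w_of(son), 1.3 * pred_gain)
})

test_that("Poisson noise: seeded, mean-preserving, variance consistent", {
  geom <- coarse_geom(rows = 50L, cols = 50L)
  ph <- build_air_phantom(c(10L, 10L, 5L), c(1, 1, 1))
  st <- forward_project(ph, geom, n_spot_samples = 1L,
                        n_time_samples = 1L, n_det_sub = 1L)
  n1 <- add_counting_noise(st, gain = 1e4, seed = 42L)
  n2 <- add_counting_noise(st, gain = 1e4, seed = 42L)
  expect_identical(n1$images, n2$images)
  # gain -> infinity: output approaches input
  nb <- add_counting_noise(st, gain = 1e9, seed = 1L)
  expect_lt(max(abs(nb$images - st$images) / st$images), 1e-3)
  # variance/mean of counts ~ 1 (Poisson), >= 6e4 pixels at lambda = 1e4
  counts <- n1$images * 1e4
  expect_gt(length(counts), 6e4)
  vm <- var(as.vector(counts)) / mean(counts)
  expect_gt(vm, 0.95); expect_lt(vm, 1.05)
  expect_error(add_counting_noise(st, gain = -1), "gain")
})

test_that("log normalization: air zeros, closed form, monotone in thickness", {
  geom <- coarse_geom(rows = 8L, cols = 12L)
  ph <- build_air_phantom(c(10L, 10L, 5L), c(1, 1, 1))
  st <- forward_project(ph, geom, n_spot_samples = 1L, n_time_samples = 1L,
                        n_det_sub = 1L)
  lg <- to_line_integrals(st)
  expect_equal(max(abs(lg$images)), 0, tolerance = 1e-9)
  st2 <- st; st2$images[] <- st$ref_signal * exp(-2)
  expect_equal(to_line_integrals(st2)$images[1L], 2, tolerance = 1e-12)
  expect_error(to_line_integrals(lg), "already")
  # thicker slab gives larger p everywhere
  mk <- function(T, nz) {
    p <- build_air_phantom(c(40L, 40L, nz), c(1, 1, 2))
    p$materials <- "PMMA"
    p$thickness_mm <- T
    forward_project(p, coarse_geom(rows = 8L, cols = 12L, pitch = 0.3),
                    n_spot_samples = 1L, n_time_samples = 1L, n_det_sub = 1L)
  }
  p20 <- to_line_integrals(mk(20, 10L))$images
  p40 <- to_line_integrals(mk(40, 20L))$images
  expect_true(all(p40 > p20))
})
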