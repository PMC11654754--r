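make_vol <- function(slices, geom = coarse_geom(rows = dim(slices)[1L],
                                                cols = dim(slices)[2L])) {
  tomobreast:::new_recon_volume(slices, "perspective",
                                seq_len(dim(slices)[3L]) + 9, geom)
}

test_that("baseline equalization flattens ramps, preserves texture", {
  set.seed(12)
  nr <- 60L; nc <- 80L
  geom <- coarse_geom(rows = nr, cols = nc, pitch = 0.4)
  ramp <- matrix(seq(0, 2, length.out = nc), nr, nc, byrow = TRUE)
  texture <- matrix(rnorm(nr * nc, sd = 0.1), nr, nc)
  vol <- make_vol(array(ramp + texture, dim = c(nr, nc, 1L)), geom)
  # the baseline scale must be small against the image extent (as it is on
  # full-pitch clinical grids); here 2 mm = 5 px on an 80-px slice
  eq <- equalize_baseline(vol, baseline_sigma_mm = 2)
  out <- eq$slices[, , 1L]
  # ramp amplitude reduced to < 10% (compare smoothed row means)
  prof_in <- colMeans(ramp + texture); prof_out <- colMeans(out)
  amp <- function(p) diff(range(stats::filter(p, rep(1 / 9, 9))[5:(nc - 4)]))
  expect_lt(amp(prof_out), 0.1 * amp(prof_in))
  # texture RMS preserved within 5%
  hp <- function(m) m - tomobreast:::gauss_blur(m, 1.5)
  expect_lt(abs(sd(hp(out)) / sd(hp(ramp + texture)) - 1), 0.05)
  # flat slice is (nearly) unchanged
  flat <- make_vol(array(1.7, dim = c(nr, nc, 1L)), geom)
  expect_equal(equalize_baseline(flat, baseline_sigma_mm = 2)$slices,
               flat$slices, tolerance = 1e-9)
  # mask complement untouched bit-wise
  mask <- matrix(TRUE, nr, nc); mask[, 1:10] <- FALSE
  eqm <- equalize_baseline(vol, breast_mask = mask, baseline_sigma_mm = 2)
  expect_identical(eqm$slices[, , 1L][!mask], vol$slices[, , 1L][!mask])
  expect_error(equalize_baseline(vol, breast_mask = mask & FALSE), "mask")
})

test_that("multifrequency enhancement: identity, contrast, overshoot clamp", {
  set.seed(8)
  nr <- 48L; nc <- 48L
  img <- matrix(rnorm(nr * nc, 1, 0.05), nr, nc)
  img[24L, 24L] <- img[24L, 24L] + 0.6             # calc-like spot
  vol <- make_vol(array(img, dim = c(nr, nc, 1L)))
  # identity config is a no-op to machine precision
  id <- multiband_enhance(vol, flavor_config(n_bands = 4L))
  expect_equal(id$slices, vol$slices, tolerance = 1e-10)
  # fine-band gain 2 increases calc peak contrast
  g <- flavor_config(n_bands = 4L, band_gains = c(2, 1, 1, 1))
  en <- multiband_enhance(vol, g)
  contr <- function(v) v$slices[24L, 24L, 1L] - median(v$slices[, , 1L])
  expect_gt(contr(en), contr(vol))
  # step edge: dark undershoot magnitude halved at clamp 0.5
  step <- matrix(0, nr, nc); step[, 25:48] <- 1
  vs <- make_vol(array(step, dim = c(nr, nc, 1L)))
  boost <- flavor_config(n_bands = 3L, band_gains = c(3, 1, 1))
  un <- multiband_enhance(vs, boost)
  cl <- multiband_enhance(vs, flavor_config(n_bands = 3L,
                                            band_gains = c(3, 1, 1),
                                            overshoot_clamp = 0.5))
  under_un <- min(un$slices[24L, , 1L])
  under_cl <- min(cl$slices[24L, , 1L])
  expect_lt(under_un, 0)
  expect_lte(abs(under_cl), 0.5 * abs(under_un) + 1e-9)
  expect_error(multiband_enhance(vol, flavor_config(n_bands = 3L,
                                                    band_gains = c(1, 1))),
               "gain")
})

test_that("physics-constrained denoising honors the hard bound", {
  geom <- coarse_geom(rows = 120L, cols = 120L)
  ph <- build_air_phantom(c(10L, 10L, 5L), c(1, 1, 1))
  st0 <- forward_project(ph, geom, n_spot_samples = 1L, n_time_samples = 1L,
                         n_det_sub = 1L)
  gain <- 1e4
  st <- add_counting_noise(st0, gain, seed = 77L)
  # clamp_k = 0 is the identity
  expect_identical(constrained_denoise(st, noise_model(gain, 0))$images,
                   st$images)
  nm <- noise_model(gain, clamp_k = 2)
  den <- constrained_denoise(st, nm)
  # hard bound everywhere
  bound <- 2 * sqrt(st$images / gain)
  expect_true(all(abs(st$images - den$images) <= bound + 1e-12))
  # flat-field variance reduced, mean preserved within 0.1%
  expect_lt(var(as.vector(den$images)), var(as.vector(st$images)))
  expect_lt(abs(mean(den$images) / mean(st$images) - 1), 1e-3)
  # residual distribution: no mass beyond clamp_k sigma (histogram check)
  resid <- (st$images - den$images) / sqrt(st$images / gain)
  expect_lte(max(abs(resid)), 2 + 1e-9)
  # pluggable estimator: aggressive mean filter still respects the bound
  nm2 <- noise_model(gain, clamp_k = 1,
                     denoiser = function(img, g) {
                       matrix(mean(img), nrow(img), ncol(img))
                     })
  den2 <- constrained_denoise(st, nm2)
  expect_true(all(abs(st$images - den2$images) <=
                    sqrt(st$images / gain) + 1e-12))
})

test_that("synthetic mammogram: degenerate config, calc geometry, contrast", {
  ce <- calc_experiment()
  den <- constrained_denoise(add_counting_noise(ce$stack, 1e5, seed = 3L),
                             noise_model(1e5, 2))
  # k = 0 and zero detail weight: SM equals the (log of the) central view
  sm0 <- synthesize_sm(den, ce$vol, k = 0L, detail_weight = 0)
  cen <- -log(pmax(den$images[, , 13L], 1e-9 * den$ref_signal) /
                den$ref_signal)
  expect_equal(unclass(sm0), cen, tolerance = 1e-12, ignore_attr = TRUE)
  # calc lands within 1 px of its central-projection shadow
  sm <- synthesize_sm(den, ce$vol, k = 2L, detail_weight = 1)
  pk <- which(sm == max(sm), arr.ind = TRUE)[1L, ]
  lg_cen <- -log(ce$stack$images[, , 13L] / ce$stack$ref_signal)
  ref <- which(lg_cen == max(lg_cen), arr.ind = TRUE)[1L, ]
  expect_lte(max(abs(pk - ref)), 1)
  # detail weight raises calc contrast
  smA <- synthesize_sm(den, ce$vol, k = 2L, detail_weight = 0)
  roi <- function(img) img[ref[1L], ref[2L]] - median(img)
  expect_gt(roi(sm), roi(smA))
  # Cartesian volume is rejected
  cart <- resample_cartesian(ce$vol)
  expect_error(synthesize_sm(den, cart, k = 1L), "perspective")
})
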