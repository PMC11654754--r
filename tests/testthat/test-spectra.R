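single_bin_spectrum <- function(energy, n = 1e5) {
  sp <- generate_spectrum(40)
  sp$fluence_per_mAs[] <- 0
  sp$fluence_per_mAs[which.min(abs(sp$energy_bins_keV - energy))] <- n
  sp
}

test_that("Kramers spectrum shape, endpoint, and kVp monotonicity", {
  sp <- generate_spectrum(28)
  E <- sp$energy_bins_keV
  expect_true(all(sp$fluence_per_mAs[E >= 28] == 0))
  # bin ratio follows (kvp - E)/E
  r <- sp$fluence_per_mAs[E == 27.5] / sp$fluence_per_mAs[E == 10]
  expect_equal(r, ((28 - 27.5) / 27.5) / ((28 - 10) / 10), tolerance = 1e-12)
  tot <- vapply(seq(26, 34, 2), function(k)
    sum(generate_spectrum(k)$fluence_per_mAs), 0)
  expect_true(all(diff(tot) > 0))
  expect_error(generate_spectrum(10), "kvp")
})

test_that("Beer-Lambert filtration composes and hardens the beam", {
  sp <- generate_spectrum(30)
  expect_equal(attenuate(sp, "Al", 0)$fluence_per_mAs, sp$fluence_per_mAs)
  a <- attenuate(attenuate(sp, "Al", 0.3), "Al", 0.4)
  b <- attenuate(sp, "Al", 0.7)
  expect_equal(a$fluence_per_mAs, b$fluence_per_mAs, tolerance = 1e-12)
  # single 20-keV bin through 0.7 mm Al: transmitted fraction from the table
  sb <- single_bin_spectrum(20)
  out <- attenuate(sb, "Al", 0.7)
  expect_equal(sum(out$fluence_per_mAs) / sum(sb$fluence_per_mAs),
               exp(-mu_of("Al", 20) * 0.7), tolerance = 1e-12)
  # hardening: mean energy non-decreasing with thickness
  me <- vapply(c(0, 0.3, 0.7, 1.5), function(t)
    mean_energy(attenuate(sp, "Al", t)), 0)
  expect_true(all(diff(me) > 0))
  expect_error(attenuate(sp, "unobtainium", 1), "unknown material")
})

test_that("material tables: Rh K-edge discontinuity, Al smooth", {
  E <- energy_grid()
  rh <- mu_of("Rh", E)
  # jump between the bins straddling 23.22 keV
  i <- which(E == 23)
  expect_gt(rh[i + 1L] / rh[i], 2)
  # Al has no edge in 5-50 keV: strictly decreasing with no positive jump,
  # and smooth in log-log (bounded curvature)
  al <- mu_of("Al", E)
  expect_true(all(diff(al) < 0))
  expect_lt(max(abs(diff(diff(log(al))))), 0.05)
  # attenuation decreases with energy away from edges
  expect_true(all(diff(mu_of("PMMA", E)) < 0))
})

test_that("1-D CNR model: null contrast, Poisson scaling, closed form", {
  sp <- attenuate(generate_spectrum(28), "Al", 0.7)
  bg <- list("breast_50_50", 45)
  expect_equal(as.numeric(cnr_1d(sp, bg, list("breast_50_50", 5))), 0)
  c1 <- as.numeric(cnr_1d(sp, bg, list("calcium", 1), mAs = 1))
  c2 <- as.numeric(cnr_1d(sp, bg, list("calcium", 1), mAs = 2))
  expect_equal(c2 / c1, sqrt(2), tolerance = 1e-12)
  # monoenergetic closed form: CNR = sqrt(N_bg) * (1 - exp(-(mu_obj-mu_bg) t))
  sb <- single_bin_spectrum(25, n = 4e4)
  area <- 0.085^2
  t_obj <- 0.8
  got <- as.numeric(cnr_1d(sb, list("PMMA", 30), list("Al", t_obj),
                           pixel_area_mm2 = area))
  n_bg <- 4e4 * area * exp(-mu_of("PMMA", 25) * 30)
  dmu <- mu_of("Al", 25) - mu_of("PMMA", 25)
  expect_equal(got, sqrt(n_bg) * (1 - exp(-dmu * t_obj)), tolerance = 1e-10)
})

test_that("slab AGD: linearity in mAs and behavior in thickness", {
  sp <- attenuate(generate_spectrum(30), "Al", 0.7)
  expect_equal(agd_slab(sp, 50, mAs = 0), 0)
  expect_equal(agd_slab(sp, 50, mAs = 6), 2 * agd_slab(sp, 50, mAs = 3),
               tolerance = 1e-12)
  # fixed entrance fluence: dose per unit mass decreases with thickness
  agds <- vapply(c(30, 50, 70, 90), function(T) agd_slab(sp, T), 0)
  expect_true(all(diff(agds) < 0))
  expect_error(agd_slab(sp, 10), "breast_thickness")
  # glandularity scales linearly (spec slab model)
  expect_equal(agd_slab(sp, 50, glandularity = 1),
               2 * agd_slab(sp, 50, glandularity = 0.5), tolerance = 1e-12)
})

test_that("FOM scan: ranking, feasibility flags, exposure-time arithmetic", {
  es <- exposure_setting(28, 50, tube_power_kW = 5)
  expect_equal(es$exposure_time_ms, 50 * 28 / 5)
  expect_equal(exposure_setting(28, 50, 2.5)$exposure_time_ms,
               2 * es$exposure_time_ms)
  res <- scan_fom(c(26, 30, 34), list(list("Al", 0.7)), 60,
                  geometry = make_geometry())
  expect_s3_class(res, "fom_scan")
  expect_true(all(res$filter_material == "Al"))
  expect_true(all(diff(res$fom) <= 0))
  # FOM rank order across filters is mAs-target invariant
  r1 <- scan_fom(seq(24, 38, 2), list(list("Al", 0.7), list("Rh", 0.05)), 60,
                 cnr_target = 3)
  r2 <- scan_fom(seq(24, 38, 2), list(list("Al", 0.7), list("Rh", 0.05)), 60,
                 cnr_target = 6)
  key <- function(r) paste(r$filter_material, r$kvp)
  expect_identical(key(r1), key(r2))
})
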