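#' Generate a tungsten-anode bremsstrahlung spectrum
#'
#' Kramers-form spectrum `N(E) propto (kvp - E) / E` on the package energy
#' grid, zero at and above the tube voltage, normalized so that the total
#' fluence per mAs at the reference distance equals
#' `1e6 * (kvp / 28)^2` photons/mm^2/mAs (a nominal scale: fluence grows
#' roughly quadratically with tube voltage at fixed mAs). Characteristic
#' tungsten L-lines are omitted; the package makes only ranking-level
#' spectral claims, for which the continuum shape suffices.
#'
#' @param kvp tube voltage in kV, in \[20, 50\].
#' @return An object of class `xray_spectrum`: list with `kvp`,
#'   `energy_bins_keV`, `fluence_per_mAs`, `anode`, `filters`.
#' @export
generate_spectrum <- function(kvp) {
  if (kvp < 20 || kvp > 50) tb_stop("kvp must lie in [20, 50], got ", kvp)
  E <- energy_grid()
  n <- pmax(kvp - E, 0) / E
  total <- 1e6 * (kvp / 28)^2
  fl <- if (sum(n) > 0) n / sum(n) * total else n
  structure(list(kvp = kvp, energy_bins_keV = E, fluence_per_mAs = fl,
                 anode = "W", filters = list()),
            class = "xray_spectrum")
}

#' @export
print.xray_spectrum <- function(x, ...) {
  fstr <- if (length(x$filters)) {
    paste(vapply(x$filters, function(f)
      sprintf("%s %g mm", f[[1L]], as.numeric(f[[2L]])), ""), collapse = " + ")
  } else "none"
  cat(sprintf(
    "<xray_spectrum> %s anode, %g kVp, filters: %s\n  total %.4g ph/mm^2/mAs, mean energy %.2f keV\n",
    x$anode, x$kvp, fstr, sum(x$fluence_per_mAs), mean_energy(x)))
  invisible(x)
}

#' Mean (fluence-weighted) energy of a spectrum in keV
#' @param spectrum an `xray_spectrum`.
#' @export
mean_energy <- function(spectrum) {
  w <- spectrum$fluence_per_mAs
  sum(w * spectrum$energy_bins_keV) / sum(w)
}

#' Filter a spectrum through a material slab
#'
#' Per-bin Beer--Lambert attenuation `exp(-mu(E) * t)`. Composable and
#' order-independent; `thickness_mm = 0` is the identity.
#'
#' @param spectrum an `xray_spectrum`.
#' @param material material label, see [material_names()].
#' @param thickness_mm slab thickness in mm, >= 0.
#' @return the attenuated `xray_spectrum`, with the filter recorded.
#' @export
attenuate <- function(spectrum, material, thickness_mm) {
  stopifnot(inherits(spectrum, "xray_spectrum"))
  if (thickness_mm < 0) tb_stop("thickness_mm must be >= 0")
  mu <- mu_of(material, spectrum$energy_bins_keV)
  spectrum$fluence_per_mAs <- spectrum$fluence_per_mAs * exp(-mu * thickness_mm)
  spectrum$filters <- c(spectrum$filters, list(list(material, thickness_mm)))
  spectrum
}

# a-Se detector absorption efficiency per energy bin
detector_efficiency <- function(energy_keV, t_se_mm = 0.2) {
  1 - exp(-mu_of("a-Se", energy_keV) * t_se_mm)
}

#' One-dimensional quantum-noise CNR model
#'
#' Energy-integrating a-Se detector signal for a background column and for
#' the same column with `object` replacing an equal thickness of background;
#' quantum (Poisson) noise is the single noise source. Signals are
#' `S = sum N(E) E eps(E)` photons-weighted over one pixel, noise
#' `sigma_bg = sqrt(sum N(E) (E eps(E))^2)`, and `CNR = |S_bg - S_obj| /
#' sigma_bg`, which scales as `sqrt(mAs)`.
#'
#' @param spectrum incident `xray_spectrum` (before the background column).
#' @param background list/vector `(material, thickness_mm)`.
#' @param object list/vector `(material, thickness_mm)`; the object replaces
#'   an equal thickness of background material.
#' @param mAs tube load in mAs.
#' @param pixel_area_mm2 detector pixel area in mm^2.
#' @param t_se_mm a-Se converter thickness (mm).
#' @return dimensionless CNR (with attribute `signals`).
#' @export
cnr_1d <- function(spectrum, background, object, mAs = 1,
                   pixel_area_mm2 = 0.085^2, t_se_mm = 0.2) {
  stopifnot(inherits(spectrum, "xray_spectrum"))
  bg_mat <- as.character(background[[1L]]); bg_t <- as.numeric(background[[2L]])
  ob_mat <- as.character(object[[1L]]);     ob_t <- as.numeric(object[[2L]])
  if (bg_t <= 0 || ob_t < 0) tb_stop("thicknesses must be positive")
  if (ob_t > bg_t) tb_stop("object thicker than background column")
  E <- spectrum$energy_bins_keV
  eps <- detector_efficiency(E, t_se_mm)
  w <- E * eps
  n0 <- spectrum$fluence_per_mAs * mAs * pixel_area_mm2
  mu_bg <- mu_of(bg_mat, E)
  n_bg <- n0 * exp(-mu_bg * bg_t)
  n_obj <- n0 * exp(-mu_bg * (bg_t - ob_t) - mu_of(ob_mat, E) * ob_t)
  s_bg <- sum(n_bg * w); s_obj <- sum(n_obj * w)
  var_bg <- sum(n_bg * w^2)
  if (var_bg <= 0 || s_bg <= 0) {
    warning("zero fluence after attenuation; CNR set to 0")
    return(structure(0, signals = c(bg = s_bg, obj = s_obj)))
  }
  structure(abs(s_bg - s_obj) / sqrt(var_bg),
            signals = c(bg = s_bg, obj = s_obj))
}

#' Average glandular dose of a compressed-breast slab (simplified)
#'
#' Slab absorption model: the energy absorbed in the slab per unit area,
#' attributed to the glandular fraction, divided by the areal mass of the
#' slab. `AGD = sum Phi(E) E (1 - exp(-mu_breast(E) T)) g / (rho T)`,
#' converted to mGy. Linear in mAs. This is NOT a Dance-factor AGD; only
#' directional/ranking claims are made from it.
#'
#' @param spectrum incident `xray_spectrum` at the breast entrance.
#' @param breast_thickness_mm compressed thickness in \[20, 90\] mm.
#' @param glandularity glandular mass fraction in \[0, 1\].
#' @param mAs tube load.
#' @return dose in mGy.
#' @export
agd_slab <- function(spectrum, breast_thickness_mm, glandularity = 0.5,
                     mAs = 1) {
  stopifnot(inherits(spectrum, "xray_spectrum"))
  if (breast_thickness_mm < 20 || breast_thickness_mm > 90) {
    tb_stop("breast_thickness_mm must lie in [20, 90]")
  }
  if (glandularity < 0 || glandularity > 1) {
    tb_stop("glandularity must lie in [0, 1]")
  }
  E <- spectrum$energy_bins_keV
  mu <- mu_of("breast_50_50", E)               # 1/mm
  phi <- spectrum$fluence_per_mAs * mAs        # photons/mm^2
  keV_to_J <- 1.602176634e-16
  T <- breast_thickness_mm
  e_abs <- sum(phi * E * keV_to_J * (1 - exp(-mu * T)))  # J/mm^2
  rho <- density_of("breast_50_50") * 1e-3     # g/mm^3
  mass_per_area_kg <- rho * T * 1e-3           # kg/mm^2
  dose_Gy <- e_abs * glandularity / mass_per_area_kg
  dose_Gy * 1000
}

#' Exposure setting at a given tube power
#'
#' `exposure_time_ms = mAs / (P_kW * 1000 / kvp) * 1000`: the time needed to
#' deliver `mAs` at tube current `P / kvp`.
#'
#' @param kvp tube voltage (kV).
#' @param mAs tube load.
#' @param tube_power_kW peak generator power (default 5 kW).
#' @return list of class `exposure_setting`.
#' @export
exposure_setting <- function(kvp, mAs, tube_power_kW = 5) {
  stopifnot(kvp > 0, mAs >= 0, tube_power_kW > 0)
  list(kvp = kvp, mAs = mAs, tube_power_kW = tube_power_kW,
       exposure_time_ms = mAs * kvp / tube_power_kW)
}

#' CNR^2/AGD figure-of-merit scan over tube voltage and filtration
#'
#' For each (kvp, filter) candidate: attenuates a Kramers spectrum by the
#' filter, finds the mAs needed to reach the reference CNR (1-mm calcium
#' object over the breast background, quantum-noise 1-D model), evaluates the
#' AGD at that mAs, the figure of merit `CNR^2 / AGD`, and the exposure time
#' per projection at the generator's peak power. Results are sorted by FOM
#' (descending); settings whose exposure time exceeds the geometry's pulse
#' budget, or whose target CNR is unreachable within `mAs_cap`, are flagged
#' infeasible rather than erroring.
#'
#' @param kvp_grid tube voltages to scan.
#' @param filter_pool list of `(material, thickness_mm)` pairs.
#' @param breast_thickness_mm compressed breast thickness (mm).
#' @param geometry optional [make_geometry()] object supplying the per-pulse
#'   exposure-time budget.
#' @param cnr_target reference CNR to match (per-thickness config; default 5).
#' @param glandularity glandular fraction for the dose model.
#' @param object contrast object, default 1 mm calcium.
#' @param mAs_cap maximum deliverable mAs per scan.
#' @param tube_power_kW generator peak power (default 5).
#' @return data.frame of class `fom_scan` with one row per candidate:
#'   `kvp`, `filter_material`, `filter_thickness_mm`, `mAs`, `cnr`,
#'   `agd_mGy`, `fom`, `exposure_time_ms`, `feasible`.
#' @export
scan_fom <- function(kvp_grid, filter_pool, breast_thickness_mm,
                     geometry = NULL, cnr_target = 5, glandularity = 0.5,
                     object = list("calcium", 1.0), mAs_cap = 200,
                     tube_power_kW = 5) {
  if (!length(kvp_grid) || !length(filter_pool)) {
    tb_stop("kvp_grid and filter_pool must be nonempty")
  }
  budget_ms <- if (!is.null(geometry)) geometry$pulse_length_ms else Inf
  rows <- list()
  for (flt in filter_pool) {
    fm <- as.character(flt[[1L]]); ft <- as.numeric(flt[[2L]])
    for (kvp in kvp_grid) {
      sp <- attenuate(generate_spectrum(kvp), fm, ft)
      cnr1 <- as.numeric(cnr_1d(sp, list("breast_50_50", breast_thickness_mm),
                                object, mAs = 1))
      if (cnr1 <= 0) {
        mAs <- Inf
      } else {
        mAs <- (cnr_target / cnr1)^2     # CNR ~ sqrt(mAs)
      }
      feasible <- is.finite(mAs) && mAs <= mAs_cap
      cnr <- if (is.finite(mAs)) cnr1 * sqrt(mAs) else 0
      agd <- if (is.finite(mAs))
        agd_slab(sp, breast_thickness_mm, glandularity, mAs) else NA_real_
      es <- exposure_setting(kvp, if (is.finite(mAs)) mAs else NA_real_,
                             tube_power_kW)
      # per-projection exposure time, if attached to a geometry
      n_proj <- if (!is.null(geometry)) geometry$n_projections else 1L
      t_proj <- es$exposure_time_ms / n_proj
      if (is.finite(t_proj) && t_proj > budget_ms) feasible <- FALSE
      rows[[length(rows) + 1L]] <- data.frame(
        kvp = kvp, filter_material = fm, filter_thickness_mm = ft,
        mAs = mAs, cnr = cnr, agd_mGy = agd,
        fom = if (!is.na(agd) && agd > 0) cnr^2 / agd else NA_real_,
        exposure_time_ms = t_proj, feasible = feasible,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$fom, na.last = TRUE), ]
  rownames(out) <- NULL
  class(out) <- c("fom_scan", class(out))
  out
}
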