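#' Material attenuation tables
#'
#' Linear attenuation coefficients mu (1/mm) on the package energy grid
#' (5--50 keV in 0.5 keV steps) for the materials used throughout the
#' toolkit: filters (Al, Rh), phantom media (PMMA, adipose, glandular,
#' breast_50_50, air), high-contrast materials (calcium, titanium) and the
#' a-Se detector converter. Values derive from approximate standard-reference
#' anchors interpolated log-log (see `data-raw/make_mu_tables.R`); they are
#' accurate at the 10--20% level, adequate for the ranking and directional
#' claims this package makes, and not for regulatory dosimetry.
#'
#' @return A data.frame with columns `material`, `energy_keV`, `mu_per_mm`,
#'   `density_g_cm3`.
#' @export
material_table <- function() {
  if (is.null(.tb_env$mu_tables)) {
    path <- system.file("extdata", "mu_tables.csv", package = "tomobreast")
    .tb_env$mu_tables <- read.csv(path, stringsAsFactors = FALSE)
  }
  .tb_env$mu_tables
}

#' Known material names
#' @export
material_names <- function() unique(material_table()$material)

#' Linear attenuation coefficient lookup
#'
#' @param material material label, see [material_names()].
#' @param energy_keV energies in keV (vector); values are linearly
#'   interpolated on the 0.5 keV grid and clamped to its ends.
#' @return mu in 1/mm, same length as `energy_keV`.
#' @export
mu_of <- function(material, energy_keV) {
  tab <- material_table()
  rows <- tab[tab$material == material, ]
  if (nrow(rows) == 0L) {
    tb_stop("unknown material '", material, "'; known: ",
            paste(material_names(), collapse = ", "),
            class = "tomobreast_lookup_error")
  }
  approx(rows$energy_keV, rows$mu_per_mm, xout = energy_keV, rule = 2)$y
}

#' Material mass density
#' @param material material label.
#' @return density in g/cm^3.
#' @export
density_of <- function(material) {
  tab <- material_table()
  rows <- tab[tab$material == material, ]
  if (nrow(rows) == 0L) {
    tb_stop("unknown material '", material, "'",
            class = "tomobreast_lookup_error")
  }
  rows$density_g_cm3[1L]
}

#' Package energy grid (keV)
#' @export
energy_grid <- function() seq(5, 50, by = 0.5)
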