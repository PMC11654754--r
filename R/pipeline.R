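#' Run a configured simulation/reconstruction pipeline
#'
#' Executes the configured stages in order — any prefix of
#' `phantom -> simulate -> recon -> postproc -> sm` (with optional artifact
#' reduction inside `recon`) — writing all intermediates as TIFF+JSON pairs
#' and a run manifest. All randomness flows from named seeds in the config,
#' so identical config + seeds reproduce outputs bit-identically.
#'
#' @param config a config list, or a path to a JSON config file. Recognized
#'   top-level keys: `outdir`, `seed`, `stages` (character vector),
#'   `geometry`, `phantom`, `simulate`, `recon`, `postproc`, `sm`.
#' @return the run manifest (list of class `run_manifest`), invisibly
#'   written to `<outdir>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  known_stages <- c("phantom", "simulate", "recon", "postproc", "sm")
  stages <- config$stages %||% known_stages
  bad <- setdiff(stages, known_stages)
  if (length(bad)) tb_config_error("stages", paste0("unknown stage '", bad[1L], "'"))
  ord <- match(stages, known_stages)
  if (is.unsorted(ord)) tb_config_error("stages", "stages out of order")
  if (!identical(known_stages[seq_along(stages)], stages)) {
    tb_config_error("stages", "stages must be a prefix of the full pipeline")
  }
  outdir <- config$outdir %||% tempfile("tomobreast_run_")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  manifest <- list(config = config, seeds = list(master = seed),
                   package_version = as.character(utils::packageVersion("tomobreast")),
                   stage_timings_s = list(), outputs = list())
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      tb_stop("stage '", name, "' failed: ", conditionMessage(e))
    })
    manifest$stage_timings_s[[name]] <<- proc.time()[["elapsed"]] - t0
    message(sprintf("[tomobreast] stage %-9s %6.2f s", name,
                    manifest$stage_timings_s[[name]]))
    res
  }
  record <- function(name, path) {
    manifest$outputs[[name]] <<- list(path = path,
                                      md5 = unname(tools::md5sum(path)))
  }

  geom <- make_geometry(as_config_list(config$geometry))
  phantom <- stack <- vol <- NULL

  if ("phantom" %in% stages) {
    pc <- as_config_list(config$phantom)
    phantom <- timed("phantom", {
      ph <- build_slab_phantom(
        thickness_mm = pc$thickness_mm %||% 50,
        glandularity = pc$glandularity %||% 0.3,
        shape = pc$shape %||% c(96L, 72L, 50L),
        voxel_size_mm = pc$voxel_size_mm %||% c(0.2, 0.2, 1),
        texture_beta = pc$texture_beta %||% 3,
        seed = pc$seed %||% seed)
      for (ins in pc$inserts %||% list()) {
        ph <- add_insert(ph, do.call(insert_spec, as_config_list(ins)))
      }
      ph
    })
    manifest$seeds$phantom <- phantom$seed
  }
  if ("simulate" %in% stages) {
    sc <- as_config_list(config$simulate)
    stack <- timed("simulate", {
      st <- forward_project(phantom, geom,
                            spectrum = sc$effective_energy_keV %||% 20,
                            n_spot_samples = sc$n_spot_samples %||% 3L,
                            n_time_samples = sc$n_time_samples %||% 3L,
                            n_det_sub = sc$n_det_sub %||% 3L)
      if (!is.null(sc$noise_gain)) {
        st <- add_counting_noise(st, sc$noise_gain,
                                 seed = sc$noise_seed %||% (seed + 1L))
      }
      st
    })
    manifest$seeds$noise <- config$simulate$noise_seed %||% (seed + 1L)
    p <- file.path(outdir, "projections.tif")
    write_stack(stack, p); record("projections", p)
  }
  if ("recon" %in% stages) {
    rc <- as_config_list(config$recon)
    vol <- timed("recon", {
      lg <- to_line_integrals(stack)
      z <- seq(rc$z_min %||% 1,
               rc$z_max %||% (phantom$thickness_mm - 1),
               by = rc$spacing %||% 1)
      if (isTRUE(rc$artifact_reduction)) {
        masks <- segment_objects(lg)
        rem <- remove_objects(lg, masks)
        fp <- ramp_filter(lg, window = rc$window %||% "hann", rP = rem)
        masked_backproject(fp, masks, geom, z)
      } else {
        fp <- ramp_filter(lg, window = rc$window %||% "hann")
        backproject_perspective(fp, geom, z)
      }
    })
    p <- file.path(outdir, "recon.tif")
    write_stack(vol, p); record("recon", p)
  }
  if ("postproc" %in% stages) {
    pp <- as_config_list(config$postproc)
    vol <- timed("postproc", {
      v <- equalize_baseline(vol,
                             baseline_sigma_mm = pp$baseline_sigma_mm %||% 20)
      cfg <- flavor_config(
        n_bands = pp$n_bands %||% 4L,
        band_gains = pp$band_gains %||% rep(1, pp$n_bands %||% 4L),
        overshoot_clamp = pp$overshoot_clamp)
      multiband_enhance(v, cfg)
    })
    p <- file.path(outdir, "postproc.tif")
    write_stack(vol, p); record("postproc", p)
  }
  if ("sm" %in% stages) {
    smc <- as_config_list(config$sm)
    sm <- timed("sm", {
      den <- constrained_denoise(stack,
                                 noise_model(gain = smc$gain %||% 1e4,
                                             clamp_k = smc$clamp_k %||% 2))
      synthesize_sm(den, vol, k = smc$k %||% 2L,
                    detail_weight = smc$detail_weight %||% 0.5)
    })
    p <- file.path(outdir, "sm.tif")
    write_tiff_f32(unclass(sm), p); record("sm", p)
  }
  class(manifest) <- "run_manifest"
  writeLines(jsonlite::toJSON(unclass(manifest), auto_unbox = TRUE,
                              digits = NA, null = "null", pretty = TRUE,
                              force = TRUE),
             file.path(outdir, "manifest.json"))
  manifest$outdir <- outdir
  invisible(manifest)
}

# jsonlite may hand back data.frames / NULL for absent config sections
as_config_list <- function(x) {
  if (is.null(x)) return(list())
  if (is.data.frame(x)) return(as.list(x))
  as.list(x)
}
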