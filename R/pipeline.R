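#' Era presets for the two processing regimes
#'
#' The package reproduces two data-collection/processing eras of a
#' breeding-program HTP comparison: `era_2018` — UAS calibrated with a
#' single 85% reflectance panel on blue/green/red/red-edge bands and NIR
#' derived from quantum-efficiency coefficients, handheld platform a
#' broadband radiometer; `era_2020` — UAS calibrated with a five-panel
#' empirical line on all bands, handheld platform a full-range
#' hyperspectral radiometer whose curves are quality-controlled and
#' averaged into 50 nm broadbands.
#'
#' @param era `"era_2018"` or `"era_2020"`.
#' @return list of era settings.
#' @export
era_preset <- function(era = c("era_2020", "era_2018")) {
  era <- match.arg(era)
  if (era == "era_2018") {
    list(name = "era_2018", calibration_method = "single_panel",
         panels = panel_set(0.85), nir_derived = TRUE,
         handheld_platform = "radiometer_broadband")
  } else {
    list(name = "era_2020", calibration_method = "multi_panel",
         panels = panel_set(c(0.02, 0.11, 0.22, 0.44, 0.85)),
         nir_derived = FALSE,
         handheld_platform = "hyperspectral")
  }
}

# Band-dependent solar-drift sensitivity anchors shared by every platform:
# canopy shadowing and irradiance change away from solar noon hit the
# near-infrared (multiple-scattering dominated) harder than the red.
drift_weight_anchors <- function() {
  c(R450 = 1.1, R550 = 1.0, R680 = 0.55, R700 = 0.8, R800 = 1.35, R970 = 1.45)
}

drift_weight_fn <- function() {
  w <- drift_weight_anchors()
  centers <- c(450, 550, 680, 700, 800, 970)
  function(wl) stats::approx(centers, unname(w), xout = wl, rule = 2)$y
}

#' Platform sensor presets
#'
#' UAS: broadband camera emitting digital numbers (affine DN transfer),
#' four-hour collection window, 20-minute capture. For `era_2018` the NIR
#' band is absent and the blue channel carries a strong secondary
#' 775-825 nm response (weight 3; the red channel a weak one, 0.2), the
#' sensor property that makes the quantum-efficiency NIR derivation
#' meaningful. Handheld radiometer/hyperspectral: reflectance units,
#' six-hour collection window.
#'
#' @param era an [era_preset()] or era name.
#' @param noise_sd observation noise (reflectance units; scaled by the DN
#'   gain for the UAS).
#' @param drift_amplitude drift slope per hour from solar noon.
#' @return a [sensor_model()].
#' @name sensor_presets
NULL

#' @rdname sensor_presets
#' @export
uas_sensor <- function(era = era_preset("era_2020"), noise_sd = 0.008,
                       drift_amplitude = 0.05) {
  if (is.character(era)) era <- era_preset(era)
  gain <- 1000; offset <- 200
  if (era$nir_derived) {
    bands <- default_bands(include_blue = TRUE, include_nir = FALSE)
    leakage <- data.frame(band = c("R450", "R680"),
                          center = 800, width = 50,
                          weight = c(3, 0.2))
  } else {
    bands <- default_bands(include_blue = TRUE, include_nir = TRUE)
    leakage <- NULL
  }
  sensor_model("uas_broadband", bands = bands, leakage = leakage,
               dn_gain = gain, dn_offset = offset,
               noise_sd = noise_sd * gain,
               window_hours = 2, drift_amplitude = drift_amplitude,
               drift_weights = drift_weight_anchors())
}

#' @rdname sensor_presets
#' @export
handheld_sensor <- function(era = era_preset("era_2020"), noise_sd = 0.008,
                            drift_amplitude = 0.05) {
  if (is.character(era)) era <- era_preset(era)
  if (era$handheld_platform == "hyperspectral") {
    sensor_model("hyperspectral", noise_sd = noise_sd,
                 window_hours = 3, drift_amplitude = drift_amplitude,
                 drift_weights = drift_weight_fn())
  } else {
    sensor_model("radiometer_broadband", bands = default_bands(),
                 noise_sd = noise_sd,
                 window_hours = 3, drift_amplitude = drift_amplitude,
                 drift_weights = drift_weight_anchors())
  }
}

#' Build a pipeline configuration
#'
#' @param era era name (`"era_2020"` or `"era_2018"`).
#' @param out_dir run directory (created by [run_pipeline()]).
#' @param seed master seed; every stage derives its own stream from it.
#' @param design list of [generate_trial_design()] arguments.
#' @param genetics list of [simulate_genetic_values()] arguments (without
#'   `design`/`seed`).
#' @param noise_sd,drift_amplitude sensor noise and drift settings.
#' @param uas_capture_hours half-spread of UAS plot observation times
#'   around solar noon (default 1/6 h, a 20-minute flight).
#' @param indices index set for [compute_sri_table()].
#' @param normalize_handheld divide handheld bands by their within-trial
#'   standard deviation before index computation.
#' @param orthomosaic also simulate an orthomosaic for the first
#'   environment, write it with polygons, and extract plot means with a
#'   soil mask.
#' @param spectrum_step wavelength step (nm) of simulated canopy spectra.
#' @return a `run_config` list.
#' @export
pipeline_config <- function(era = "era_2020",
                            out_dir = tempfile("phenospectra_run_"),
                            seed = 1,
                            design = list(design_kind = "augmented_with_checks",
                                          n_entries = 120, n_checks = 8,
                                          checks_rep = 5, x = 2),
                            genetics = list(),
                            noise_sd = 0.008,
                            drift_amplitude = 0.05,
                            uas_capture_hours = 1 / 6,
                            indices = c("ndvi", "ndre", "tcari", "nwi", "mtvi"),
                            normalize_handheld = TRUE,
                            orthomosaic = FALSE,
                            spectrum_step = 5) {
  structure(list(era = era, out_dir = out_dir, seed = as.integer(seed),
                 design = design, genetics = genetics,
                 noise_sd = noise_sd, drift_amplitude = drift_amplitude,
                 uas_capture_hours = uas_capture_hours,
                 indices = indices, normalize_handheld = normalize_handheld,
                 orthomosaic = orthomosaic, spectrum_step = spectrum_step),
            class = "run_config")
}

# Simulate canopy spectra for every plot of a genetic simulation.
simulate_plot_spectra <- function(sim, seed, step = 5, noise_sd = 0.004) {
  pv <- sim$plot_values
  wl <- seq(338, 2515, by = step)
  lapply(seq_len(nrow(pv)), function(i)
    simulate_canopy_spectrum(pv$latent_trait[i], pv$water_proxy[i],
                             seed = child_seed(seed, pv$plot_id[i]),
                             wavelengths = wl, noise_sd = noise_sd))
}

# Collection-time offsets: plots observed in field order across the
# platform's capture span, one sweep per environment.
collection_offsets <- function(plot_env, span_hours) {
  out <- numeric(length(plot_env))
  for (env in unique(plot_env)) {
    ix <- which(plot_env == env)
    out[ix] <- if (length(ix) == 1) 0
    else seq(-span_hours, span_hours, length.out = length(ix))
  }
  out
}

# Observe every plot through a broadband sensor; returns a wide band table.
observe_plots_broadband <- function(spectra, plot_ids, plot_env, sensor,
                                    span_hours, seed) {
  offsets <- collection_offsets(plot_env, span_hours)
  rows <- lapply(seq_along(spectra), function(i) {
    obs <- observe_plot(spectra[[i]], sensor, offsets[i],
                        seed = child_seed(seed, plot_ids[i]),
                        plot_id = plot_ids[i])
    obs$band_values
  })
  out <- cbind(data.frame(plot_id = plot_ids),
               as.data.frame(do.call(rbind, rows)))
  out$time_offset_hours <- offsets
  out
}

# Observe every plot through the hyperspectral channel; long curve table.
observe_plots_hyperspectral <- function(spectra, plot_ids, plot_env, sensor,
                                        span_hours, seed) {
  offsets <- collection_offsets(plot_env, span_hours)
  do.call(rbind, lapply(seq_along(spectra), function(i) {
    obs <- observe_plot(spectra[[i]], sensor, offsets[i],
                        seed = child_seed(seed, plot_ids[i]),
                        plot_id = plot_ids[i])
    data.frame(plot_id = plot_ids[i], wavelength = obs$curve$wavelength,
               reflectance = obs$curve$reflectance)
  }))
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the stage chain generate -> calibrate -> process -> indices ->
#' heritability -> association under one configuration, writing every
#' stage artifact (CSV/JSON) plus a provenance manifest into
#' `config$out_dir`. Identical configuration and seed reproduce identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage messages.
#' @return (invisibly) a list with the main in-memory results: `design`,
#'   `sim`, `sri` (per-platform index tables joined to yield),
#'   `heritability` (per trait/platform H2 table), `correlation`, `pca`,
#'   `regressions`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  era <- era_preset(config$era)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  outfile <- function(f) file.path(config$out_dir, f)
  seed <- config$seed

  ## stage 1: generate ------------------------------------------------------
  design <- do.call(generate_trial_design,
                    c(config$design, list(seed = child_seed(seed, "design"))))
  sim <- do.call(simulate_genetic_values,
                 c(list(design = design, seed = child_seed(seed, "genetics")),
                   config$genetics))
  spectra <- simulate_plot_spectra(sim, child_seed(seed, "spectra"),
                                   step = config$spectrum_step)
  pv <- sim$plot_values
  say("generate: %d plots, %d entries, x=%d", nrow(pv), design$n_entries,
      design$x)
  utils::write.csv(pv, outfile("plot_table.csv"), row.names = FALSE)
  jsonlite::write_json(
    sim$ground_truth[c("sigma_G2", "sigma_GE2", "sigma_eps2", "sigma_rep2",
                       "sigma_block2", "genetic_corr_yield", "x", "r",
                       "trait_mean", "yield_mean")],
    outfile("ground_truth.json"), auto_unbox = TRUE, digits = NA)

  usens <- uas_sensor(era, config$noise_sd, config$drift_amplitude)
  hsens <- handheld_sensor(era, config$noise_sd, config$drift_amplitude)

  uas_dn <- observe_plots_broadband(spectra, pv$plot_id, pv$environment_id,
                                    usens, config$uas_capture_hours,
                                    child_seed(seed, "uas"))
  utils::write.csv(uas_dn, outfile("uas_dn.csv"), row.names = FALSE)
  panel_dn <- observe_panels(era$panels, usens, time_offset_hours = 0,
                             seed = child_seed(seed, "panels"))
  utils::write.csv(panel_dn, outfile("uas_panels.csv"), row.names = FALSE)

  if (era$handheld_platform == "hyperspectral") {
    hh_curves <- observe_plots_hyperspectral(spectra, pv$plot_id,
                                             pv$environment_id, hsens,
                                             hsens$window_hours,
                                             child_seed(seed, "handheld"))
    utils::write.csv(hh_curves, outfile("handheld_curves.csv"),
                     row.names = FALSE)
  } else {
    hh_bands <- observe_plots_broadband(spectra, pv$plot_id,
                                        pv$environment_id, hsens,
                                        hsens$window_hours,
                                        child_seed(seed, "handheld"))
    utils::write.csv(hh_bands, outfile("handheld_bands.csv"),
                     row.names = FALSE)
  }

  ## stage 2: calibrate the UAS channel -------------------------------------
  cal <- fit_empirical_line(panel_dn, method = era$calibration_method)
  write_calibration_model(cal, outfile("calibration_model.json"))
  band_cols <- usens$bands$band
  dn_long <- data.frame(
    plot_id = rep(uas_dn$plot_id, length(band_cols)),
    band = rep(band_cols, each = nrow(uas_dn)),
    dn = unlist(uas_dn[band_cols], use.names = FALSE))
  sr_long <- apply_calibration(dn_long, cal)
  uas_sr <- as.data.frame(matrix(sr_long$sr, nrow = nrow(uas_dn),
                                 dimnames = list(NULL, band_cols)))
  uas_sr <- cbind(data.frame(plot_id = uas_dn$plot_id), uas_sr)
  if (era$nir_derived) {
    nir <- derive_nir(uas_sr$R450, uas_sr$R680, normalize = TRUE)
    uas_sr$R800 <- as.numeric(nir)
    say("calibrate: derived NIR band from quantum-efficiency coefficients")
  }
  say("calibrate: %s on %d band(s), %d value(s) clipped",
      era$calibration_method, length(band_cols),
      attr(sr_long, "n_clipped"))
  utils::write.csv(uas_sr, outfile("uas_reflectance.csv"), row.names = FALSE)

  ## stage 3: process the handheld channel -----------------------------------
  if (era$handheld_platform == "hyperspectral") {
    hh_wide <- curves_to_broadband(hh_curves, bands = default_bands())
    n_fail <- sum(nzchar(hh_wide$qc_flag))
    say("process: %d/%d curves removed by quality control", n_fail,
        nrow(hh_wide))
  } else {
    hh_wide <- hh_bands[, c("plot_id", hsens$bands$band)]
    hh_wide$qc_flag <- ""
  }
  hh_bands_used <- intersect(names(hh_wide), default_bands()$band)
  if (config$normalize_handheld) {
    env_of <- stats::setNames(pv$environment_id, pv$plot_id)
    long <- data.frame(
      plot_id = rep(hh_wide$plot_id, length(hh_bands_used)),
      trial_id = rep(unname(env_of[hh_wide$plot_id]), length(hh_bands_used)),
      band = rep(hh_bands_used, each = nrow(hh_wide)),
      value = unlist(hh_wide[hh_bands_used], use.names = FALSE))
    long <- normalize_by_trial_sd(long)
    for (b in hh_bands_used)
      hh_wide[[b]] <- long$normalized[long$band == b]
  }
  utils::write.csv(hh_wide, outfile("handheld_reflectance.csv"),
                   row.names = FALSE)

  ## optional: orthomosaic round trip for the first environment -------------
  ortho <- NULL
  if (isTRUE(config$orthomosaic)) {
    env1 <- pv$environment_id == pv$environment_id[1]
    ortho <- simulate_orthomosaic(uas_sr[env1, c("plot_id", "R550", "R680",
                                                 "R700", "R800", "R970")],
                                  seed = child_seed(seed, "ortho"))
    write_raster_tiff(ortho$raster, outfile("orthomosaic.tif"))
    write_polygons_geojson(ortho$polygons, outfile("plots.geojson"))
    msk <- mask_soil(ortho$raster, ortho$polygons)
    zonal <- extract_plot_means(ortho$raster, ortho$polygons, msk$mask)
    utils::write.csv(zonal, outfile("zonal_means.csv"), row.names = FALSE)
    say("orthomosaic: %d polygons, mean masked fraction %.2f",
        length(ortho$polygons), mean(msk$masked_fraction$masked_fraction))
  }

  ## stage 4: indices ---------------------------------------------------------
  yield <- stats::setNames(pv$yield, pv$plot_id)
  sri <- list()
  for (pl in c("uas", "handheld")) {
    tab <- if (pl == "uas") uas_sr else hh_wide
    s <- compute_sri_table(tab, indices = config$indices, platform = pl)
    s$yield <- unname(yield[s$plot_id])
    sri[[pl]] <- s
    utils::write.csv(s, outfile(sprintf("sri_%s.csv", pl)), row.names = FALSE)
  }
  say("indices: %s", paste(config$indices, collapse = ", "))

  ## stage 5: heritability ---------------------------------------------------
  key <- pv[, c("plot_id", "genotype_id", "environment_id", "replicate_id",
                "block_id")]
  h2_rows <- list()
  for (pl in names(sri)) {
    merged <- merge(key, sri[[pl]], by = "plot_id")
    for (ix in intersect(config$indices, names(merged))) {
      comp <- estimate_variance_components(merged, value_col = ix)
      h <- broad_sense_heritability(comp, x = design$x, r = design$r,
                                    trait = ix)
      h2_rows[[paste(pl, ix)]] <- data.frame(
        platform = pl, trait = ix, H2 = h$H2,
        sigma_G2 = comp$sigma_G2, sigma_GE2 = comp$sigma_GE2,
        sigma_eps2 = comp$sigma_eps2, converged = comp$converged)
    }
  }
  compy <- estimate_variance_components(merge(key, pv[, c("plot_id", "yield")],
                                              by = "plot_id"),
                                        value_col = "yield")
  hy <- broad_sense_heritability(compy, x = design$x, r = design$r,
                                 trait = "yield")
  h2_rows[["yield"]] <- data.frame(platform = "ground", trait = "yield",
                                   H2 = hy$H2, sigma_G2 = compy$sigma_G2,
                                   sigma_GE2 = compy$sigma_GE2,
                                   sigma_eps2 = compy$sigma_eps2,
                                   converged = compy$converged)
  h2_table <- do.call(rbind, h2_rows)
  rownames(h2_table) <- NULL
  utils::write.csv(h2_table, outfile("heritability.csv"), row.names = FALSE)
  say("heritability: %d trait/platform fits", nrow(h2_table))

  ## stage 6: association ----------------------------------------------------
  assoc_tab <- data.frame(yield = unname(yield[sri$uas$plot_id]))
  for (pl in names(sri))
    for (ix in intersect(config$indices, names(sri[[pl]])))
      assoc_tab[[paste(pl, ix, sep = "_")]] <-
    sri[[pl]][[ix]][match(sri$uas$plot_id, sri[[pl]]$plot_id)]
  cm <- correlation_matrix(assoc_tab)
  utils::write.csv(correlation_long(cm), outfile("correlation.csv"),
                   row.names = FALSE)
  pca <- pca_traits(assoc_tab)
  jsonlite::write_json(as.list(pca$variance_explained),
                       outfile("pca_variance_explained.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(variable = rownames(pca$loadings),
                              pca$loadings, check.names = FALSE),
                   outfile("pca_loadings.csv"), row.names = FALSE)
  regress <- lapply(stats::setNames(names(sri), names(sri)), function(pl) {
    s <- sri[[pl]]
    do.call(rbind, lapply(intersect(config$indices, names(s)), function(ix) {
      lr <- linear_regression(s$yield, s[[ix]])
      data.frame(platform = pl, index = ix, slope = lr$slope,
                 intercept = lr$intercept, r_squared = lr$r_squared,
                 n = lr$n)
    }))
  })
  regress <- do.call(rbind, regress)
  rownames(regress) <- NULL
  utils::write.csv(regress, outfile("regressions.csv"), row.names = FALSE)
  say("association: correlation, PCA (Dim1 %.1f%%), %d regressions",
      pca$variance_explained[1], nrow(regress))

  ## manifest ----------------------------------------------------------------
  cfg_path <- outfile("config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("phenospectra")),
    era = era$name, seed = seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_plots = nrow(pv),
    qc_removed = if (era$handheld_platform == "hyperspectral")
      sum(nzchar(hh_wide$qc_flag)) else 0L,
    files = sort(list.files(config$out_dir)))
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(design = design, sim = sim, sri = sri,
                 heritability = h2_table, correlation = cm, pca = pca,
                 regressions = regress, ortho = ortho, manifest = manifest))
}

#' Collection-window heritability experiment
#'
#' Observes identical genetics (same latent values, canopy spectra and
#' observation-noise draws) through two otherwise identical reflectance
#' channels that differ only in how far plot observation times spread from
#' solar noon: a handheld sweep across the full six-hour window versus a
#' short UAS capture. Solar drift then perturbs the handheld observations
#' plot-by-plot, inflating the residual variance of every index, and the
#' broad-sense heritability of handheld indices falls below the UAS ones.
#'
#' @param n_seeds replicate simulations to average over.
#' @param n_entries,x,r alpha-lattice dimensions of each simulated trial.
#' @param handheld_span,uas_span observation-time half-spreads (h).
#' @param drift_amplitude,noise_sd channel settings (shared).
#' @param indices index set to evaluate.
#' @param sigma_G2,sigma_GE2,sigma_eps2 generating variances.
#' @param seed master seed.
#' @return list with `summary` (per-platform mean H2 across indices and
#'   seeds), `per_index` (platform x index means), `delta` (mean UAS minus
#'   handheld H2) and `runs` (the full per-seed table).
#' @export
collection_window_experiment <- function(n_seeds = 20,
                                         n_entries = 150, x = 2, r = 2,
                                         handheld_span = 3,
                                         uas_span = 1 / 6,
                                         drift_amplitude = 0.05,
                                         noise_sd = 0.008,
                                         indices = c("ndvi", "ndre", "tcari",
                                                     "nwi", "mtvi"),
                                         sigma_G2 = 1, sigma_GE2 = 0.25,
                                         sigma_eps2 = 0.5,
                                         seed = 1) {
  channels <- list(
    handheld = sensor_model("radiometer_broadband", bands = default_bands(),
                            noise_sd = noise_sd, window_hours = handheld_span,
                            drift_amplitude = drift_amplitude,
                            drift_weights = drift_weight_anchors()),
    uas = sensor_model("radiometer_broadband", bands = default_bands(),
                       noise_sd = noise_sd, window_hours = max(uas_span, 1e-6),
                       drift_amplitude = drift_amplitude,
                       drift_weights = drift_weight_anchors()))
  spans <- c(handheld = handheld_span, uas = uas_span)

  runs <- list()
  for (s in seq_len(n_seeds)) {
    sd_i <- child_seed(seed, paste0("win", s))
    design <- generate_trial_design("alpha_lattice", n_entries = n_entries,
                                    r = r, x = x, seed = sd_i)
    sim <- simulate_genetic_values(design, sigma_G2 = sigma_G2,
                                   sigma_GE2 = sigma_GE2,
                                   sigma_eps2 = sigma_eps2,
                                   seed = child_seed(sd_i, "gen"))
    pv <- sim$plot_values
    spectra <- simulate_plot_spectra(sim, child_seed(sd_i, "spec"),
                                     step = 5, noise_sd = 0)
    key <- pv[, c("plot_id", "genotype_id", "environment_id",
                  "replicate_id", "block_id")]
    for (ch in names(channels)) {
      bt <- observe_plots_broadband(spectra, pv$plot_id, pv$environment_id,
                                    channels[[ch]], spans[[ch]],
                                    child_seed(sd_i, "obs")) # shared draws
      sri <- compute_sri_table(bt, indices = indices)
      merged <- merge(key, sri, by = "plot_id")
      for (ix in indices) {
        comp <- estimate_variance_components(merged, value_col = ix,
                                             method = "anova_moments")
        h <- broad_sense_heritability(comp, x = x, r = r, trait = ix)
        runs[[length(runs) + 1]] <- data.frame(seed_rep = s, platform = ch,
                                               index = ix, H2 = h$H2)
      }
    }
  }
  runs <- do.call(rbind, runs)
  summary <- tapply(runs$H2, runs$platform, mean)
  per_index <- tapply(runs$H2, list(runs$platform, runs$index), mean)
  list(summary = summary, per_index = per_index,
       delta = unname(summary["uas"] - summary["handheld"]), runs = runs)
}
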