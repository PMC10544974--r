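#' Simulate a canopy reflectance spectrum
#'
#' Parametric vegetation curve on the full-range grid of a field
#' spectro-radiometer (338-2515 nm by default). The latent canopy trait is
#' squashed to a canopy-density/chlorophyll proxy `c = plogis(latent)` which
#' deepens the red (680 nm) absorption and raises the near-infrared plateau
#' through a logistic red edge; the water driver `w = plogis(water_proxy)`
#' deepens the 970/1200/1450/1940 nm water absorption features. At the
#' latent minimum the curve degenerates to a flat, soil-like spectrum.
#'
#' By construction the curve has a local reflectance minimum near 680 nm
#' below the 800 nm value, a monotone red-edge rise on 680-780 nm, NDVI
#' strictly increasing in the latent trait, and 970 nm reflectance strictly
#' decreasing in the water driver. Values are clamped to \[0, 1.2\].
#'
#' @param latent_trait latent canopy trait (unbounded scale).
#' @param water_proxy latent water-status driver (unbounded scale).
#' @param seed integer seed for the optional smooth noise.
#' @param wavelengths wavelength grid in nm (must cover 338-2515 at <= 5 nm
#'   steps for full-range use; any increasing grid is accepted).
#' @param noise_sd standard deviation of smooth spectral noise (reflectance
#'   units; default 0 gives a deterministic curve).
#' @return A `canopy_spectrum`: data.frame with columns `wavelength` and
#'   `reflectance`, with the drivers stored as attributes
#'   `chlorophyll_proxy` and `water_proxy`.
#' @examples
#' sp <- simulate_canopy_spectrum(1.5, water_proxy = 0)
#' @export
simulate_canopy_spectrum <- function(latent_trait,
                                     water_proxy = 0,
                                     seed = NULL,
                                     wavelengths = seq(338, 2515, by = 2.5),
                                     noise_sd = 0) {
  if (is.unsorted(wavelengths, strictly = TRUE))
    ps_stop("wavelengths must be strictly increasing", "input_error")
  cc <- stats::plogis(latent_trait)
  w <- stats::plogis(water_proxy)
  lam <- wavelengths

  gauss <- function(mu, sd) exp(-((lam - mu)^2) / (2 * sd^2))

  r680 <- 0.28 - 0.24 * cc                    # red absorption floor
  plateau <- 0.32 + 0.28 * cc                 # NIR plateau
  green <- (0.01 + 0.06 * cc) * gauss(550, 45) # green reflectance bump
  visible <- r680 + green - 0.02 * cc * gauss(450, 40)
  edge <- stats::plogis((lam - 715) / 12)     # red-edge logistic
  base <- visible * (1 - edge) + plateau * edge

  # water absorption features, scaled by the water driver (plus a small
  # permanent 970 nm dip so the band is defined even for dry canopies)
  dip <- (0.03 + 0.12 * w) * gauss(970, 45) + 0.10 * w * gauss(1200, 60) +
    (0.10 + 0.45 * w) * gauss(1450, 80) + (0.12 + 0.50 * w) * gauss(1940, 110)
  # broad shortwave-infrared decline (kept clear of the red edge)
  taper <- 1 - 0.35 * stats::plogis((lam - 1500) / 120)

  refl <- base * (1 - pmin(dip, 0.95)) * taper

  if (noise_sd > 0) {
    refl <- refl + with_seed(seed, {
      raw <- stats::rnorm(length(lam) + 24)
      sm <- stats::filter(raw, rep(1 / 25, 25), sides = 2)
      sm <- sm[!is.na(sm)][seq_along(lam)]
      as.numeric(sm) / stats::sd(sm) * noise_sd
    })
  }

  out <- data.frame(wavelength = lam, reflectance = clamp(refl, 0, 1.2))
  attr(out, "chlorophyll_proxy") <- cc
  attr(out, "water_proxy") <- w
  class(out) <- c("canopy_spectrum", "data.frame")
  out
}

#' Define a sensor observation channel
#'
#' Describes how a platform turns a canopy spectrum into an observation:
#' band set (center/width in nm, with optional secondary response windows
#' emulating out-of-band leakage), an affine digital-number transfer
#' (`dn_gain`, `dn_offset`), additive Gaussian observation noise, a
#' collection window half-width around solar noon, and a multiplicative
#' solar-drift process `1 - drift_amplitude * |t| * w_band` whose per-band
#' sensitivity weights capture the band dependence of illumination and
#' canopy-shadowing changes away from solar noon. The drift multiplier is 1
#' exactly at solar noon.
#'
#' @param platform `"uas_broadband"`, `"radiometer_broadband"` or
#'   `"hyperspectral"`. Only `uas_broadband` emits uncalibrated digital
#'   numbers; the handheld platforms emit reflectance.
#' @param bands data.frame with columns `band`, `center`, `width` (nm);
#'   ignored for hyperspectral sensors.
#' @param leakage optional data.frame `band`, `center`, `width`, `weight`
#'   adding weighted secondary response windows to named bands.
#' @param dn_gain,dn_offset affine DN transfer (reflectance platforms use
#'   gain 1, offset 0).
#' @param noise_sd additive observation noise (DN units for UAS,
#'   reflectance units otherwise).
#' @param window_hours collection-window half-width around solar noon (h).
#' @param drift_amplitude drift slope per hour from solar noon.
#' @param drift_weights named per-band sensitivity weights (default 1 for
#'   every band, the scalar linear drift law). For hyperspectral sensors a
#'   function of wavelength may be supplied.
#' @return a `sensor_model` list.
#' @export
sensor_model <- function(platform = c("uas_broadband", "radiometer_broadband",
                                      "hyperspectral"),
                         bands = default_bands(),
                         leakage = NULL,
                         dn_gain = 1, dn_offset = 0,
                         noise_sd = 0,
                         window_hours = 2,
                         drift_amplitude = 0,
                         drift_weights = NULL) {
  platform <- match.arg(platform)
  if (window_hours <= 0) ps_stop("window_hours must be > 0", "parameter_error")
  if (platform != "uas_broadband" && (dn_gain != 1 || dn_offset != 0))
    ps_stop("only uas_broadband sensors have a DN transfer", "parameter_error")
  structure(list(platform = platform, bands = bands, leakage = leakage,
                 dn_gain = dn_gain, dn_offset = dn_offset,
                 noise_sd = noise_sd, window_hours = window_hours,
                 drift_amplitude = drift_amplitude,
                 drift_weights = drift_weights),
            class = "sensor_model")
}

#' Standard broadband set used throughout the package
#'
#' The five 50 nm-wide bands the index set needs (green 550, red 680,
#' red-edge 700, near-infrared 800, water 970), plus blue 450.
#' @param include_blue include the 450 nm band.
#' @param include_nir include the 800 nm band (dropped for sensors whose
#'   NIR is derived from quantum-efficiency coefficients).
#' @return data.frame with columns `band`, `center`, `width`.
#' @export
default_bands <- function(include_blue = FALSE, include_nir = TRUE) {
  b <- data.frame(
    band = c("R450", "R550", "R680", "R700", "R800", "R970"),
    center = c(450, 550, 680, 700, 800, 970),
    width = 50
  )
  keep <- rep(TRUE, nrow(b))
  if (!include_blue) keep[b$band == "R450"] <- FALSE
  if (!include_nir) keep[b$band == "R800"] <- FALSE
  b[keep, , drop = FALSE]
}

#' Solar-drift multiplier of a sensor channel
#'
#' `1 - drift_amplitude * |t| * w`, floored at 0, where `w` is the per-band
#' (or per-wavelength) drift sensitivity weight (1 when none is set).
#' Exactly 1 at solar noon (`t = 0`).
#'
#' @param sensor a [sensor_model()].
#' @param time_offset_hours signed hours from solar noon.
#' @param band band names (broadband sensors).
#' @param wavelength wavelengths in nm (hyperspectral sensors).
#' @return vector of multiplicative drift factors.
#' @export
drift_multiplier <- function(sensor, time_offset_hours, band = NULL,
                             wavelength = NULL) {
  a <- sensor$drift_amplitude
  if (a == 0 || time_offset_hours == 0)
    return(rep(1, max(length(band), length(wavelength), 1)))
  w <- if (!is.null(band)) {
    dw <- sensor$drift_weights
    if (is.null(dw)) rep(1, length(band))
    else {
      out <- dw[band]
      out[is.na(out)] <- 1
      unname(out)
    }
  } else if (is.function(sensor$drift_weights)) {
    sensor$drift_weights(wavelength)
  } else rep(1, length(wavelength))
  pmax(1 - a * abs(time_offset_hours) * w, 0)
}

#' Band-response mean of a spectrum
#'
#' Mean reflectance over the window `[center - width/2, center + width/2)`
#' (left-closed), plus any weighted secondary (leakage) windows.
#'
#' @param spectrum data.frame with `wavelength` and `reflectance`.
#' @param center,width band center and width (nm).
#' @param leak optional data.frame `center`, `width`, `weight` of secondary
#'   response windows.
#' @return the band value (scalar).
#' @export
band_response <- function(spectrum, center, width = 50, leak = NULL) {
  win_mean <- function(ctr, wd) {
    inside <- spectrum$wavelength >= ctr - wd / 2 &
      spectrum$wavelength < ctr + wd / 2
    if (!any(inside)) ps_stop(sprintf("no samples in band window %g +/- %g nm",
                                      ctr, wd / 2), "coverage_error")
    mean(spectrum$reflectance[inside])
  }
  v <- win_mean(center, width)
  if (!is.null(leak) && nrow(leak))
    v <- v + sum(vapply(seq_len(nrow(leak)), function(i)
      leak$weight[i] * win_mean(leak$center[i], leak$width[i]), numeric(1)))
  v
}

#' Observe one plot through a sensor channel
#'
#' Broadband platforms return, per band, the band-response mean of the true
#' spectrum times the solar-drift multiplier at the given time offset,
#' passed through the sensor's affine DN transfer with additive Gaussian
#' noise. Hyperspectral platforms return the full drifted, noisy curve.
#'
#' @param spectrum a [simulate_canopy_spectrum()] curve (or any data.frame
#'   with `wavelength` and `reflectance`).
#' @param sensor a [sensor_model()].
#' @param time_offset_hours signed hours from solar noon; must lie within
#'   the sensor's collection window.
#' @param seed integer seed for the noise draw.
#' @param plot_id optional identifier carried through.
#' @return a `spectral_observation`: list with `plot_id`, `platform`,
#'   `unit` (`"dn"` or `"reflectance"`), `time_offset_hours` and either
#'   `band_values` (named numeric) or `curve` (data.frame).
#' @export
observe_plot <- function(spectrum, sensor, time_offset_hours = 0, seed = NULL,
                         plot_id = NA_character_) {
  stopifnot(inherits(sensor, "sensor_model"))
  if (abs(time_offset_hours) > sensor$window_hours)
    ps_stop(sprintf("time offset %.2f h outside the %.2f h collection window",
                    time_offset_hours, sensor$window_hours), "scheduling_error")

  if (sensor$platform == "hyperspectral") {
    d <- drift_multiplier(sensor, time_offset_hours,
                          wavelength = spectrum$wavelength)
    noise <- with_seed(seed, stats::rnorm(nrow(spectrum), 0, sensor$noise_sd))
    curve <- data.frame(wavelength = spectrum$wavelength,
                        reflectance = spectrum$reflectance * d + noise)
    return(structure(list(plot_id = plot_id, platform = sensor$platform,
                          unit = "reflectance",
                          time_offset_hours = time_offset_hours,
                          curve = curve),
                     class = "spectral_observation"))
  }

  b <- sensor$bands
  true_means <- vapply(seq_len(nrow(b)), function(i) {
    leak <- if (!is.null(sensor$leakage))
      sensor$leakage[sensor$leakage$band == b$band[i], , drop = FALSE]
    band_response(spectrum, b$center[i], b$width[i], leak)
  }, numeric(1))
  d <- drift_multiplier(sensor, time_offset_hours, band = b$band)
  noise <- with_seed(seed, stats::rnorm(nrow(b), 0, sensor$noise_sd))
  vals <- true_means * d * sensor$dn_gain + sensor$dn_offset + noise
  names(vals) <- b$band
  structure(list(plot_id = plot_id, platform = sensor$platform,
                 unit = if (sensor$platform == "uas_broadband" &&
                            (sensor$dn_gain != 1 || sensor$dn_offset != 0))
                   "dn" else "reflectance",
                 time_offset_hours = time_offset_hours,
                 band_values = vals),
            class = "spectral_observation")
}

#' Define a calibration panel set
#'
#' @param reflectances per-panel true reflectance (strictly increasing,
#'   within \[0.02, 0.85\]); panels are spectrally flat.
#' @return a `panel_set` data.frame with `panel_id` and `true_reflectance`.
#' @export
panel_set <- function(reflectances = c(0.02, 0.11, 0.22, 0.44, 0.85)) {
  if (!length(reflectances)) ps_stop("empty panel set", "input_error")
  if (is.unsorted(reflectances, strictly = TRUE))
    ps_stop("panel reflectances must be strictly increasing", "input_error")
  if (any(reflectances < 0.02 - 1e-12) || any(reflectances > 0.85 + 1e-12))
    ps_stop("panel reflectances must lie within [0.02, 0.85]", "input_error")
  structure(data.frame(panel_id = sprintf("panel%02d", seq_along(reflectances)),
                       true_reflectance = reflectances),
            class = c("panel_set", "data.frame"))
}

#' Observe calibration panels through a sensor channel
#'
#' Applies the same observation model as [observe_plot()] to spectrally
#' flat, constant-reflectance targets, yielding the per-panel, per-band DN
#' table from which an empirical-line calibration is fit.
#'
#' @param panels a [panel_set()].
#' @param sensor a [sensor_model()] (broadband).
#' @param time_offset_hours hours from solar noon.
#' @param seed integer seed.
#' @return data.frame with columns `panel_id`, `band`, `true_reflectance`,
#'   `dn`.
#' @export
observe_panels <- function(panels, sensor, time_offset_hours = 0, seed = NULL) {
  if (!nrow(panels)) ps_stop("empty panel set", "input_error")
  lam <- seq(400, 1050, by = 2.5)
  rows <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(panels)), function(i) {
      flat <- data.frame(wavelength = lam,
                         reflectance = rep(panels$true_reflectance[i],
                                           length(lam)))
      obs <- observe_plot(flat, sensor, time_offset_hours,
                          plot_id = panels$panel_id[i])
      data.frame(panel_id = panels$panel_id[i],
                 band = names(obs$band_values),
                 true_reflectance = panels$true_reflectance[i],
                 dn = unname(obs$band_values))
    }))
  })
  rownames(rows) <- NULL
  rows
}
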