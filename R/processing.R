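#' Quality-control a hyperspectral reflectance curve
#'
#' Screens the sub-1000 nm region for abnormal curves using four
#' independently switchable rules: negative reflectance (< `min_refl`),
#' implausibly high reflectance (> `max_refl`), red-edge inversion (mean
#' reflectance on 760-800 nm below the mean on 660-690 nm, the opposite of
#' any live canopy), and spikes (absolute jump > `max_jump` between
#' adjacent samples). Curves failing any active rule are removed from
#' evaluation downstream.
#'
#' @param curve data.frame with `wavelength` (nm) and `reflectance`; must
#'   cover 400-1000 nm.
#' @param min_refl,max_refl reflectance bounds below 1000 nm.
#' @param max_jump maximum allowed jump between adjacent samples.
#' @param rules character vector of active rules, any of
#'   `"negative_reflectance"`, `"implausible_reflectance"`,
#'   `"red_edge_inversion"`, `"spike"`.
#' @return list with `pass` (logical) and `reasons` (character vector of
#'   failed rules, empty when passing).
#' @export
qc_hyperspectral_curve <- function(curve,
                                   min_refl = -0.01,
                                   max_refl = 1.2,
                                   max_jump = 0.3,
                                   rules = c("negative_reflectance",
                                             "implausible_reflectance",
                                             "red_edge_inversion",
                                             "spike")) {
  if (min(curve$wavelength) > 400 || max(curve$wavelength) < 1000)
    ps_stop("curve must cover 400-1000 nm for quality control",
            "coverage_error")
  below <- curve[curve$wavelength < 1000, ]
  reasons <- character(0)
  if ("negative_reflectance" %in% rules && any(below$reflectance < min_refl))
    reasons <- c(reasons, "negative_reflectance")
  if ("implausible_reflectance" %in% rules && any(below$reflectance > max_refl))
    reasons <- c(reasons, "implausible_reflectance")
  if ("red_edge_inversion" %in% rules) {
    nir <- below$reflectance[below$wavelength >= 760 & below$wavelength <= 800]
    red <- below$reflectance[below$wavelength >= 660 & below$wavelength <= 690]
    if (length(nir) && length(red) && mean(nir) < mean(red))
      reasons <- c(reasons, "red_edge_inversion")
  }
  if ("spike" %in% rules && any(abs(diff(below$reflectance)) > max_jump))
    reasons <- c(reasons, "spike")
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Synthesize a broadband reflectance from a narrowband curve
#'
#' Unweighted mean of all narrowband samples falling inside the band
#' window, `[center - width/2, center + width/2)` (left-closed), the way
#' broadband values matching a multispectral camera are reconstructed from
#' full-range spectro-radiometer curves.
#'
#' @param curve data.frame with `wavelength` and `reflectance`.
#' @param center band center (nm).
#' @param width window width (nm, default 50).
#' @return the window mean (scalar).
#' @export
narrowband_to_broadband <- function(curve, center, width = 50) {
  if (width <= 0) ps_stop("width must be > 0", "parameter_error")
  inside <- curve$wavelength >= center - width / 2 &
    curve$wavelength < center + width / 2
  if (!any(inside))
    ps_stop(sprintf("no narrowband samples in window %g +/- %g nm",
                    center, width / 2), "coverage_error")
  mean(curve$reflectance[inside])
}

#' Synthesize all standard broadbands from a set of plot curves
#'
#' Applies [qc_hyperspectral_curve()] then [narrowband_to_broadband()] to a
#' long table of per-plot curves.
#'
#' @param curves long data.frame `plot_id`, `wavelength`, `reflectance`.
#' @param bands data.frame `band`, `center`, `width` ([default_bands()]).
#' @param qc apply quality control; failing plots get `qc_flag` set and NA
#'   band values.
#' @return wide data.frame: `plot_id`, one column per band, `qc_flag`
#'   (empty string or comma-separated fail reasons).
#' @export
curves_to_broadband <- function(curves, bands = default_bands(), qc = TRUE) {
  out <- lapply(split(curves, curves$plot_id), function(d) {
    d <- d[order(d$wavelength), ]
    flag <- ""
    if (qc) {
      q <- qc_hyperspectral_curve(d)
      if (!q$pass) flag <- paste(q$reasons, collapse = ",")
    }
    vals <- if (nzchar(flag)) rep(NA_real_, nrow(bands))
    else vapply(seq_len(nrow(bands)), function(i)
      narrowband_to_broadband(d, bands$center[i], bands$width[i]), numeric(1))
    row <- as.data.frame(as.list(stats::setNames(vals, bands$band)))
    cbind(data.frame(plot_id = d$plot_id[1]), row,
          data.frame(qc_flag = flag))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Normalize reflectance by within-trial standard deviation
#'
#' Divides each plot's band reflectance by the sample standard deviation
#' (n - 1 denominator) of that band within its trial, the
#' standardization applied to handheld radiometer data. Each trial-band
#' group must have at least two plots and nonzero spread.
#'
#' @param values long data.frame with columns `trial_id`, `band`, `value`
#'   (extra columns pass through).
#' @return the input with a `normalized` column added.
#' @export
normalize_by_trial_sd <- function(values) {
  need <- c("trial_id", "band", "value")
  if (!all(need %in% names(values)))
    ps_stop("values must have columns trial_id, band, value", "input_error")
  key <- interaction(values$trial_id, values$band, drop = TRUE)
  norm <- rep(NA_real_, nrow(values))
  for (ix in split(seq_len(nrow(values)), key)) {
    v <- values$value[ix]
    ok <- !is.na(v)
    if (sum(ok) < 2)
      ps_stop(sprintf("trial-band group %s has < 2 plots",
                      as.character(key[ix[1]])), "degenerate_group_error")
    s <- stats::sd(v[ok])
    if (!is.finite(s) || s == 0)
      ps_stop(sprintf("zero standard deviation in trial-band group %s",
                      as.character(key[ix[1]])), "degenerate_group_error")
    norm[ix] <- v / s
  }
  out <- values
  out$normalized <- norm
  out
}
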