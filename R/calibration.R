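#' Quantum-efficiency coefficients for NIR derivation
#'
#' Coefficients of the sensor-specific linear combination that recovers a
#' near-infrared band from the blue and red channels of a camera whose blue
#' filter passes near-infrared light, together with the normalization
#' coefficient applied to the derived band when indices are computed.
#'
#' @param c_blue,c_red linear-combination coefficients.
#' @param nir_norm normalization divisor (> 0) applied to the derived band.
#' @return a `qe_coefficients` list.
#' @export
qe_coefficients <- function(c_blue = 2.921, c_red = 0.754, nir_norm = 3.07) {
  if (nir_norm <= 0) ps_stop("nir_norm must be > 0", "parameter_error")
  structure(list(c_blue = c_blue, c_red = c_red, nir_norm = nir_norm),
            class = "qe_coefficients")
}

#' Fit an empirical-line calibration from panel readings
#'
#' Relates observed digital numbers to known panel surface reflectance per
#' band, `SR = DN * m + b`. With two or more distinct panels
#' (`method = "multi_panel"`) the slope and intercept are the ordinary
#' least-squares fit of true reflectance on DN. With exactly one panel
#' (`method = "single_panel"`, the simple white-panel strategy) the line is
#' forced through the origin: `m = SR / DN`, `b = 0`.
#'
#' @param panel_dn data.frame with columns `panel_id`, `band`,
#'   `true_reflectance`, `dn` (the output of [observe_panels()]).
#' @param method `"multi_panel"` or `"single_panel"`; the default picks
#'   multi-panel when more than one panel is present.
#' @return a `calibration_model`: data.frame with columns `band`, `m`, `b`,
#'   `r_squared`, `n_panels`, `flag`, and attribute `method`. A fitted
#'   negative slope is returned but flagged (`flag = "negative_slope"`)
#'   with a warning.
#' @examples
#' pd <- data.frame(panel_id = c("a", "b"), band = "R680",
#'                  true_reflectance = c(0.02, 0.85), dn = c(10, 90))
#' fit_empirical_line(pd)
#' @export
fit_empirical_line <- function(panel_dn, method = NULL) {
  need <- c("panel_id", "band", "true_reflectance", "dn")
  if (!all(need %in% names(panel_dn)))
    ps_stop("panel table must have panel_id, band, true_reflectance, dn",
            "input_error")
  n_panels <- length(unique(panel_dn$panel_id))
  if (is.null(method)) method <- if (n_panels >= 2) "multi_panel" else "single_panel"
  method <- match.arg(method, c("multi_panel", "single_panel"))
  if (method == "multi_panel" && n_panels < 2)
    ps_stop("multi-panel calibration needs >= 2 distinct panels", "input_error")
  if (method == "single_panel" && n_panels != 1)
    ps_stop("single-panel calibration needs exactly 1 panel", "input_error")

  fits <- lapply(split(panel_dn, panel_dn$band), function(d) {
    if (method == "single_panel") {
      if (any(d$dn == 0)) ps_stop("single-panel DN of 0 is degenerate",
                                  "degenerate_fit_error")
      data.frame(band = d$band[1], m = d$true_reflectance[1] / d$dn[1], b = 0,
                 r_squared = NA_real_, n_panels = 1L, flag = "")
    } else {
      if (length(unique(d$dn)) < 2)
        ps_stop(sprintf("identical DN across panels for band %s", d$band[1]),
                "degenerate_fit_error")
      fit <- stats::lm(true_reflectance ~ dn, data = d)
      co <- stats::coef(fit)
      r2 <- if (stats::var(d$true_reflectance) > 0)
        suppressWarnings(summary(fit)$r.squared) else NA_real_
      data.frame(band = d$band[1], m = unname(co["dn"]),
                 b = unname(co["(Intercept)"]), r_squared = r2,
                 n_panels = n_panels, flag = "")
    }
  })
  model <- do.call(rbind, fits)
  rownames(model) <- NULL
  neg <- model$m <= 0
  if (any(neg)) {
    model$flag[neg] <- "negative_slope"
    warning(sprintf("negative fitted slope for band(s): %s",
                    paste(model$band[neg], collapse = ", ")))
  }
  structure(model, method = method,
            class = c("calibration_model", "data.frame"))
}

#' Apply an empirical-line calibration to digital numbers
#'
#' `SR = DN * m + b` per band, clipped to \[0, ceiling\] with the number of
#' clipped values reported as attribute `n_clipped`.
#'
#' @param dn_table long data.frame with columns `band` and `dn` (extra
#'   columns such as `plot_id` pass through).
#' @param model a [fit_empirical_line()] model covering every band present.
#' @param ceiling upper clip limit for reflectance (default 1.2, tolerating
#'   specular returns).
#' @return `dn_table` with an `sr` column added; attribute `n_clipped`
#'   counts values clipped at either end.
#' @export
apply_calibration <- function(dn_table, model, ceiling = 1.2) {
  if (!all(c("band", "dn") %in% names(dn_table)))
    ps_stop("dn_table must have columns band and dn", "input_error")
  missing_bands <- setdiff(unique(dn_table$band), model$band)
  if (length(missing_bands))
    ps_stop(sprintf("no calibration for band(s): %s",
                    paste(missing_bands, collapse = ", ")),
            "band_mismatch_error")
  ix <- match(dn_table$band, model$band)
  sr_raw <- dn_table$dn * model$m[ix] + model$b[ix]
  sr <- clamp(sr_raw, 0, ceiling)
  out <- dn_table
  out$sr <- sr
  attr(out, "n_clipped") <- sum(sr != sr_raw)
  out
}

#' Derive a near-infrared band from blue and red reflectance
#'
#' `NIR = c_blue * Blue - c_red * Red`, with negative results floored at 0
#' (count reported as attribute `n_floored`, with a warning). When
#' `normalize = TRUE` the result is divided by the normalization
#' coefficient, the convention used when the derived band feeds index
#' computation.
#'
#' @param blue_sr,red_sr calibrated blue and red surface reflectance.
#' @param coeffs a [qe_coefficients()] object.
#' @param normalize divide by `coeffs$nir_norm`.
#' @return derived NIR reflectance vector with attribute `n_floored`.
#' @examples
#' derive_nir(0.1, 0.1) # 0.2167
#' @export
derive_nir <- function(blue_sr, red_sr, coeffs = qe_coefficients(),
                       normalize = FALSE) {
  raw <- coeffs$c_blue * blue_sr - coeffs$c_red * red_sr
  n_floored <- sum(raw < 0, na.rm = TRUE)
  if (n_floored > 0)
    warning(sprintf("%d derived NIR value(s) below 0 floored", n_floored))
  out <- pmax(raw, 0)
  if (normalize) out <- out / coeffs$nir_norm
  attr(out, "n_floored") <- n_floored
  out
}

#' Serialize / read a calibration model as JSON
#'
#' @param model a `calibration_model`.
#' @param path file path.
#' @return `read_calibration_model` returns the model; the writer returns
#'   `path` invisibly.
#' @export
write_calibration_model <- function(model, path) {
  jsonlite::write_json(
    list(method = attr(model, "method"),
         bands = as.data.frame(model)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_model
#' @export
read_calibration_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(as.data.frame(x$bands), method = x$method,
            class = c("calibration_model", "data.frame"))
}
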