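#' Spectral reflectance indices
#'
#' The five plot-level indices used to proxy canopy vigor, chlorophyll and
#' water status from band reflectance, implemented exactly in their
#' published forms. All are vectorized; undefined values (zero
#' denominators, non-positive radicands) propagate as `NA` rather than
#' errors so plot-level problems never abort a trial-level run.
#'
#' * `ndvi(R800, R680) = (R800 - R680) / (R800 + R680)`
#' * `ndre(R800, R700) = (R800 - R700) / (R800 + R700)`
#' * `tcari(R550, R680, R700) =
#'     3 * ((R700 - R680) - 0.2 * (R700 - R550) * (R700 / R680))`
#' * `nwi(R970, R800) = (R970 - R800) / (R970 + R800)` — lower values
#'   indicate higher canopy water content
#' * `mtvi(R550, R680, R700, R800) = (R700 - R550) /
#'     sqrt((2 * R800 + 1)^2 - (6 * R800 - 5 * sqrt(R680)) - 0.5)`
#'
#' NDVI, NDRE and NWI are invariant to a common rescaling of their two
#' bands; TCARI and MTVI are not.
#'
#' @param R550,R680,R700,R800,R970 band reflectances (green, red,
#'   red-edge, near-infrared, 970 nm water band).
#' @return numeric vector of index values (`NA` where undefined).
#' @name sri
#' @examples
#' ndvi(0.5, 0.1)           # 0.667
#' tcari(0.08, 0.10, 0.20)  # 0.156
#' nwi(0.2, 0.6)            # -0.5
NULL

#' @rdname sri
#' @export
ndvi <- function(R800, R680) {
  den <- R800 + R680
  ifelse(is.na(den) | den <= 0, NA_real_, (R800 - R680) / den)
}

#' @rdname sri
#' @export
ndre <- function(R800, R700) {
  den <- R800 + R700
  ifelse(is.na(den) | den <= 0, NA_real_, (R800 - R700) / den)
}

#' @rdname sri
#' @export
tcari <- function(R550, R680, R700) {
  ifelse(is.na(R680) | R680 == 0, NA_real_,
         3 * ((R700 - R680) - 0.2 * (R700 - R550) * (R700 / R680)))
}

#' @rdname sri
#' @export
nwi <- function(R970, R800) {
  den <- R970 + R800
  ifelse(is.na(den) | den <= 0, NA_real_, (R970 - R800) / den)
}

#' @rdname sri
#' @export
mtvi <- function(R550, R680, R700, R800) {
  rad <- (2 * R800 + 1)^2 - (6 * R800 - 5 * sqrt(pmax(R680, 0))) - 0.5
  ifelse(is.na(rad) | rad <= 0 | R680 < 0, NA_real_,
         (R700 - R550) / sqrt(rad))
}

# Registry: required bands per index.
sri_registry <- function() {
  list(
    ndvi = list(bands = c("R800", "R680"),
                fn = function(d) ndvi(d$R800, d$R680)),
    ndre = list(bands = c("R800", "R700"),
                fn = function(d) ndre(d$R800, d$R700)),
    tcari = list(bands = c("R550", "R680", "R700"),
                 fn = function(d) tcari(d$R550, d$R680, d$R700)),
    nwi = list(bands = c("R970", "R800"),
               fn = function(d) nwi(d$R970, d$R800)),
    mtvi = list(bands = c("R550", "R680", "R700", "R800"),
                fn = function(d) mtvi(d$R550, d$R680, d$R700, d$R800))
  )
}

#' Compute a table of spectral reflectance indices
#'
#' One row per plot; indices whose required bands are absent from the
#' table are skipped with a message (recorded in the `skipped` attribute)
#' so a reduced band set degrades gracefully.
#'
#' @param band_table data.frame with `plot_id` and band columns (`R550`,
#'   `R680`, `R700`, `R800`, `R970` as available).
#' @param indices which indices to compute.
#' @param platform optional platform label carried into the result.
#' @return data.frame `plot_id` (+ `platform`) with one column per
#'   computed index; attributes `skipped` (named list of missing bands per
#'   skipped index) and `provenance`.
#' @export
compute_sri_table <- function(band_table,
                              indices = c("ndvi", "ndre", "tcari", "nwi",
                                          "mtvi"),
                              platform = NULL) {
  if (!"plot_id" %in% names(band_table))
    ps_stop("band_table must have a plot_id column", "schema_error")
  reg <- sri_registry()
  unknown <- setdiff(indices, names(reg))
  if (length(unknown))
    ps_stop(sprintf("unknown index: %s", paste(unknown, collapse = ", ")),
            "schema_error")
  out <- data.frame(plot_id = band_table$plot_id)
  if (!is.null(platform)) out$platform <- platform
  skipped <- list()
  for (ix in indices) {
    missing <- setdiff(reg[[ix]]$bands, names(band_table))
    if (length(missing)) {
      skipped[[ix]] <- missing
      message(sprintf("skipping %s: band(s) %s not in table", ix,
                      paste(missing, collapse = ", ")))
      next
    }
    out[[ix]] <- reg[[ix]]$fn(band_table)
  }
  attr(out, "skipped") <- skipped
  out
}
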