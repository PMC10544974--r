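#' Multi-band raster container
#'
#' A minimal in-memory raster: a named list of band matrices (rows = north
#' to south) on an axis-aligned grid with square pixels. Pixel (i, j) has
#' its center at `x = xmin + (j - 0.5) * res`, `y = ymax - (i - 0.5) * res`.
#'
#' @param bands named list of equal-dimension numeric matrices.
#' @param xmin,ymax coordinates of the top-left corner (m).
#' @param res pixel size (m).
#' @return a `ps_raster` object.
#' @export
ps_raster <- function(bands, xmin = 0, ymax = NULL, res = 0.1) {
  stopifnot(is.list(bands), length(bands) >= 1, !is.null(names(bands)))
  dims <- unique(lapply(bands, dim))
  if (length(dims) != 1) ps_stop("band matrices differ in dimension", "input_error")
  nr <- dims[[1]][1]; nc <- dims[[1]][2]
  if (is.null(ymax)) ymax <- nr * res
  structure(list(bands = bands, nrow = nr, ncol = nc,
                 xmin = xmin, ymax = ymax, res = res,
                 xmax = xmin + nc * res, ymin = ymax - nr * res),
            class = "ps_raster")
}

#' @export
print.ps_raster <- function(x, ...) {
  cat(sprintf("<ps_raster> %d x %d px, %g m/px, bands: %s\n",
              x$nrow, x$ncol, x$res, paste(names(x$bands), collapse = ", ")))
  invisible(x)
}

# Pixel-center coordinate vectors.
raster_xy <- function(r) {
  list(x = r$xmin + (seq_len(r$ncol) - 0.5) * r$res,
       y = r$ymax - (seq_len(r$nrow) - 0.5) * r$res)
}

# Even-odd (ray casting) point-in-polygon test for a closed or open ring.
# px, py are vectors; ring is a 2-column matrix of vertices.
points_in_polygon <- function(px, py, ring) {
  if (all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Simulate a georeferenced orthomosaic for a set of plots
#'
#' Lays plots out on a regular grid of sown rectangles (default 1.5 m wide
#' by 3.5 m long), burns each plot's band values into the pixels of its
#' sown area, fills the remainder with a flat low-NDVI soil spectrum, and
#' returns the raster together with per-plot polygons inset from the sown
#' edges to avoid border pixels.
#'
#' @param band_table data.frame with `plot_id` and one column per band
#'   (reflectance or DN) — typically per-plot values from [observe_plot()].
#' @param n_cols plots per row in the field layout.
#' @param plot_w,plot_l sown plot width and length (m).
#' @param alley alley width between sown plots (m).
#' @param inset polygon inset from the sown edges (m).
#' @param res ground-sampling distance (m; must be <= 0.25 so a plot spans
#'   at least 6 x 14 pixels).
#' @param soil named per-band soil reflectance (defaults give NDVI = 0.1).
#' @param noise_sd per-pixel additive noise (0 = deterministic).
#' @param seed integer seed for pixel noise.
#' @return list with `raster` (a [ps_raster()]), `polygons` (list of
#'   `list(plot_id, coords)` rings) and `layout` (plot corner table).
#' @export
simulate_orthomosaic <- function(band_table,
                                 n_cols = NULL,
                                 plot_w = 1.5, plot_l = 3.5,
                                 alley = 0.5, inset = 0.2,
                                 res = 0.1,
                                 soil = c(R450 = 0.17, R550 = 0.20,
                                          R680 = 0.18, R700 = 0.19,
                                          R800 = 0.22, R970 = 0.21),
                                 noise_sd = 0, seed = NULL) {
  if (res > 0.25)
    ps_stop("ground-sampling distance must be <= 0.25 m", "parameter_error")
  band_names <- setdiff(names(band_table), "plot_id")
  if (!length(band_names)) ps_stop("band_table has no band columns", "input_error")
  if (!all(band_names %in% names(soil)))
    ps_stop("soil reflectance missing for some bands", "input_error")
  n <- nrow(band_table)
  if (is.null(n_cols)) n_cols <- max(1L, ceiling(sqrt(n)))
  n_rows <- ceiling(n / n_cols)

  cell_w <- plot_w + alley
  cell_l <- plot_l + alley
  width <- n_cols * cell_w + alley
  height <- n_rows * cell_l + alley
  nc <- ceiling(width / res)
  nr <- ceiling(height / res)

  # sown rectangle of plot k (row-major layout)
  k <- seq_len(n)
  col_k <- (k - 1) %% n_cols
  row_k <- (k - 1) %/% n_cols
  x0 <- alley + col_k * cell_w
  y0 <- alley + row_k * cell_l
  layout <- data.frame(plot_id = band_table$plot_id,
                       xmin = x0, xmax = x0 + plot_w,
                       ymin = y0, ymax = y0 + plot_l)

  xy <- list(x = (seq_len(nc) - 0.5) * res,
             y = nr * res - (seq_len(nr) - 0.5) * res)
  px <- matrix(xy$x, nr, nc, byrow = TRUE)
  py <- matrix(xy$y, nr, nc)

  bands <- with_seed(seed, {
    lapply(stats::setNames(band_names, band_names), function(b) {
      m <- matrix(soil[[b]], nr, nc)
      for (i in k) {
        sel <- px >= layout$xmin[i] & px < layout$xmax[i] &
          py >= layout$ymin[i] & py < layout$ymax[i]
        m[sel] <- band_table[[b]][i]
      }
      if (noise_sd > 0) m <- m + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
      m
    })
  })

  polygons <- lapply(k, function(i) {
    xa <- layout$xmin[i] + inset; xb <- layout$xmax[i] - inset
    ya <- layout$ymin[i] + inset; yb <- layout$ymax[i] - inset
    list(plot_id = band_table$plot_id[i],
         coords = cbind(x = c(xa, xb, xb, xa, xa),
                        y = c(ya, ya, yb, yb, ya)))
  })
  check_polygon_overlap(polygons)

  list(raster = ps_raster(bands, xmin = 0, ymax = nr * res, res = res),
       polygons = polygons, layout = layout)
}

# Bounding-box overlap check (rectangular plot polygons).
check_polygon_overlap <- function(polygons) {
  if (length(polygons) < 2) return(invisible(TRUE))
  bb <- t(vapply(polygons, function(p)
    c(min(p$coords[, 1]), max(p$coords[, 1]),
      min(p$coords[, 2]), max(p$coords[, 2])), numeric(4)))
  n <- nrow(bb)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    hit <- bb[j, 1] < bb[i, 2] & bb[j, 2] > bb[i, 1] &
      bb[j, 3] < bb[i, 4] & bb[j, 4] > bb[i, 3]
    if (any(hit))
      ps_stop(sprintf("plot polygons overlap: %s and %s",
                      polygons[[i]]$plot_id, polygons[[j[which(hit)[1]]]]$plot_id),
              "layout_error")
  }
  invisible(TRUE)
}

#' Compute a normalized-difference index raster
#'
#' @param raster a [ps_raster()] containing both bands.
#' @param nir_band,red_band band names (defaults `R800`, `R680` give NDVI).
#' @return matrix of index values.
#' @export
raster_index <- function(raster, nir_band = "R800", red_band = "R680") {
  if (!all(c(nir_band, red_band) %in% names(raster$bands)))
    ps_stop("raster lacks the bands needed by the index", "band_mismatch_error")
  a <- raster$bands[[nir_band]]; b <- raster$bands[[red_band]]
  out <- (a - b) / (a + b)
  out[a + b <= 0] <- NA_real_
  out
}

#' Mask soil pixels by index threshold
#'
#' Marks pixels whose NDVI (by default) falls below a threshold as soil.
#' When plot polygons are supplied, the per-plot masked fraction is
#' reported; plots with every pixel masked are flagged.
#'
#' @param raster a [ps_raster()].
#' @param polygons optional polygon list as from [simulate_orthomosaic()].
#' @param threshold index threshold below which a pixel is soil
#'   (default 0.3).
#' @param nir_band,red_band bands of the thresholding index.
#' @return list with `mask` (logical matrix, TRUE = masked/soil),
#'   `masked_fraction` (per-plot data.frame with `plot_id`,
#'   `masked_fraction`, `all_masked`) when polygons are given.
#' @export
mask_soil <- function(raster, polygons = NULL, threshold = 0.3,
                      nir_band = "R800", red_band = "R680") {
  idx <- raster_index(raster, nir_band, red_band)
  mask <- is.na(idx) | idx < threshold
  out <- list(mask = mask, threshold = threshold)
  if (!is.null(polygons)) {
    xy <- raster_xy(raster)
    px <- matrix(xy$x, raster$nrow, raster$ncol, byrow = TRUE)
    py <- matrix(xy$y, raster$nrow, raster$ncol)
    out$masked_fraction <- do.call(rbind, lapply(polygons, function(p) {
      inside <- points_in_polygon(as.vector(px), as.vector(py), p$coords)
      mf <- mean(as.vector(mask)[inside])
      data.frame(plot_id = p$plot_id, masked_fraction = mf,
                 all_masked = mf >= 1)
    }))
  }
  out
}

#' Extract per-plot band means from a raster
#'
#' Averages, for every polygon and band, the pixels whose centers fall
#' inside the polygon (pixel-center rule), skipping masked pixels. Plots
#' whose pixels are all masked get NA means and a flag.
#'
#' @param raster a [ps_raster()].
#' @param polygons polygon list (`list(plot_id, coords)` per plot).
#' @param mask optional logical matrix (TRUE = exclude pixel).
#' @return data.frame: `plot_id`, one column per band, `n_pixels` (used),
#'   `all_masked`.
#' @export
extract_plot_means <- function(raster, polygons, mask = NULL) {
  xy <- raster_xy(raster)
  px <- as.vector(matrix(xy$x, raster$nrow, raster$ncol, byrow = TRUE))
  py <- as.vector(matrix(xy$y, raster$nrow, raster$ncol))
  rows <- lapply(polygons, function(p) {
    inside <- points_in_polygon(px, py, p$coords)
    if (!any(inside))
      ps_stop(sprintf("polygon for plot %s covers no pixel centers",
                      p$plot_id), "extraction_error")
    use <- inside
    if (!is.null(mask)) use <- use & !as.vector(mask)
    vals <- vapply(raster$bands, function(m)
      if (any(use)) mean(as.vector(m)[use]) else NA_real_, numeric(1))
    cbind(data.frame(plot_id = p$plot_id),
          as.data.frame(as.list(vals)),
          data.frame(n_pixels = sum(use), all_masked = !any(use)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a raster as multi-page TIFF with a world file
#'
#' Bands are stored as 32-bit float TIFF pages (one page per band, in the
#' order of the `.bands.json` sidecar); georeferencing is written to an
#' ESRI world file (`.tfw`) alongside.
#'
#' @param raster a [ps_raster()].
#' @param path output path ending in `.tif`.
#' @return `path`, invisibly.
#' @export
write_raster_tiff <- function(raster, path) {
  tiff::writeTIFF(unname(raster$bands), path, bits.per.sample = 32L,
                  reduce = FALSE)
  tfw <- sub("\\.tif{1,2}$", ".tfw", path)
  writeLines(format(c(raster$res, 0, 0, -raster$res,
                      raster$xmin + raster$res / 2,
                      raster$ymax - raster$res / 2),
                    scientific = FALSE), tfw)
  jsonlite::write_json(names(raster$bands),
                       sub("\\.tif{1,2}$", ".bands.json", path))
  invisible(path)
}

#' Read a raster written by [write_raster_tiff()]
#'
#' @param path `.tif` path with its `.tfw` and `.bands.json` sidecars.
#' @return a [ps_raster()].
#' @export
read_raster_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  bands <- as.character(jsonlite::read_json(
    sub("\\.tif{1,2}$", ".bands.json", path), simplifyVector = TRUE))
  tfw <- as.numeric(readLines(sub("\\.tif{1,2}$", ".tfw", path)))
  res <- tfw[1]
  ps_raster(stats::setNames(pages, bands),
            xmin = tfw[5] - res / 2, ymax = tfw[6] + res / 2, res = res)
}

#' Write plot polygons as GeoJSON
#'
#' One `Feature` per plot with a `plot_id` property and a `Polygon`
#' geometry in the raster's planar coordinates.
#'
#' @param polygons polygon list (`list(plot_id, coords)`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_polygons_geojson <- function(polygons, path) {
  features <- lapply(polygons, function(p) {
    ring <- lapply(seq_len(nrow(p$coords)), function(i)
      c(p$coords[i, 1], p$coords[i, 2]))
    list(type = "Feature",
         properties = list(plot_id = p$plot_id),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read plot polygons from GeoJSON
#'
#' @param path GeoJSON file with `Polygon` features carrying a `plot_id`
#'   property.
#' @return polygon list (`list(plot_id, coords)` per feature).
#' @export
read_polygons_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  lapply(g$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], function(pt)
      c(pt[[1]], pt[[2]])))
    colnames(ring) <- c("x", "y")
    list(plot_id = f$properties$plot_id, coords = ring)
  })
}
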