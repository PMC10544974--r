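# Orthomosaic simulation, zonal extraction, soil masking, and the writers.

make_band_table <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(plot_id = sprintf("P%03d", seq_len(n)),
             R550 = runif(n, 0.05, 0.12), R680 = runif(n, 0.03, 0.10),
             R700 = runif(n, 0.06, 0.15), R800 = runif(n, 0.35, 0.55),
             R970 = runif(n, 0.30, 0.50))
}

test_that("noiseless zonal means equal the generating plot values exactly", {
  bt <- make_band_table(12)
  om <- simulate_orthomosaic(bt, n_cols = 4)
  zon <- extract_plot_means(om$raster, om$polygons)
  expect_equal(zon$plot_id, bt$plot_id)
  for (b in c("R550", "R680", "R700", "R800", "R970"))
    expect_equal(zon[[b]], bt[[b]], tolerance = 1e-12)
  expect_true(all(zon$n_pixels >= 6 * 14)) # plot spans enough pixels
})

test_that("the requested number of polygons is emitted and georeferenced", {
  bt <- make_band_table(195)
  om <- simulate_orthomosaic(bt, n_cols = 15)
  expect_length(om$polygons, 195)
  # polygons lie inside the raster extent
  for (p in om$polygons[c(1, 100, 195)]) {
    expect_true(all(p$coords[, 1] >= om$raster$xmin &
                      p$coords[, 1] <= om$raster$xmax))
    expect_true(all(p$coords[, 2] >= om$raster$ymin &
                      p$coords[, 2] <= om$raster$ymax))
  }
})

test_that("zonal means match a brute-force pixel-center enumeration", {
  # checkerboard fixture with a hand-placed polygon
  m <- matrix(rep(c(1, 2), length.out = 100), 10, 10)
  r <- ps_raster(list(V = m), xmin = 0, ymax = 10, res = 1)
  ring <- cbind(x = c(2.2, 7.8, 7.8, 2.2, 2.2), y = c(1.2, 1.2, 6.4, 6.4, 1.2))
  got <- extract_plot_means(r, list(list(plot_id = "q", coords = ring)))
  # oracle: enumerate all pixel centers
  vals <- c()
  for (i in 1:10) for (j in 1:10) {
    cx <- j - 0.5; cy <- 10 - i + 0.5
    if (cx > 2.2 && cx < 7.8 && cy > 1.2 && cy < 6.4)
      vals <- c(vals, m[i, j])
  }
  expect_equal(got$V, mean(vals))
  expect_equal(got$n_pixels, length(vals))
})

test_that("soil model sits below the vegetation threshold everywhere", {
  bt <- make_band_table(4)
  om <- simulate_orthomosaic(bt, n_cols = 2)
  msk <- mask_soil(om$raster, om$polygons)
  ndvi_map <- raster_index(om$raster)
  # every pixel outside the sown rectangles is soil; masked, NDVI ~ 0.1
  xy <- phenospectra:::raster_xy(om$raster)
  px <- matrix(xy$x, om$raster$nrow, om$raster$ncol, byrow = TRUE)
  py <- matrix(xy$y, om$raster$nrow, om$raster$ncol)
  in_any <- Reduce(`|`, lapply(seq_len(nrow(om$layout)), function(i)
    px >= om$layout$xmin[i] & px < om$layout$xmax[i] &
      py >= om$layout$ymin[i] & py < om$layout$ymax[i]))
  expect_true(all(msk$mask[!in_any]))
  expect_equal(mean(ndvi_map[!in_any]), 0.1, tolerance = 1e-12)
  # vegetated plots (NDVI ~ 0.6-0.9 here) are unmasked
  expect_equal(msk$masked_fraction$masked_fraction, rep(0, 4))
})

test_that("masking recovers canopy-only means on a half-soil plot", {
  # one polygon deliberately drawn over half canopy, half soil
  canopy <- c(R680 = 0.05, R800 = 0.50)
  soil <- c(R680 = 0.18, R800 = 0.22)
  m680 <- matrix(soil["R680"], 10, 20); m800 <- matrix(soil["R800"], 10, 20)
  m680[, 1:10] <- canopy["R680"]; m800[, 1:10] <- canopy["R800"]
  r <- ps_raster(list(R680 = m680, R800 = m800), res = 0.1)
  ring <- cbind(x = c(0.01, 1.99, 1.99, 0.01, 0.01),
                y = c(0.01, 0.01, 0.99, 0.99, 0.01))
  poly <- list(list(plot_id = "h", coords = ring))
  blend <- extract_plot_means(r, poly)
  expect_equal(blend$R800, mean(c(canopy["R800"], soil["R800"])),
               tolerance = 1e-12, ignore_attr = TRUE)
  msk <- mask_soil(r, poly)
  clean <- extract_plot_means(r, poly, msk$mask)
  expect_equal(clean$R800, unname(canopy["R800"]), tolerance = 1e-12)
  expect_equal(clean$R680, unname(canopy["R680"]), tolerance = 1e-12)
  expect_equal(msk$masked_fraction$masked_fraction, 0.5)
})

test_that("fully masked plots are flagged with missing means", {
  r <- ps_raster(list(R680 = matrix(0.18, 5, 5), R800 = matrix(0.22, 5, 5)),
                 res = 0.2)
  poly <- list(list(plot_id = "s",
                    coords = cbind(x = c(0.05, 0.95, 0.95, 0.05, 0.05),
                                   y = c(0.05, 0.05, 0.95, 0.95, 0.05))))
  msk <- mask_soil(r, poly)
  expect_true(msk$masked_fraction$all_masked)
  out <- extract_plot_means(r, poly, msk$mask)
  expect_true(out$all_masked)
  expect_true(is.na(out$R800))
})

test_that("masking cannot worsen NDVI ordering against the latent truth", {
  tr <- small_trial(n_entries = 8, x = 1, r = 2, sigma_eps2 = 0.5)
  pv <- tr$sim$plot_values
  # order-preserving squash keeps every canopy above the soil threshold so
  # no plot is masked away entirely
  pv$latent_trait <- 0.5 + 2 * plogis(pv$latent_trait)
  bands <- do.call(rbind, lapply(seq_len(nrow(pv)), function(i) {
    sp <- simulate_canopy_spectrum(pv$latent_trait[i], 0)
    data.frame(plot_id = pv$plot_id[i],
               R680 = band_response(sp, 680, 50),
               R800 = band_response(sp, 800, 50))
  }))
  # polygons widened past the sown edge so soil contaminates the raw means
  om <- simulate_orthomosaic(bands, n_cols = 4, inset = -0.2)
  msk <- mask_soil(om$raster, om$polygons)
  raw <- extract_plot_means(om$raster, om$polygons)
  cln <- extract_plot_means(om$raster, om$polygons, msk$mask)
  inversions <- function(vals) {
    ord <- pv$latent_trait[match(raw$plot_id, pv$plot_id)]
    sum(outer(vals, vals, `<`) & outer(ord, ord, `>`))
  }
  expect_lte(inversions(ndvi(cln$R800, cln$R680)),
             inversions(ndvi(raw$R800, raw$R680)))
})

test_that("overlapping plot polygons are a layout error", {
  polys <- list(
    list(plot_id = "a", coords = cbind(x = c(0, 2, 2, 0, 0),
                                       y = c(0, 0, 2, 2, 0))),
    list(plot_id = "b", coords = cbind(x = c(1, 3, 3, 1, 1),
                                       y = c(1, 1, 3, 3, 1))))
  expect_error(phenospectra:::check_polygon_overlap(polys),
               class = "layout_error")
})

test_that("coarse ground-sampling distances are refused", {
  expect_error(simulate_orthomosaic(make_band_table(4), res = 0.5),
               class = "parameter_error")
})

test_that("rasters and polygons survive their file round trips", {
  bt <- make_band_table(6)
  om <- simulate_orthomosaic(bt, n_cols = 3)
  tif <- withr::local_tempfile(fileext = ".tif")
  write_raster_tiff(om$raster, tif)
  back <- read_raster_tiff(tif)
  expect_equal(names(back$bands), names(om$raster$bands))
  expect_equal(back$bands$R800, om$raster$bands$R800, tolerance = 1e-6)
  expect_equal(back$res, om$raster$res)
  expect_equal(back$xmin, om$raster$xmin)

  gj <- withr::local_tempfile(fileext = ".geojson")
  write_polygons_geojson(om$polygons, gj)
  polys <- read_polygons_geojson(gj)
  expect_length(polys, 6)
  expect_equal(polys[[1]]$plot_id, om$polygons[[1]]$plot_id)
  expect_equal(polys[[1]]$coords, om$polygons[[1]]$coords,
               ignore_attr = TRUE)
  # extraction through the round-tripped artifacts still matches
  zon <- extract_plot_means(back, polys)
  expect_equal(zon$R800, bt$R800, tolerance = 1e-6)
})
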