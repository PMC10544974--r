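test_that("canopy spectra satisfy the vegetation-shape invariants", {
  for (latent in c(-6, -1, 0, 1.5, 4)) {
    sp <- simulate_canopy_spectrum(latent, 0)
    expect_true(all(sp$reflectance >= 0 & sp$reflectance <= 1.2))
    # local minimum in the red absorption region, below the NIR shoulder
    sub <- sp[sp$wavelength >= 600 & sp$wavelength <= 750, ]
    wmin <- sub$wavelength[which.min(sub$reflectance)]
    expect_gt(wmin, 620)
    expect_lt(wmin, 720)
    r680 <- band_response(sp, 680, 50)
    r800 <- band_response(sp, 800, 50)
    expect_lt(r680, r800)
    # monotone red-edge rise
    seg <- sp$reflectance[sp$wavelength >= 680 & sp$wavelength <= 780]
    expect_true(all(diff(seg) > 0))
  }
})

test_that("NDVI from the curve is strictly increasing in the latent trait", {
  lat <- seq(-4, 4, by = 0.5)
  nd <- vapply(lat, function(l) {
    sp <- simulate_canopy_spectrum(l, 0)
    ndvi(band_response(sp, 800, 50), band_response(sp, 680, 50))
  }, numeric(1))
  expect_true(all(diff(nd) > 0))
})

test_that("degenerate canopy at the latent minimum is soil-like", {
  sp <- simulate_canopy_spectrum(-50, 0)
  expect_lt(ndvi(band_response(sp, 800, 50), band_response(sp, 680, 50)), 0.3)
})

test_that("higher water driver lowers the 970 nm band", {
  r <- vapply(seq(-3, 3), function(w)
    band_response(simulate_canopy_spectrum(1, w), 970, 50), numeric(1))
  expect_true(all(diff(r) < 0))
})

test_that("spectra are reproducible under a fixed seed", {
  a <- simulate_canopy_spectrum(1, 0, seed = 3, noise_sd = 0.01)
  b <- simulate_canopy_spectrum(1, 0, seed = 3, noise_sd = 0.01)
  expect_identical(a, b)
})

test_that("noiseless identity channel returns band-window means", {
  sp <- veg_curve()
  obs <- observe_plot(sp, identity_sensor(), 0, plot_id = "x")
  for (b in names(obs$band_values)) {
    ctr <- default_bands()$center[default_bands()$band == b]
    expect_equal(unname(obs$band_values[b]), band_response(sp, ctr, 50))
  }
  expect_identical(obs$unit, "reflectance")
})

test_that("linear drift law has its closed form and is 1 at solar noon", {
  s <- sensor_model("radiometer_broadband", noise_sd = 0, window_hours = 3,
                    drift_amplitude = 0.05)
  expect_equal(unname(drift_multiplier(s, 0, band = "R680")), 1)
  expect_equal(unname(drift_multiplier(s, 2, band = "R680")), 0.90)
  sp <- veg_curve()
  o0 <- observe_plot(sp, s, 0)
  o2 <- observe_plot(sp, s, 2)
  expect_equal(unname(o2$band_values / o0$band_values),
               rep(0.90, length(o0$band_values)))
})

test_that("per-band drift weights scale the drift law", {
  s <- sensor_model("radiometer_broadband", noise_sd = 0, window_hours = 3,
                    drift_amplitude = 0.05,
                    drift_weights = c(R680 = 0.5, R800 = 1.5))
  d <- drift_multiplier(s, 2, band = c("R680", "R800", "R970"))
  expect_equal(d, c(1 - 0.05 * 2 * 0.5, 1 - 0.05 * 2 * 1.5, 0.90))
})

test_that("observations outside the collection window are refused", {
  expect_error(observe_plot(veg_curve(), identity_sensor(window_hours = 2), 2.5),
               class = "scheduling_error")
})

test_that("uncalibrated DN observations are flagged as such", {
  s <- sensor_model("uas_broadband", dn_gain = 100, dn_offset = 500,
                    noise_sd = 0, window_hours = 2)
  obs <- observe_plot(veg_curve(), s, 0)
  expect_identical(obs$unit, "dn")
  expect_true(all(obs$band_values > 1.2))
})

test_that("repeated observation dispersion grows with the window length", {
  # the same plot observed across increasingly long collection windows:
  # drift makes repeated readings disagree more
  sp <- veg_curve()
  spans <- c(0.25, 1, 2, 3)
  mad_of_span <- vapply(spans, function(w) {
    s <- sensor_model("radiometer_broadband", noise_sd = 0, window_hours = 3,
                      drift_amplitude = 0.05,
                      drift_weights = c(R550 = 1, R680 = 0.55, R700 = 0.8,
                                        R800 = 1.35, R970 = 1.45))
    times <- seq(-w, w, length.out = 11)
    vals <- vapply(times, function(t)
      unname(observe_plot(sp, s, t)$band_values["R800"]), numeric(1))
    mean(abs(vals - mean(vals)))
  }, numeric(1))
  expect_true(all(diff(mad_of_span) > 0))
})

test_that("hyperspectral observation returns the full drifted curve", {
  s <- sensor_model("hyperspectral", noise_sd = 0, window_hours = 3,
                    drift_amplitude = 0.1)
  sp <- veg_curve()
  obs <- observe_plot(sp, s, 1)
  expect_equal(nrow(obs$curve), nrow(sp))
  expect_equal(obs$curve$reflectance, sp$reflectance * 0.9)
})

test_that("panel observations follow the same channel arithmetic", {
  s_id <- identity_sensor()
  p <- panel_set(c(0.02, 0.85))
  tab <- observe_panels(p, s_id, seed = 1)
  expect_equal(tab$dn, tab$true_reflectance)

  s_dn <- sensor_model("uas_broadband", dn_gain = 1000, dn_offset = 0,
                       noise_sd = 0, window_hours = 2)
  tab2 <- observe_panels(panel_set(0.85), s_dn, seed = 1)
  expect_equal(unique(tab2$dn), 850)

  # replicate noisy observations of one panel stay distinct rows
  s_noisy <- sensor_model("radiometer_broadband", noise_sd = 0.01,
                          window_hours = 2)
  two <- rbind(observe_panels(panel_set(0.85), s_noisy, seed = 1),
               observe_panels(panel_set(0.85), s_noisy, seed = 2))
  expect_equal(length(unique(two$panel_id)), 1)
  expect_false(any(duplicated(two$dn)))
})

test_that("panel sets enforce their reflectance range and ordering", {
  expect_error(panel_set(numeric(0)), class = "input_error")
  expect_error(panel_set(c(0.5, 0.2)), class = "input_error")
  expect_error(panel_set(c(0.01, 0.5)), class = "input_error")
})
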