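# Shared fixtures, all built in code.

# A small balanced alpha-lattice with simulated genetics.
small_trial <- function(n_entries = 30, x = 2, r = 2, seed = 42,
                        sigma_G2 = 4, sigma_GE2 = 1, sigma_eps2 = 2) {
  design <- generate_trial_design("alpha_lattice", n_entries = n_entries,
                                  r = r, x = x, seed = seed)
  sim <- simulate_genetic_values(design, sigma_G2 = sigma_G2,
                                 sigma_GE2 = sigma_GE2,
                                 sigma_eps2 = sigma_eps2,
                                 sigma_rep2 = 0, sigma_block2 = 0,
                                 seed = seed + 1)
  list(design = design, sim = sim)
}

# Identity observation channel: reflectance in, reflectance out.
identity_sensor <- function(bands = default_bands(), window_hours = 3) {
  sensor_model("radiometer_broadband", bands = bands, noise_sd = 0,
               window_hours = window_hours, drift_amplitude = 0)
}

# A healthy vegetation curve fixture.
veg_curve <- function(latent = 1.5, water = 0) {
  simulate_canopy_spectrum(latent, water)
}

# Random band tables for index property tests.
random_band_table <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(plot_id = sprintf("p%04d", seq_len(n)),
             R550 = runif(n, 0.02, 0.6), R680 = runif(n, 0.02, 0.6),
             R700 = runif(n, 0.02, 0.6), R800 = runif(n, 0.05, 0.9),
             R970 = runif(n, 0.05, 0.9))
}
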