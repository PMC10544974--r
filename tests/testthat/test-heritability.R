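test_that("heritability formula reproduces hand-computed values", {
  h <- broad_sense_heritability(list(sigma_G2 = 2, sigma_GE2 = 1,
                                     sigma_eps2 = 3), x = 2, r = 3)
  expect_equal(h$H2, 2 / (2 + 0.5 + 0.5), tolerance = 1e-15)
  expect_equal(h$H2, 0.6667, tolerance = 1e-4)

  expect_equal(broad_sense_heritability(list(sigma_G2 = 1, sigma_GE2 = 0,
                                             sigma_eps2 = 0),
                                        x = 1, r = 1)$H2, 1)
  expect_equal(broad_sense_heritability(list(sigma_G2 = 0, sigma_GE2 = 1,
                                             sigma_eps2 = 1),
                                        x = 2, r = 2)$H2, 0)
  expect_error(broad_sense_heritability(list(sigma_G2 = 0, sigma_GE2 = 0,
                                             sigma_eps2 = 0), x = 1, r = 1),
               class = "undefined_value_error")
  expect_error(broad_sense_heritability(list(sigma_G2 = 1, sigma_GE2 = 0,
                                             sigma_eps2 = 0), x = 0, r = 1),
               class = "parameter_error")
})

test_that("H2 is monotone in its components over a parameter grid", {
  sG <- seq(0.2, 4, length.out = 8)
  h_of_g <- vapply(sG, function(g)
    broad_sense_heritability(list(sigma_G2 = g, sigma_GE2 = 1,
                                  sigma_eps2 = 2), x = 2, r = 3)$H2,
    numeric(1))
  expect_true(all(diff(h_of_g) > 0))
  sE <- seq(0.2, 6, length.out = 8)
  h_of_e <- vapply(sE, function(e)
    broad_sense_heritability(list(sigma_G2 = 1, sigma_GE2 = 1,
                                  sigma_eps2 = e), x = 2, r = 3)$H2,
    numeric(1))
  expect_true(all(diff(h_of_e) < 0))
  # and increasing in x and r (more environments/replicates shrink noise)
  h_x <- vapply(1:5, function(x)
    broad_sense_heritability(list(sigma_G2 = 1, sigma_GE2 = 1,
                                  sigma_eps2 = 2), x = x, r = 2)$H2,
    numeric(1))
  expect_true(all(diff(h_x) > 0))
})

test_that("expected-mean-squares estimators match a hand-built EMS oracle", {
  # 5 genotypes x 2 environments x 2 reps, fully balanced
  set.seed(31)
  g <- rep(sprintf("g%d", 1:5), each = 4)
  e <- rep(rep(c("E1", "E2"), each = 2), 5)
  rp <- rep(c("R1", "R2"), 10)
  y <- rnorm(20, sd = 2) + rep(rnorm(5, sd = 2), each = 4) +
    as.numeric(factor(paste(g, e))) * 0.3
  d <- data.frame(genotype_id = g, environment_id = e, replicate_id = rp,
                  block_id = paste(e, rp), value = y)
  vc <- estimate_variance_components(d, method = "anova_moments")

  # oracle: explicit sum-of-squares arithmetic
  x <- 2; r <- 2; ng <- 5
  gm <- mean(y)
  mg <- tapply(y, g, mean); me <- tapply(y, e, mean)
  mge <- tapply(y, paste(g, e), mean)
  ss_g <- x * r * sum((mg - gm)^2)
  ss_ge <- r * sum((mge - rep(mg, each = 0) - 0)^2) # filled in below
  # interaction SS: r * sum over cells of (cell - g - e + grand)^2
  ss_ge <- r * sum((mge - mg[sub(" .*", "", names(mge))] -
                      me[sub(".* ", "", names(mge))] + gm)^2)
  ms_g <- ss_g / (ng - 1)
  ms_ge <- ss_ge / ((ng - 1) * (x - 1))
  cell_means <- mge[paste(g, e)]
  ss_within <- sum((y - cell_means)^2)
  # residual after removing the env:rep stratum, as the model does
  a <- anova(stats::aov(value ~ environment_id + environment_id:replicate_id +
                          genotype_id + genotype_id:environment_id, data = d))
  ms_e <- a["Residuals", "Mean Sq"]
  expect_equal(vc$sigma_eps2, ms_e, tolerance = 1e-10)
  expect_equal(vc$sigma_GE2, max(0, (ms_ge - ms_e) / r), tolerance = 1e-10)
  expect_equal(vc$sigma_G2, max(0, (ms_g - ms_ge) / (x * r)),
               tolerance = 1e-10)
})

test_that("REML and moments estimators agree on balanced data", {
  tr <- small_trial(n_entries = 250, x = 2, r = 2, seed = 101,
                    sigma_G2 = 4, sigma_GE2 = 1, sigma_eps2 = 2)
  pt <- tr$sim$plot_values
  pt$value <- pt$latent_trait
  reml <- estimate_variance_components(pt, method = "reml")
  mom <- estimate_variance_components(pt, method = "anova_moments")
  for (comp in c("sigma_G2", "sigma_GE2", "sigma_eps2"))
    expect_equal(reml[[comp]], mom[[comp]], tolerance = 0.02)
})

test_that("degenerate all-equal data yields all-zero components", {
  d <- data.frame(genotype_id = rep(c("a", "b"), 4),
                  environment_id = rep(c("E1", "E2"), each = 4),
                  replicate_id = rep(c("R1", "R2"), each = 2),
                  block_id = "b1", value = 3)
  vc <- estimate_variance_components(d)
  expect_equal(vc$sigma_G2, 0)
  expect_equal(vc$sigma_GE2, 0)
  expect_equal(vc$sigma_eps2, 0)
})

test_that("single-environment data collapses the G-by-E term", {
  tr <- small_trial(n_entries = 40, x = 1, r = 2, seed = 8)
  pt <- tr$sim$plot_values; pt$value <- pt$latent_trait
  expect_message(vc <- estimate_variance_components(pt), "single environment")
  expect_equal(vc$sigma_GE2, 0)
  expect_gt(vc$sigma_G2, 0)
})

test_that("variance components are recovered in an unreplicated augmented trial", {
  # genotype variance identified through the repeated checks and the two
  # environments; the H2 convention for unreplicated entries uses r = 1
  d <- generate_trial_design("augmented_with_checks", n_entries = 150,
                             n_checks = 10, checks_rep = 6, x = 2, seed = 77)
  sim <- simulate_genetic_values(d, sigma_G2 = 1, sigma_GE2 = 0.2,
                                 sigma_eps2 = 0.4, sigma_rep2 = 0,
                                 sigma_block2 = 0, seed = 78)
  pt <- sim$plot_values; pt$value <- pt$latent_trait
  vc <- estimate_variance_components(pt)
  expect_true(vc$converged)
  expect_equal(vc$sigma_G2, 1, tolerance = 0.35)
  h <- broad_sense_heritability(vc, x = 2, r = 1)
  expect_true(h$H2 > 0 && h$H2 < 1)
})

test_that("adjusted entry means equal raw means in orthogonal designs", {
  # complete blocks (block = replicate): genotype and block are orthogonal,
  # so block adjustment leaves genotype means untouched
  tr <- small_trial(n_entries = 12, x = 1, r = 2, seed = 55, sigma_eps2 = 1)
  pt <- tr$sim$plot_values; pt$value <- pt$latent_trait
  pt$block_id <- pt$replicate_id
  adj <- adjusted_entry_means(pt)
  raw <- tapply(pt$value, pt$genotype_id, mean)
  expect_equal(adj$adjusted_mean, as.numeric(raw[adj$genotype_id]),
               tolerance = 1e-10)
})

test_that("adjusted means beat raw means under an inflated block effect", {
  d <- generate_trial_design("alpha_lattice", n_entries = 24, r = 2,
                             block_size = 6, x = 1, seed = 66)
  sim <- simulate_genetic_values(d, sigma_G2 = 1, sigma_GE2 = 0,
                                 sigma_eps2 = 0.1, sigma_rep2 = 0,
                                 sigma_block2 = 0, seed = 67)
  pt <- sim$plot_values; pt$value <- pt$latent_trait
  # inflate one block by a large constant
  bump <- unique(pt$block_id)[1]
  pt$value[pt$block_id == bump] <- pt$value[pt$block_id == bump] + 5
  truth <- with(sim$ground_truth, setNames(genotype_effects$trait,
                                           genotype_effects$genotype_id))
  truth <- truth + sim$ground_truth$trait_mean
  adj <- adjusted_entry_means(pt)
  raw <- tapply(pt$value, pt$genotype_id, mean)
  rmse <- function(v) sqrt(mean((v - truth[names(v)])^2))
  adj_v <- setNames(adj$adjusted_mean, adj$genotype_id)
  expect_lt(rmse(adj_v), rmse(raw))
})

test_that("genotypes absent from an environment come back as NA", {
  d <- data.frame(genotype_id = c("a", "b", "a", "b", "c"),
                  environment_id = c("E1", "E1", "E1", "E1", "E2"),
                  replicate_id = c("R1", "R1", "R2", "R2", "R1"),
                  block_id = "x",
                  value = c(1, 2, 1.5, 2.5, 9))
  adj <- adjusted_entry_means(d)
  expect_true(is.na(adj$adjusted_mean[adj$environment_id == "E1" &
                                        adj$genotype_id == "c"]))
  expect_false(anyNA(adj$adjusted_mean[adj$environment_id == "E1" &
                                         adj$genotype_id %in% c("a", "b")]))
})
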