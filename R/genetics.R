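#' Simulate latent genetic values and grain yield for a trial design
#'
#' Draws independent Gaussian effects under the random-effects decomposition
#' used for broad-sense heritability: a plot's latent canopy trait is
#' genotype effect + genotype-by-environment effect + replicate and block
#' effects + residual, with variances `sigma_G2`, `sigma_GE2`, `sigma_rep2`,
#' `sigma_block2` and `sigma_eps2`. Grain yield is generated the same way
#' from its own effect set, with its genotype effects correlated with the
#' canopy-trait genotype effects at `genetic_corr_yield` (so the canopy
#' trait is a genetically informative secondary trait for yield, as spectral
#' indices are used in practice).
#'
#' @param design a [generate_trial_design()] object.
#' @param sigma_G2,sigma_GE2,sigma_eps2 genetic, genotype-by-environment and
#'   residual variances of the latent canopy trait (all >= 0).
#' @param sigma_rep2,sigma_block2 replicate-within-environment and
#'   block-within-replicate variances.
#' @param genetic_corr_yield correlation in \[-1, 1\] between the canopy-trait
#'   and yield genotype effects.
#' @param yield_mean,yield_sigma_G2,yield_sigma_GE2,yield_sigma_eps2 yield
#'   scale: intercept (t/ha) and effect variances; defaults mirror the
#'   canopy-trait variances.
#' @param trait_mean intercept of the latent trait (default 0.5, a mid-canopy
#'   operating point for the spectrum simulator).
#' @param seed integer seed.
#' @return A list of class `genetic_simulation` with
#'   `plot_values` (data.frame: design columns plus `latent_trait`,
#'   `water_proxy`, `yield`) and `ground_truth` (parameters and the drawn
#'   effect tables: `genotype_effects`, `ge_effects`, `rep_effects`,
#'   `block_effects`, `plot_errors`).
#' @details The plot-level water status driver `water_proxy` is taken
#'   proportional to the yield deviation of the plot (scaled to unit
#'   variance), so higher-yielding plots have wetter, cooler canopies; this
#'   couples the 970 nm water band negatively to yield, the sign structure
#'   expected of a normalized water index.
#' @export
simulate_genetic_values <- function(design,
                                    sigma_G2 = 1,
                                    sigma_GE2 = 0.25,
                                    sigma_eps2 = 0.5,
                                    sigma_rep2 = 0.05,
                                    sigma_block2 = 0.05,
                                    genetic_corr_yield = 0.7,
                                    yield_mean = 5,
                                    yield_sigma_G2 = sigma_G2,
                                    yield_sigma_GE2 = sigma_GE2,
                                    yield_sigma_eps2 = sigma_eps2,
                                    trait_mean = 0.5,
                                    seed = NULL) {
  stopifnot(inherits(design, "trial_design"))
  vars <- c(sigma_G2, sigma_GE2, sigma_eps2, sigma_rep2, sigma_block2,
            yield_sigma_G2, yield_sigma_GE2, yield_sigma_eps2)
  if (any(vars < 0)) ps_stop("variance components must be >= 0", "parameter_error")
  if (abs(genetic_corr_yield) > 1)
    ps_stop("genetic_corr_yield must lie in [-1, 1]", "parameter_error")

  p <- design$plots
  gen <- sort(unique(p$genotype_id))
  env <- sort(unique(p$environment_id))
  ge_keys <- as.vector(outer(gen, env, paste, sep = ":"))
  rep_keys <- unique(paste(p$environment_id, p$replicate_id, sep = ":"))
  blk_keys <- unique(p$block_id)

  with_seed(seed, {
    g_trait <- stats::rnorm(length(gen), 0, sqrt(sigma_G2))
    # correlated yield genotype effects: rho * standardized trait + residual part
    z <- stats::rnorm(length(gen))
    g_std <- if (sigma_G2 > 0) g_trait / sqrt(sigma_G2) else stats::rnorm(length(gen))
    g_yield <- sqrt(yield_sigma_G2) *
      (genetic_corr_yield * g_std + sqrt(1 - genetic_corr_yield^2) * z)

    ge_trait <- stats::rnorm(length(ge_keys), 0, sqrt(sigma_GE2))
    ge_yield <- stats::rnorm(length(ge_keys), 0, sqrt(yield_sigma_GE2))
    rep_eff <- stats::rnorm(length(rep_keys), 0, sqrt(sigma_rep2))
    blk_eff <- stats::rnorm(length(blk_keys), 0, sqrt(sigma_block2))
    e_trait <- stats::rnorm(nrow(p), 0, sqrt(sigma_eps2))
    e_yield <- stats::rnorm(nrow(p), 0, sqrt(yield_sigma_eps2))

    names(g_trait) <- names(g_yield) <- gen
    names(ge_trait) <- names(ge_yield) <- ge_keys
    names(rep_eff) <- rep_keys
    names(blk_eff) <- blk_keys

    ge_ix <- paste(p$genotype_id, p$environment_id, sep = ":")
    rep_ix <- paste(p$environment_id, p$replicate_id, sep = ":")

    latent <- trait_mean + g_trait[p$genotype_id] + ge_trait[ge_ix] +
      rep_eff[rep_ix] + blk_eff[p$block_id] + e_trait
    yield <- yield_mean + g_yield[p$genotype_id] + ge_yield[ge_ix] +
      rep_eff[rep_ix] + blk_eff[p$block_id] + e_yield

    ydev <- yield - yield_mean
    ysd <- stats::sd(ydev)
    water <- if (is.finite(ysd) && ysd > 0) ydev / ysd else ydev * 0

    plot_values <- cbind(p,
                         data.frame(latent_trait = unname(latent),
                                    water_proxy = unname(water),
                                    yield = unname(yield)))
    ground_truth <- list(
      sigma_G2 = sigma_G2, sigma_GE2 = sigma_GE2, sigma_eps2 = sigma_eps2,
      sigma_rep2 = sigma_rep2, sigma_block2 = sigma_block2,
      genetic_corr_yield = genetic_corr_yield,
      yield_sigma_G2 = yield_sigma_G2, yield_sigma_GE2 = yield_sigma_GE2,
      yield_sigma_eps2 = yield_sigma_eps2,
      trait_mean = trait_mean, yield_mean = yield_mean,
      x = design$x, r = design$r, seed = seed,
      genotype_effects = data.frame(genotype_id = gen,
                                    trait = unname(g_trait),
                                    yield = unname(g_yield)),
      ge_effects = data.frame(key = ge_keys, trait = unname(ge_trait),
                              yield = unname(ge_yield)),
      rep_effects = data.frame(key = rep_keys, effect = unname(rep_eff)),
      block_effects = data.frame(key = blk_keys, effect = unname(blk_eff)),
      plot_errors = data.frame(plot_id = p$plot_id, trait = e_trait,
                               yield = e_yield)
    )
    structure(list(plot_values = plot_values, ground_truth = ground_truth),
              class = "genetic_simulation")
  })
}

#' Plug-in broad-sense heritability implied by simulation parameters
#'
#' @param sim a `genetic_simulation` or its `ground_truth` list.
#' @return the heritability of entry means implied by the generating
#'   variances and the design's `x` and `r`.
#' @export
true_heritability <- function(sim) {
  gt <- if (inherits(sim, "genetic_simulation")) sim$ground_truth else sim
  gt$sigma_G2 / (gt$sigma_G2 + gt$sigma_GE2 / gt$x +
                   gt$sigma_eps2 / (gt$x * gt$r))
}
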