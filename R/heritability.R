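#' Estimate variance components of a trial trait
#'
#' Fits the random-effects decomposition underlying broad-sense
#' heritability — genotype, genotype-by-environment, replicate within
#' environment, block within replicate, residual — and returns the
#' variance components. Model terms absent from the design are dropped
#' automatically: with a single environment the G-by-E term collapses into
#' error, single-replicate designs drop the replicate term, and so on; a
#' message reports any reduction.
#'
#' Two estimators are provided. `"reml"` (the default) maximizes the
#' restricted likelihood of the Gaussian mixed model via [lme4::lmer()],
#' which constrains every component to be nonnegative. `"anova_moments"`
#' computes the classical expected-mean-squares estimators from the
#' two-way genotype-by-environment ANOVA (valid for balanced designs with
#' equal replication), flooring negative solutions at zero. On balanced
#' data the two agree closely.
#'
#' @param plot_table data.frame with columns `genotype_id`,
#'   `environment_id`, `replicate_id`, `block_id` and the trait in
#'   `value_col`.
#' @param value_col name of the trait column (default `"value"`).
#' @param method `"reml"` or `"anova_moments"`.
#' @return a `variance_components` list: `sigma_G2`, `sigma_GE2`,
#'   `sigma_eps2`, `sigma_rep2`, `sigma_block2`, `method`, `converged`,
#'   `x`, `r_effective` (mean plots per genotype-environment cell), `n`.
#' @export
estimate_variance_components <- function(plot_table,
                                         value_col = "value",
                                         method = c("reml", "anova_moments")) {
  method <- match.arg(method)
  need <- c("genotype_id", "environment_id", value_col)
  if (!all(need %in% names(plot_table)))
    ps_stop(sprintf("plot_table must have columns %s",
                    paste(need, collapse = ", ")), "input_error")
  d <- plot_table[!is.na(plot_table[[value_col]]), , drop = FALSE]
  d$y <- d[[value_col]]
  d$genotype_id <- factor(d$genotype_id)
  d$environment_id <- factor(d$environment_id)
  if (nlevels(d$genotype_id) < 2)
    ps_stop("need >= 2 genotypes", "input_error")
  x <- nlevels(d$environment_id)
  cell <- table(d$genotype_id, d$environment_id)
  r_eff <- mean(cell[cell > 0])

  has_rep <- "replicate_id" %in% names(d) &&
    any(tapply(d$replicate_id, d$environment_id,
               function(z) length(unique(z))) > 1)
  has_blk <- "block_id" %in% names(d) && length(unique(d$block_id)) > 1
  has_ge <- x >= 2
  if (!has_ge && method == "reml")
    message("single environment: genotype-by-environment collapses into error")

  if (all(d$y == d$y[1])) {
    return(structure(list(sigma_G2 = 0, sigma_GE2 = 0, sigma_eps2 = 0,
                          sigma_rep2 = 0, sigma_block2 = 0, method = method,
                          converged = TRUE, x = x, r_effective = r_eff,
                          n = nrow(d)),
                     class = "variance_components"))
  }

  if (method == "reml") {
    terms <- c("(1 | genotype_id)")
    if (has_ge) terms <- c(terms, "(1 | genotype_id:environment_id)")
    if (has_rep) terms <- c(terms, "(1 | environment_id:replicate_id)")
    if (has_blk) terms <- c(terms, "(1 | block_id)")
    fixed <- if (x >= 2) "environment_id" else "1"
    f <- stats::as.formula(paste("y ~", fixed, "+", paste(terms, collapse = " + ")))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(f, data = d,
                 control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                             check.nobs.vs.nRE = "ignore"))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    comp <- function(name) {
      v <- vc$vcov[vc$grp == name]
      if (length(v)) v else 0
    }
    converged <- length(fit@optinfo$conv$lme4) == 0 ||
      !any(grepl("failed", unlist(fit@optinfo$conv$lme4$messages %||% ""),
                 ignore.case = TRUE))
    out <- list(sigma_G2 = comp("genotype_id"),
                sigma_GE2 = comp("genotype_id:environment_id"),
                sigma_eps2 = comp("Residual"),
                sigma_rep2 = comp("environment_id:replicate_id"),
                sigma_block2 = comp("block_id"),
                method = "reml", converged = converged)
  } else {
    if (!has_ge) {
      # one-way random genotype ANOVA: MS_G = sigma_eps2 + r * sigma_G2
      a <- stats::anova(stats::aov(y ~ genotype_id, data = d))
      ms_g <- a["genotype_id", "Mean Sq"]
      ms_e <- a["Residuals", "Mean Sq"]
      out <- list(sigma_G2 = max(0, (ms_g - ms_e) / r_eff),
                  sigma_GE2 = 0, sigma_eps2 = ms_e,
                  sigma_rep2 = 0, sigma_block2 = 0,
                  method = "anova_moments", converged = TRUE)
    } else {
      if (stats::var(as.vector(cell)) > 0)
        warning("anova_moments assumes balanced data; cell counts vary")
      rterm <- if (has_rep) " + environment_id:replicate_id" else ""
      a <- stats::anova(stats::aov(stats::as.formula(
        paste0("y ~ environment_id", rterm,
               " + genotype_id + genotype_id:environment_id")), data = d))
      ge_row <- grep("genotype_id:environment_id|environment_id:genotype_id",
                     rownames(a), value = TRUE)[1]
      ms_g <- a["genotype_id", "Mean Sq"]
      ms_ge <- a[ge_row, "Mean Sq"]
      ms_e <- a["Residuals", "Mean Sq"]
      r <- r_eff
      # EMS (reps nested in environments, genotype crossed with environment):
      #   MS_G  = eps + r * GE + x * r * G;  MS_GE = eps + r * GE;  MSE = eps
      sigma_eps2 <- ms_e
      sigma_GE2 <- max(0, (ms_ge - ms_e) / r)
      sigma_G2 <- max(0, (ms_g - ms_ge) / (x * r))
      out <- list(sigma_G2 = sigma_G2, sigma_GE2 = sigma_GE2,
                  sigma_eps2 = sigma_eps2, sigma_rep2 = NA_real_,
                  sigma_block2 = NA_real_,
                  method = "anova_moments", converged = TRUE)
    }
  }
  structure(c(out, list(x = x, r_effective = r_eff, n = nrow(d))),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "<variance_components> [%s] sigma_G2=%.4g sigma_GE2=%.4g sigma_eps2=%.4g (x=%d, n=%d)\n",
    x$method, x$sigma_G2, x$sigma_GE2, x$sigma_eps2, x$x, x$n))
  invisible(x)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' `H2 = sigma_G2 / (sigma_G2 + sigma_GE2 / x + sigma_eps2 / (x * r))`,
#' where `x` is the number of environments and `r` the number of
#' replications per environment. With nonnegative components the result
#' lies in \[0, 1\] without any clamping.
#'
#' @param components a `variance_components` object or a list/vector with
#'   `sigma_G2`, `sigma_GE2`, `sigma_eps2`.
#' @param x number of environments (>= 1); defaults to the value recorded
#'   in `components`.
#' @param r number of replications (>= 1); defaults to the rounded mean
#'   plots per genotype-environment cell. For populations pooling
#'   replicated and unreplicated trials, pass the convention you want
#'   (`r = 1` is the conservative choice).
#' @param trait optional trait label.
#' @return a `heritability_result`: list with `H2`, `x`, `r`, `trait`,
#'   `components`.
#' @examples
#' broad_sense_heritability(list(sigma_G2 = 2, sigma_GE2 = 1, sigma_eps2 = 3),
#'                          x = 2, r = 3)$H2 # 0.6667
#' @export
broad_sense_heritability <- function(components, x = NULL, r = NULL,
                                     trait = NA_character_) {
  x <- x %||% components$x
  r <- r %||% round(components$r_effective %||% 1)
  if (is.null(x) || x < 1 || is.null(r) || r < 1)
    ps_stop("x and r must be >= 1", "parameter_error")
  sG <- components$sigma_G2; sGE <- components$sigma_GE2 %||% 0
  sE <- components$sigma_eps2
  if (any(c(sG, sGE, sE) < 0))
    ps_stop("variance components must be >= 0", "parameter_error")
  den <- sG + sGE / x + sE / (x * r)
  if (den == 0)
    ps_stop("all variance components are zero; heritability undefined",
            "undefined_value_error")
  structure(list(H2 = sG / den, x = x, r = r, trait = trait,
                 components = components),
            class = "heritability_result")
}

#' @export
print.heritability_result <- function(x, ...) {
  cat(sprintf("<heritability_result> H2 = %.3f (x=%d, r=%d%s)\n", x$H2,
              x$x, x$r,
              if (is.na(x$trait)) "" else paste0(", trait=", x$trait)))
  invisible(x)
}

#' Adjusted genotype means within each environment
#'
#' Computes per-environment genotype means adjusted for replicate and
#' block effects by a fixed-effects companion fit (genotype fixed,
#' sum-to-zero contrasts on replicate and block so the genotype
#' coefficients are means at the average design level). In orthogonal
#' designs without block effects these equal the raw genotype means.
#' Genotypes absent from an environment are returned as `NA`.
#'
#' @param plot_table data.frame with `genotype_id`, `environment_id`,
#'   optional `replicate_id` and `block_id`, and the trait in `value_col`.
#' @param value_col trait column name.
#' @return data.frame `environment_id`, `genotype_id`, `adjusted_mean`.
#' @export
adjusted_entry_means <- function(plot_table, value_col = "value") {
  d <- plot_table
  d$y <- d[[value_col]]
  all_gen <- sort(unique(d$genotype_id))
  res <- lapply(split(d, d$environment_id), function(de) {
    de <- de[!is.na(de$y), , drop = FALSE]
    de$genotype_id <- factor(de$genotype_id)
    if (nlevels(de$genotype_id) == 1) {
      found <- stats::setNames(rep(NA_real_, length(all_gen)), all_gen)
      found[levels(de$genotype_id)] <- mean(de$y)
      return(data.frame(environment_id = de$environment_id[1],
                        genotype_id = all_gen,
                        adjusted_mean = unname(found)))
    }
    terms <- "0 + genotype_id"
    contr <- list()
    if ("replicate_id" %in% names(de) && length(unique(de$replicate_id)) > 1) {
      de$replicate_id <- factor(de$replicate_id)
      terms <- c(terms, "replicate_id"); contr$replicate_id <- "contr.sum"
    }
    if ("block_id" %in% names(de) && length(unique(de$block_id)) > 1) {
      de$block_id <- factor(de$block_id)
      terms <- c(terms, "block_id"); contr$block_id <- "contr.sum"
    }
    fit <- stats::lm(stats::as.formula(paste("y ~", paste(terms, collapse = " + "))),
                     data = de, contrasts = if (length(contr)) contr else NULL)
    co <- stats::coef(fit)
    gn <- levels(de$genotype_id)
    adj <- co[paste0("genotype_id", gn)]
    # a dropped (confounded) block level makes its sum-contrast column NA;
    # genotype coefficients remain estimable in the designs generated here
    found <- stats::setNames(rep(NA_real_, length(all_gen)), all_gen)
    found[gn] <- unname(adj)
    data.frame(environment_id = de$environment_id[1],
               genotype_id = all_gen, adjusted_mean = unname(found))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
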