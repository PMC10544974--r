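#' Generate a field-trial design
#'
#' Builds the plot-to-genotype mapping for the two trial layouts common in
#' wheat breeding programs: resolvable alpha-lattice designs (complete
#' replicates split into incomplete blocks of equal size) and augmented
#' designs in which test entries are unreplicated and a small set of check
#' cultivars is repeated across incomplete blocks to support error
#' estimation. The same design is laid down in each of `x` environments
#' (years/locations), which is how multi-environment heritability gets its
#' `x` dimension.
#'
#' For augmented designs `n_entries` counts all unique genotypes including
#' the checks; each check appears `checks_rep` times in total (its first
#' occurrence plus `checks_rep - 1` repeats), one occurrence per incomplete
#' block, so the per-environment plot count is
#' `n_entries + n_checks * (checks_rep - 1)`. An alpha-lattice has
#' `n_entries * r` plots per environment.
#'
#' @param design_kind `"alpha_lattice"` or `"augmented_with_checks"`.
#' @param n_entries number of unique genotypes (checks included).
#' @param n_checks number of check genotypes (augmented designs).
#' @param checks_rep total number of occurrences of each check, first
#'   occurrence included (augmented designs; equals the number of blocks).
#' @param r number of complete replicates (alpha-lattice; must be >= 2).
#'   Augmented designs have `r = 1` by construction.
#' @param block_size entries per incomplete block (alpha-lattice); must
#'   divide `n_entries`. Defaults to a near-square divisor.
#' @param x number of environments.
#' @param seed integer seed controlling randomization; the layout is
#'   reproducible bit-for-bit under a fixed seed.
#' @return An object of class `trial_design`: a list with `plots` (a
#'   data.frame with columns `plot_id`, `genotype_id`, `environment_id`,
#'   `replicate_id`, `block_id`, `is_check`), `design_kind`, `n_entries`,
#'   `n_checks`, `x` and `r`.
#' @examples
#' d <- generate_trial_design("alpha_lattice", n_entries = 24, r = 2,
#'                            block_size = 6, seed = 1)
#' nrow(d$plots) # 24 * 2
#' @export
generate_trial_design <- function(design_kind = c("alpha_lattice", "augmented_with_checks"),
                                  n_entries,
                                  n_checks = 0L,
                                  checks_rep = 1L,
                                  r = 1L,
                                  block_size = NULL,
                                  x = 1L,
                                  seed = NULL) {
  design_kind <- match.arg(design_kind)
  if (n_entries < 1) ps_stop("n_entries must be >= 1", "design_error")
  if (x < 1) ps_stop("x (environments) must be >= 1", "design_error")

  genotypes <- sprintf("G%04d", seq_len(n_entries))

  plots <- with_seed(seed, {
    if (design_kind == "alpha_lattice") {
      if (r < 2) ps_stop("alpha-lattice designs require r >= 2 complete replicates",
                         "design_error")
      if (is.null(block_size)) {
        divs <- which(n_entries %% seq_len(n_entries) == 0)
        block_size <- divs[which.min(abs(divs - sqrt(n_entries)))]
      }
      if (n_entries %% block_size != 0)
        ps_stop(sprintf("block_size %d does not divide n_entries %d",
                        block_size, n_entries), "design_error")
      n_blocks <- n_entries %/% block_size
      do.call(rbind, lapply(seq_len(x), function(env) {
        do.call(rbind, lapply(seq_len(r), function(rep) {
          ord <- sample(genotypes)
          data.frame(
            genotype_id = ord,
            environment_id = sprintf("E%d", env),
            replicate_id = sprintf("R%d", rep),
            block_id = sprintf("E%d_R%d_B%02d", env, rep,
                               rep(seq_len(n_blocks), each = block_size)),
            stringsAsFactors = FALSE
          )
        }))
      }))
    } else {
      if (n_checks > n_entries)
        ps_stop("n_checks cannot exceed n_entries", "design_error")
      if (n_checks > 0 && checks_rep < 1)
        ps_stop("checks_rep must be >= 1", "design_error")
      checks <- genotypes[seq_len(n_checks)]
      tests <- setdiff(genotypes, checks)
      n_blocks <- max(1L, as.integer(checks_rep))
      # unreplicated entries are spread over the blocks; every check occurs
      # once in each block
      do.call(rbind, lapply(seq_len(x), function(env) {
        tests_shuffled <- sample(tests)
        rows <- data.frame(
          genotype_id = c(tests_shuffled, rep(checks, times = n_blocks)),
          block = c(sort(rep(seq_len(n_blocks), length.out = length(tests))),
                    rep(seq_len(n_blocks), each = length(checks))),
          stringsAsFactors = FALSE
        )
        rows <- rows[order(rows$block), , drop = FALSE]
        data.frame(
          genotype_id = rows$genotype_id,
          environment_id = sprintf("E%d", env),
          replicate_id = "R1",
          block_id = sprintf("E%d_B%02d", env, rows$block),
          stringsAsFactors = FALSE
        )
      }))
    }
  })

  plots$is_check <- plots$genotype_id %in% genotypes[seq_len(n_checks)] & n_checks > 0
  plots$plot_id <- sprintf("P%05d", seq_len(nrow(plots)))
  plots <- plots[, c("plot_id", "genotype_id", "environment_id",
                     "replicate_id", "block_id", "is_check")]
  rownames(plots) <- NULL

  out <- structure(
    list(plots = plots, design_kind = design_kind,
         n_entries = as.integer(n_entries), n_checks = as.integer(n_checks),
         x = as.integer(x),
         r = if (design_kind == "alpha_lattice") as.integer(r) else 1L),
    class = "trial_design"
  )
  validate_trial_design(out)
  out
}

#' Validate a trial design's structural invariants
#'
#' Checks that every plot maps to exactly one genotype and environment, that
#' alpha-lattice replicates are complete and partitioned into equal blocks,
#' and that augmented designs replicate only the checks.
#'
#' @param design a `trial_design`.
#' @return `design`, invisibly; errors of class `design_error` otherwise.
#' @export
validate_trial_design <- function(design) {
  p <- design$plots
  if (anyNA(p)) ps_stop("design table contains missing values", "design_error")
  if (anyDuplicated(p$plot_id)) ps_stop("duplicated plot_id", "design_error")
  if (design$design_kind == "alpha_lattice") {
    for (env in unique(p$environment_id)) {
      pe <- p[p$environment_id == env, ]
      for (rep in unique(pe$replicate_id)) {
        pr <- pe[pe$replicate_id == rep, ]
        if (anyDuplicated(pr$genotype_id))
          ps_stop("genotype repeated within a complete replicate", "design_error")
        if (length(unique(table(pr$block_id))) != 1)
          ps_stop("incomplete blocks are not of equal size", "design_error")
      }
    }
  } else {
    tab <- table(p$genotype_id, p$environment_id)
    noncheck <- !rownames(tab) %in% unique(p$genotype_id[p$is_check])
    if (any(tab[noncheck, ] > 1))
      ps_stop("non-check entry replicated in an augmented design", "design_error")
  }
  invisible(design)
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("<trial_design> %s: %d entries (%d checks), x=%d, r=%d, %d plots\n",
              x$design_kind, x$n_entries, x$n_checks, x$x, x$r, nrow(x$plots)))
  invisible(x)
}
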