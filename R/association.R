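#' Pairwise Pearson correlation matrix with per-cell sample sizes
#'
#' Pairwise-complete Pearson correlations across trait/platform columns,
#' with the number of complete pairs reported per cell. Constant columns
#' yield `NA` cells with the reason recorded.
#'
#' @param trait_table numeric data.frame (one column per trait).
#' @param min_pairs minimum complete pairs per cell (default 3); cells
#'   with fewer become `NA`.
#' @return a `correlation_matrix`: list with `r` (matrix), `n` (matrix of
#'   complete pairs), `dropped` (names of constant columns).
#' @export
correlation_matrix <- function(trait_table, min_pairs = 3) {
  m <- as.matrix(trait_table)
  if (!is.numeric(m)) ps_stop("trait_table must be numeric", "input_error")
  p <- ncol(m)
  labs <- colnames(m)
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  constant <- !is.na(sds) & sds == 0
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  ok <- !is.na(m)
  n <- crossprod(ok)
  r[n < min_pairs] <- NA_real_
  r[constant, ] <- NA_real_
  r[, constant] <- NA_real_
  diag(r) <- ifelse(constant, NA_real_, 1)
  dimnames(r) <- dimnames(n) <- list(labs, labs)
  structure(list(r = r, n = n, dropped = labs[constant]),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat("<correlation_matrix>\n")
  print(round(x$r, digits))
  invisible(x)
}

#' Long heatmap-ready form of a correlation matrix
#'
#' @param cm a [correlation_matrix()].
#' @return data.frame `var1`, `var2`, `r`, `n`.
#' @export
correlation_long <- function(cm) {
  labs <- rownames(cm$r)
  grid <- expand.grid(var1 = labs, var2 = labs, stringsAsFactors = FALSE)
  grid$r <- as.vector(cm$r)
  grid$n <- as.vector(cm$n)
  grid
}

#' Ordinary least-squares regression of a trait on an index
#'
#' @param y response (e.g. grain yield).
#' @param x predictor (e.g. an index); needs >= 3 complete pairs and
#'   nonzero variance.
#' @return list with `slope`, `intercept`, `r_squared`, `n`.
#' @export
linear_regression <- function(y, x) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3) ps_stop("need >= 3 complete pairs", "regression_error")
  if (stats::var(x[ok]) == 0)
    ps_stop("predictor has zero variance", "regression_error")
  fit <- stats::lm(y[ok] ~ x[ok])
  co <- stats::coef(fit)
  list(slope = unname(co[2]), intercept = unname(co[1]),
       r_squared = suppressWarnings(summary(fit)$r.squared), n = sum(ok))
}

#' Principal component analysis of trait/platform columns
#'
#' Listwise-complete PCA via eigen-decomposition of the correlation
#' (scaled) or covariance matrix, with a deterministic sign convention:
#' each loading vector is flipped so its largest-magnitude element is
#' positive. Variance explained is reported in percent and sums to 100.
#'
#' @param trait_table numeric data.frame.
#' @param center,scale center/scale the columns (scaling is the default
#'   since traits mix units).
#' @return a `pca_result`: list with `loadings` (variables x components),
#'   `scores` (rows x components), `variance_explained` (percent, named
#'   `Dim1`, `Dim2`, ...), `n` (complete rows used).
#' @export
pca_traits <- function(trait_table, center = TRUE, scale = TRUE) {
  m <- as.matrix(trait_table)
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  if (ncol(m) < 2) ps_stop("PCA needs >= 2 variables", "input_error")
  if (nrow(m) < ncol(m))
    warning("fewer complete rows than variables; components are rank-deficient")
  pc <- stats::prcomp(m, center = center, scale. = scale)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  dims <- paste0("Dim", seq_along(ve))
  colnames(rot) <- colnames(scores) <- names(ve) <- dims
  structure(list(loadings = rot, scores = scores, variance_explained = ve,
                 n = nrow(m)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d rows; variance explained: %s\n", x$n,
              paste(sprintf("%s %.1f%%", names(x$variance_explained),
                            x$variance_explained), collapse = ", ")))
  invisible(x)
}
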