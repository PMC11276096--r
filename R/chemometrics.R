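#' Correlation-matrix principal component analysis
#'
#' Eigendecomposition of the correlation matrix of the columns of a feature
#' matrix — the standardization-invariant form of PCA appropriate when
#' variables mix measurement scales (mg/kg phenolics alongside g/kg sugars).
#' Loadings are correlation-scaled (`eigenvector * sqrt(eigenvalue)`), so a
#' loading is the correlation between variable and component and each
#' loading column has squared norm equal to its eigenvalue.  Scores are the
#' projections of the z-scored samples onto the eigenvectors.  The sign of
#' each component is fixed so its largest-magnitude loading is positive.
#'
#' @param x A `feature_matrix` (standardized or not; standardization is
#'   applied internally) or a plain numeric matrix with >= 2 rows and >= 2
#'   columns.  Constant columns must have been dropped upstream.
#' @return A `pca_cor` object with `eigenvalues` (descending), `loadings`
#'   (variables x components), `scores` (samples x components),
#'   `explained_fraction` and `n_variables`.  Eigenvalues sum to the number
#'   of variables.
#' @export
pca_cor <- function(x) {
  fm <- standardize_features(x)
  if (nrow(fm$dropped_columns) > 0L &&
      any(fm$dropped_columns$reason == "zero variance")) {
    stop("constant column(s) reached PCA: ",
         paste(fm$dropped_columns$column[
           fm$dropped_columns$reason == "zero variance"], collapse = ", "),
         " (drop upstream)")
  }
  z <- fm$values
  if (nrow(z) < 2L || ncol(z) < 2L) stop("need >= 2 samples and >= 2 variables")
  p <- ncol(z)
  eig <- eigen(stats::cor(z), symmetric = TRUE)
  lambda <- pmax(eig$values, 0)   # clip -1e-16 round-off on rank-deficient data
  vec <- eig$vectors
  # deterministic sign: largest-|loading| variable positive in each component
  for (j in seq_len(p)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  loadings <- vec %*% diag(sqrt(lambda), p)
  dimnames(loadings) <- list(colnames(z), paste0("PC", seq_len(p)))
  scores <- z %*% vec
  dimnames(scores) <- list(rownames(z), paste0("PC", seq_len(p)))
  structure(list(eigenvalues = lambda, loadings = loadings, scores = scores,
                 explained_fraction = lambda / p, n_variables = p),
            class = "pca_cor")
}

#' @export
print.pca_cor <- function(x, ...) {
  cat("correlation-matrix PCA:", nrow(x$loadings), "variables,",
      nrow(x$scores), "samples\n")
  ev <- round(100 * x$explained_fraction, 1)
  cat("explained variance (%):", paste(utils::head(ev, 5), collapse = ", "),
      if (length(ev) > 5) "...", "\n")
  invisible(x)
}

#' Cumulative explained variance
#'
#' @param result A `pca_cor` object.
#' @param k Number of leading components.
#' @return Percent of total variance captured by components 1..k.
#' @export
explained_variance <- function(result, k) {
  stopifnot(inherits(result, "pca_cor"))
  if (k < 1L || k > length(result$eigenvalues)) stop("k out of range")
  100 * sum(result$eigenvalues[seq_len(k)]) / result$n_variables
}

#' Per-variable contributions to a principal component
#'
#' Contribution of variable i to component j, based on correlations:
#' `100 * loading_ij^2 / eigenvalue_j`.  Contributions sum to 100 within a
#' component; the loading's sign is carried separately as the direction of
#' influence.
#'
#' @param result A `pca_cor` object.
#' @param component Component index j (eigenvalue must be > 0).
#' @return Data frame with `variable`, `contribution` (percent) and
#'   `direction` (+1/-1), in the input variable order.
#' @export
variable_contributions <- function(result, component = 1L) {
  stopifnot(inherits(result, "pca_cor"))
  if (component < 1L || component > length(result$eigenvalues)) {
    stop("component out of range")
  }
  lambda <- result$eigenvalues[component]
  if (lambda <= 0) stop("component ", component, " has zero eigenvalue")
  l <- result$loadings[, component]
  data.frame(variable = rownames(result$loadings),
             contribution = 100 * l^2 / lambda,
             direction = ifelse(l >= 0, 1, -1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Biplot coordinates for a component plane
#'
#' Sample scores and variable loading vectors restricted to the (i, j)
#' plane. Coordinates only; no plotting.
#'
#' @param result A `pca_cor` object.
#' @param i,j Distinct component indices.
#' @return List with matrices `scores` (samples x 2) and `variables`
#'   (variables x 2).
#' @export
biplot_coords <- function(result, i = 1L, j = 2L) {
  stopifnot(inherits(result, "pca_cor"))
  if (i == j) stop("components must differ")
  k <- length(result$eigenvalues)
  if (any(c(i, j) < 1L) || any(c(i, j) > k)) stop("component out of range")
  list(scores = result$scores[, c(i, j), drop = FALSE],
       variables = result$loadings[, c(i, j), drop = FALSE])
}

#' Pearson correlation with t-based significance
#'
#' Pearson r with the two-sided p-value from
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` on n - 2 degrees of freedom
#' (see [p_from_r()]).
#'
#' @param x,y Numeric vectors of equal length n >= 3 with nonzero variance.
#' @return A `correlation_result` with `r`, `n`, `p_value`, and significance
#'   flags at 0.05 and 0.01.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need n >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("zero variance input")
  r <- stats::cor(x, y)
  p <- p_from_r(r, n)
  structure(list(r = r, n = n, p_value = p,
                 significant_05 = p < 0.05, significant_01 = p < 0.01),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f (n = %d, p = %.4g)%s\n", x$r, x$n, x$p_value,
              if (x$significant_01) " **" else if (x$significant_05) " *" else ""))
  invisible(x)
}

#' Two-sided p-value of a Pearson correlation
#'
#' Exact under bivariate normality: the statistic
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` follows a t distribution with n - 2
#' degrees of freedom under the null of no correlation; the two-sided p
#' doubles its upper tail.  The convention for n matters: correlations of
#' per-cultivar means use n = 7 here, replicate-level correlations n = 21.
#'
#' @param r Pearson coefficient, |r| <= 1.
#' @param n Number of observations, >= 3.
#' @return Two-sided p-value; |r| = 1 returns 0 with a message.
#' @export
p_from_r <- function(r, n) {
  stopifnot(abs(r) <= 1, n >= 3)
  if (abs(r) == 1) {
    message("|r| = 1: p = 0 (degenerate)")
    return(0)
  }
  t <- abs(r) * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(t, df = n - 2, lower.tail = FALSE)
}

#' Correlate each column of a matrix against an endpoint
#'
#' Convenience screen producing one row per variable: the layout of a
#' phenolics-vs-antioxidant-activity correlation table.
#'
#' @param x Numeric matrix (samples x variables).
#' @param y Endpoint vector, length `nrow(x)`.
#' @return Data frame with `variable`, `r`, `n`, `p_value`,
#'   `significant_05`.
#' @export
correlate_columns <- function(x, y) {
  rows <- lapply(colnames(x), function(v) {
    ct <- pearson_cor(x[, v], y)
    data.frame(variable = v, r = ct$r, n = ct$n, p_value = ct$p_value,
               significant_05 = ct$significant_05, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
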