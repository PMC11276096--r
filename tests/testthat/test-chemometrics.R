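test_that("correlation-matrix PCA matches the svd oracle and its own invariants", {
  for (seed in 1:10) {
    x <- withr::with_seed(seed, matrix(rnorm(16), 4, 4,
                                       dimnames = list(NULL, paste0("v", 1:4))))
    res <- pca_cor(x)
    # eigenvalues agree with prcomp's svd route
    oracle <- prcomp(x, center = TRUE, scale. = TRUE)
    expect_equal(res$eigenvalues, oracle$sdev^2, tolerance = 1e-8)
    # eigenvalue sum = number of variables
    expect_equal(sum(res$eigenvalues), 4, tolerance = 1e-8)
    # loadings column norms are the eigenvalues
    expect_equal(colSums(res$loadings^2), res$eigenvalues,
                 tolerance = 1e-8, ignore_attr = TRUE)
    # reconstruction: cor(x) = L L^T with all components
    expect_equal(res$loadings %*% t(res$loadings), cor(x),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # loadings match prcomp rotation up to column sign (informative
    # components only: with 4 centered samples the last eigenvalue is ~0 and
    # its eigenvector is arbitrary)
    informative <- which(res$eigenvalues > 1e-6)
    for (j in informative) {
      a <- res$loadings[, j] / sqrt(res$eigenvalues[j])
      b <- oracle$rotation[, j]
      expect_lt(min(sum(abs(a - b)), sum(abs(a + b))), 1e-6)
    }
    # sign convention: largest-|loading| entry positive
    for (j in informative) {
      expect_gte(res$loadings[which.max(abs(res$loadings[, j])), j], 0)
    }
  }
})

test_that("rank-1 toy collapses to a single component", {
  x <- cbind(a = c(1, 2, 3, 4), b = 2 * c(1, 2, 3, 4) + 5)
  res <- pca_cor(x)
  expect_equal(res$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_equal(explained_variance(res, 1), 100)
  expect_equal(explained_variance(res, 2), 100)
  # all variable vectors collinear in the biplot plane
  bp <- biplot_coords(res, 1, 2)
  expect_lt(abs(bp$variables[1, 2]), 1e-6)
  expect_lt(abs(bp$variables[2, 2]), 1e-6)
})

test_that("variable contributions sum to 100 and carry direction", {
  fm <- pivot_to_matrix(apple_summaries("phenolics"),
                        pomochem:::phenolic_pca_variables())
  res <- pca_cor(fm)
  for (j in 1:4) {
    ct <- variable_contributions(res, j)
    expect_equal(sum(ct$contribution), 100, tolerance = 1e-8)
    expect_true(all(ct$direction %in% c(-1, 1)))
  }
  # leading positive contributors to PC1 include procyanidin B2 at ~17.6%
  ct1 <- variable_contributions(res, 1)
  expect_equal(ct1$contribution[ct1$variable == "pCB2"], 17.6, tolerance = 0.5)
  expect_error(variable_contributions(res, 99), "out of range")
})

test_that("scores are uncorrelated across components and plane extraction validates", {
  fm <- pivot_to_matrix(apple_summaries("phenolics"),
                        pomochem:::phenolic_pca_variables())
  res <- pca_cor(fm)
  cv <- cov(res$scores[, 1:4])
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  # PC1-PC2 and PC1-PC3 planes both computable
  expect_equal(dim(biplot_coords(res, 1, 2)$scores), c(7L, 2L))
  expect_equal(dim(biplot_coords(res, 1, 3)$scores), c(7L, 2L))
  expect_error(biplot_coords(res, 2, 2), "differ")
})

test_that("PCA refuses constant columns and degenerate shapes", {
  x <- cbind(a = c(1, 2, 3), b = c(1, 1, 1))
  expect_error(pca_cor(x), "constant column")
  expect_error(pca_cor(cbind(a = c(1, 2, 3))), "2 samples and >= 2 variables")
})

test_that("Pearson correlation and its p-value follow the t formula", {
  x <- c(1, 3, 2, 5, 4, 7, 6)
  y <- c(2, 4, 5, 4, 8, 9, 11)
  ct <- pearson_cor(x, y)
  oracle <- cor.test(x, y)
  expect_equal(ct$r, unname(oracle$estimate))
  expect_equal(ct$p_value, oracle$p.value, tolerance = 1e-12)
  expect_equal(pearson_cor(x, x)$r, 1)
  expect_equal(p_from_r(0, 10), 1)
  expect_message(p0 <- p_from_r(1, 5), "degenerate")
  expect_equal(p0, 0)
  expect_error(pearson_cor(1:2, 1:2), "n >= 3")
  expect_error(pearson_cor(rep(1, 5), 1:5), "zero variance")

  # strictly decreasing in |r| at fixed n, and in n at fixed |r|
  rs <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(vapply(rs, p_from_r, 1, n = 10)) < 0))
  ns <- c(5, 10, 20, 50)
  expect_true(all(diff(vapply(ns, function(n) p_from_r(0.4, n), 1)) < 0))
})

test_that("the sample-unit convention matters: means (n = 7) vs replicates (n = 21)", {
  dpph <- cultivar_means("assays", "DPPH_IC50")
  pca_means <- cultivar_means("phenolics", "pCA")[names(dpph)]
  r <- pearson_cor(pca_means, dpph)
  expect_equal(r$p_value, p_from_r(r$r, 7))
  # the same r judged at replicate scale would be far stronger
  expect_lt(p_from_r(r$r, 21), 1e-4)
  expect_gt(r$p_value, 0.01)
})
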