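test_that("forward pass equals plain affine composition under identity transfers", {
  # all-zero weights -> zero output
  w0 <- mlp_weights(matrix(0, 2, 3), rep(0, 3), matrix(0, 3, 1), 0)
  m0 <- mlp_model(w0, f_hidden = "identity")
  expect_equal(unname(mlp_forward(m0, matrix(1:4, 2, 2))), matrix(0, 2, 1))

  # 1-1-1 net, tanh hidden: x = 0 -> y = w2 * tanh(0) + b2 = 1
  w <- mlp_weights(matrix(1, 1, 1), 0, matrix(2, 1, 1), 1)
  m <- mlp_model(w, f_hidden = "tanh")
  expect_equal(unname(mlp_forward(m, matrix(0))), matrix(1))
  # and at x = 1: 2 * tanh(1) + 1
  expect_equal(unname(mlp_forward(m, matrix(1)))[1, 1], 2 * tanh(1) + 1)

  # random small nets vs direct matrix arithmetic
  for (seed in 1:5) {
    w <- small_net(m = 4, h = 3, q = 2, seed = seed)
    mdl <- mlp_model(w, f_hidden = "identity", f_output = "identity")
    x <- withr::with_seed(seed + 100, matrix(rnorm(12), 3, 4))
    direct <- sweep(sweep(x %*% w$W1, 2, w$B1, "+") %*% w$W2, 2, w$B2, "+")
    expect_equal(unname(mlp_forward(mdl, x)), unname(direct), tolerance = 1e-12)
  }
})

test_that("the published weight tables load shape-checked and drive the forward pass", {
  w <- paper_weights()
  expect_equal(dim(w$W1), c(12L, 11L))
  expect_equal(length(w$B1), 11L)
  expect_equal(dim(w$W2), c(11L, 2L))
  expect_equal(w$input_names[1], "A")
  expect_equal(w$W1["A", 4], 0.839)
  expect_equal(w$B2[1], -0.118)       # DPPH output bias
  expect_equal(w$W2[11, "DPPH"], -0.074)

  # zero input, identity transfers/normalizers: y = W2^T B1 + B2, by explicit
  # dot products
  mdl <- mlp_model(w, f_hidden = "identity", f_output = "identity")
  y <- mlp_forward(mdl, matrix(0, 1, 12, dimnames = list(NULL, w$input_names)))
  oracle <- vapply(1:2, function(j) {
    sum(vapply(1:11, function(k) w$W1[1, k] * 0 + w$W2[k, j] * w$B1[k],
               numeric(1))) + w$B2[j]
  }, numeric(1))
  expect_equal(unname(drop(y)), oracle, tolerance = 1e-12)

  # column mismatch names the offender
  x <- matrix(0, 1, 12, dimnames = list(NULL, c(w$input_names[-1], "bogus")))
  expect_error(mlp_forward(mdl, x), "missing: A")
  expect_error(mlp_forward(mdl, x), "extra: bogus")
})

test_that("weight tables round-trip through the printed layout", {
  w <- paper_weights()
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  save_weight_tables(w, p1, p2)
  back <- load_weight_tables(p1, p2)
  expect_equal(back$W1, w$W1)
  expect_equal(back$B1, w$B1)
  expect_equal(back$W2, w$W2)
  expect_equal(back$B2, w$B2)

  # label errors are named
  bad <- read.csv(p1); bad$input[13] <- "oops"
  pb <- tempfile(fileext = ".csv"); write.csv(bad, pb, row.names = FALSE)
  expect_error(load_weight_tables(pb, p2), "Bias")
})

test_that("min-max normalization round-trips and handles constant columns", {
  x <- cbind(a = c(1, 5, 3), b = c(10, 10, 10))
  nm <- pomochem:::minmax_fit(x)
  z <- pomochem:::minmax_apply(nm, x)
  expect_equal(range(z[, "a"]), c(0, 1))
  expect_equal(z[, "b"], rep(0.5, 3), ignore_attr = TRUE)
  back <- pomochem:::minmax_invert(nm, z)
  expect_equal(back, x, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("r2 scoring matches its definition and the OLS oracle", {
  expect_equal(unname(r2_score(cbind(1:5), cbind(1:5))), 1)
  y <- c(1, 2, 4, 3, 5)
  expect_equal(unname(r2_score(cbind(rep(mean(y), 5)), cbind(y))), 0)
  # hand-computed on 3 points vs the fitted line's R^2
  x <- c(1, 2, 3); obs <- c(1, 2, 2)
  fit <- lm(obs ~ x)
  expect_equal(unname(r2_score(cbind(fitted(fit)), cbind(obs))),
               summary(fit)$r.squared, tolerance = 1e-12)
  expect_error(r2_score(cbind(1:3), cbind(rep(2, 3))), "zero variance")
})

test_that("training is deterministic under a seed and exact on realizable functions", {
  # noiseless linear data, identity transfers: r2 = 1 to 6 decimals
  map <- default_generative_map(noise_sd = 0)
  tr <- simulate_training_set(map, 21L, seed = 8)
  m <- mlp_fit(tr$inputs, tr$outputs, hidden = 2L, restarts = 2L,
               f_hidden = "identity", seed = 21)
  expect_true(all(m$training_r2 > 1 - 1e-6))

  # same seed and spec -> identical weights
  m2 <- mlp_fit(tr$inputs, tr$outputs, hidden = 2L, restarts = 2L,
                f_hidden = "identity", seed = 21)
  expect_identical(m$weights, m2$weights)

  # function generated by a fixed small tanh network is recovered (predictions,
  # not weights: the parametrization is not identifiable)
  net <- small_net(m = 3, h = 2, q = 1, seed = 7)
  gen <- mlp_model(net, f_hidden = "tanh")
  x <- withr::with_seed(30, matrix(runif(60, -1, 1), 20, 3))
  y <- mlp_forward(gen, x)
  fit <- mlp_fit(x, y, hidden = 2L, restarts = 10L, seed = 31)
  expect_true(all(fit$training_r2 >= 0.999))
})
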