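# Feed-forward multilayer perceptron with one hidden layer:
#   Y = denorm( f_out( f_hid( X_norm W1 + B1 ) W2 + B2 ) )
# Weight matrices are stored input-major (rows = source layer), the layout
# in which trained weight tables are printed and exchanged.

transfer_fun <- function(name) {
  switch(name,
         identity = list(f = function(z) z, df = function(z, a) matrix(1, nrow(z), ncol(z))),
         tanh     = list(f = tanh,          df = function(z, a) 1 - a^2),
         logistic = list(f = function(z) 1 / (1 + exp(-z)),
                         df = function(z, a) a * (1 - a)),
         stop("unknown transfer function: ", name))
}

# Per-column min-max normalizer to [0, 1]; constant columns map to 0.5 so the
# transform stays defined (and invertible up to that constant).
minmax_fit <- function(x) {
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  structure(list(min = lo, range = ifelse(hi > lo, hi - lo, 1),
                 constant = hi == lo), class = "minmax_norm")
}
minmax_apply <- function(norm, x) {
  z <- sweep(sweep(x, 2L, norm$min, "-"), 2L, norm$range, "/")
  z[, norm$constant] <- 0.5
  z
}
minmax_invert <- function(norm, z) {
  x <- sweep(sweep(z, 2L, norm$range, "*"), 2L, norm$min, "+")
  x[, norm$constant] <- rep(norm$min[norm$constant], each = nrow(z))
  x
}
identity_norm <- function(p) {
  structure(list(min = rep(0, p), range = rep(1, p),
                 constant = rep(FALSE, p)), class = "minmax_norm")
}

#' Construct a set of MLP weights
#'
#' @param W1 Input-to-hidden weight matrix, inputs x hidden.
#' @param B1 Hidden bias vector, length = hidden count.
#' @param W2 Hidden-to-output weight matrix, hidden x outputs.
#' @param B2 Output bias vector, length = output count.
#' @param input_names,output_names Variable names; defaults taken from
#'   dimnames.
#' @return An `mlp_weights` object.
#' @export
mlp_weights <- function(W1, B1, W2, B2,
                        input_names = rownames(W1),
                        output_names = colnames(W2)) {
  W1 <- as.matrix(W1); W2 <- as.matrix(W2)
  h <- ncol(W1)
  if (length(B1) != h) stop("B1 length ", length(B1), " != hidden count ", h)
  if (nrow(W2) != h) stop("W2 has ", nrow(W2), " rows; expected ", h)
  if (length(B2) != ncol(W2)) stop("B2 length != output count")
  if (is.null(input_names)) input_names <- paste0("x", seq_len(nrow(W1)))
  if (is.null(output_names)) output_names <- paste0("y", seq_len(ncol(W2)))
  rownames(W1) <- input_names; colnames(W2) <- output_names
  structure(list(W1 = W1, B1 = as.numeric(B1), W2 = W2,
                 B2 = as.numeric(B2), input_names = input_names,
                 output_names = output_names, hidden_count = h),
            class = "mlp_weights")
}

#' Assemble an MLP model
#'
#' @param weights An `mlp_weights` object.
#' @param f_hidden,f_output Transfer function names (`"identity"`, `"tanh"`,
#'   `"logistic"`). Defaults: tanh hidden, identity output.
#' @param input_norm,output_norm `minmax_norm` objects (or `NULL` for the
#'   identity normalizer).
#' @param training_r2 Optional per-output training r-squared.
#' @return An `mlp_model` object.
#' @export
mlp_model <- function(weights, f_hidden = "tanh", f_output = "identity",
                      input_norm = NULL, output_norm = NULL,
                      training_r2 = NULL) {
  stopifnot(inherits(weights, "mlp_weights"))
  transfer_fun(f_hidden); transfer_fun(f_output)  # validate names
  if (is.null(input_norm)) input_norm <- identity_norm(nrow(weights$W1))
  if (is.null(output_norm)) output_norm <- identity_norm(ncol(weights$W2))
  structure(list(weights = weights, f_hidden = f_hidden, f_output = f_output,
                 input_norm = input_norm, output_norm = output_norm,
                 training_r2 = training_r2),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  w <- x$weights
  cat("MLP ", nrow(w$W1), "-", w$hidden_count, "-", ncol(w$W2),
      " (hidden: ", x$f_hidden, ", output: ", x$f_output, ")\n", sep = "")
  if (!is.null(x$training_r2)) {
    cat("training r2:", paste(sprintf("%s = %.4f", names(x$training_r2),
                                      x$training_r2), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Forward pass of an MLP model
#'
#' Normalizes the inputs, propagates through the hidden and output layers,
#' and de-normalizes the result.
#'
#' @param model An `mlp_model`.
#' @param inputs Numeric matrix whose columns match the model's
#'   `input_names` (a named vector is treated as one row).
#' @return Matrix of predictions, one column per output.
#' @export
mlp_forward <- function(model, inputs) {
  stopifnot(inherits(model, "mlp_model"))
  w <- model$weights
  if (is.null(dim(inputs))) inputs <- matrix(inputs, nrow = 1L,
                                             dimnames = list(NULL, names(inputs)))
  if (!is.null(colnames(inputs))) {
    extra <- setdiff(colnames(inputs), w$input_names)
    miss <- setdiff(w$input_names, colnames(inputs))
    if (length(miss) > 0L || length(extra) > 0L) {
      stop("input column mismatch;",
           if (length(miss)) paste0(" missing: ", paste(miss, collapse = ", ")),
           if (length(extra)) paste0(" extra: ", paste(extra, collapse = ", ")))
    }
    inputs <- inputs[, w$input_names, drop = FALSE]
  } else if (ncol(inputs) != nrow(w$W1)) {
    stop("expected ", nrow(w$W1), " input columns, got ", ncol(inputs))
  }
  fh <- transfer_fun(model$f_hidden); fo <- transfer_fun(model$f_output)
  xn <- minmax_apply(model$input_norm, inputs)
  z1 <- sweep(xn %*% w$W1, 2L, w$B1, "+")
  h <- fh$f(z1)
  z2 <- sweep(h %*% w$W2, 2L, w$B2, "+")
  yn <- fo$f(z2)
  out <- minmax_invert(model$output_norm, yn)
  colnames(out) <- w$output_names
  out
}

#' Coefficient of determination per output column
#'
#' `1 - SS_res / SS_tot` for each output.
#'
#' @param predicted,observed Numeric matrices of equal shape (vectors are
#'   treated as single columns), >= 2 rows.
#' @return Named numeric vector, one r-squared per output column.
#' @export
r2_score <- function(predicted, observed) {
  if (is.null(dim(predicted))) predicted <- cbind(predicted)
  if (is.null(dim(observed))) observed <- cbind(observed)
  stopifnot(all(dim(predicted) == dim(observed)), nrow(observed) >= 2L)
  out <- vapply(seq_len(ncol(observed)), function(j) {
    ss_tot <- sum((observed[, j] - mean(observed[, j]))^2)
    if (ss_tot == 0) stop("output column ", j, " has zero variance")
    1 - sum((observed[, j] - predicted[, j])^2) / ss_tot
  }, numeric(1))
  names(out) <- colnames(observed)
  out
}

# --- training ----------------------------------------------------------------

flatten_weights <- function(w) c(w$W1, w$B1, w$W2, w$B2)
unflatten_weights <- function(par, m, h, q, input_names, output_names) {
  i <- 0L
  W1 <- matrix(par[i + seq_len(m * h)], m, h); i <- i + m * h
  B1 <- par[i + seq_len(h)]; i <- i + h
  W2 <- matrix(par[i + seq_len(h * q)], h, q); i <- i + h * q
  B2 <- par[i + seq_len(q)]
  mlp_weights(W1, B1, W2, B2, input_names, output_names)
}

#' Train an MLP by multi-start quasi-Newton optimization
#'
#' Min-max normalizes inputs and outputs to [0, 1] on the training data,
#' then minimizes the sum of squared errors on the normalized scale with
#' BFGS (analytic backpropagation gradient), restarted from `restarts`
#' random initializations; the restart with the lowest training SSE is kept.
#' Multi-start matters because the loss surface is non-convex and single
#' runs regularly stall in poor local minima.
#'
#' @param inputs Numeric matrix, samples x inputs.
#' @param outputs Numeric matrix, samples x outputs.
#' @param hidden Hidden neuron count (>= 1).
#' @param restarts Number of random initializations (>= 1). Default 100;
#'   small overparameterized problems typically need far fewer.
#' @param max_iterations BFGS iteration cap per restart.
#' @param tol Relative convergence tolerance passed to the optimizer.
#' @param f_hidden,f_output Transfer function names.
#' @param seed Integer seed making the whole multi-start reproducible;
#'   `NULL` uses the current RNG state.
#' @return An `mlp_model` with fitted normalizers and `training_r2`.
#' @export
mlp_fit <- function(inputs, outputs, hidden = 11L, restarts = 100L,
                    max_iterations = 500L, tol = 1e-10,
                    f_hidden = "tanh", f_output = "identity", seed = NULL) {
  inputs <- as.matrix(inputs); outputs <- as.matrix(outputs)
  stopifnot(nrow(inputs) == nrow(outputs), nrow(inputs) >= 2L,
            hidden >= 1L, restarts >= 1L)
  m <- ncol(inputs); q <- ncol(outputs); h <- as.integer(hidden)
  input_names <- colnames(inputs); output_names <- colnames(outputs)
  if (is.null(input_names)) input_names <- paste0("x", seq_len(m))
  if (is.null(output_names)) output_names <- paste0("y", seq_len(q))
  in_norm <- minmax_fit(inputs); out_norm <- minmax_fit(outputs)
  xn <- minmax_apply(in_norm, inputs)
  yn <- minmax_apply(out_norm, outputs)
  fh <- transfer_fun(f_hidden); fo <- transfer_fun(f_output)

  sse <- function(par) {
    i <- 0L
    W1 <- matrix(par[i + seq_len(m * h)], m, h); i <- i + m * h
    B1 <- par[i + seq_len(h)]; i <- i + h
    W2 <- matrix(par[i + seq_len(h * q)], h, q); i <- i + h * q
    B2 <- par[i + seq_len(q)]
    a1 <- fh$f(sweep(xn %*% W1, 2L, B1, "+"))
    yhat <- fo$f(sweep(a1 %*% W2, 2L, B2, "+"))
    sum((yhat - yn)^2)
  }
  grad <- function(par) {
    i <- 0L
    W1 <- matrix(par[i + seq_len(m * h)], m, h); i <- i + m * h
    B1 <- par[i + seq_len(h)]; i <- i + h
    W2 <- matrix(par[i + seq_len(h * q)], h, q); i <- i + h * q
    B2 <- par[i + seq_len(q)]
    z1 <- sweep(xn %*% W1, 2L, B1, "+"); a1 <- fh$f(z1)
    z2 <- sweep(a1 %*% W2, 2L, B2, "+"); yhat <- fo$f(z2)
    d2 <- 2 * (yhat - yn) * fo$df(z2, yhat)
    d1 <- (d2 %*% t(W2)) * fh$df(z1, a1)
    c(t(xn) %*% d1, colSums(d1), t(a1) %*% d2, colSums(d2))
  }

  run <- function() {
    best <- NULL
    for (r in seq_len(restarts)) {
      par0 <- stats::runif(m * h + h + h * q + q, -0.5, 0.5)
      fit <- tryCatch(
        stats::optim(par0, sse, grad, method = "BFGS",
                     control = list(maxit = max_iterations, reltol = tol)),
        error = function(e) NULL)
      if (is.null(fit) || !is.finite(fit$value)) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    if (is.null(best)) stop("non-finite loss after all restarts")
    best
  }
  best <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  weights <- unflatten_weights(best$par, m, h, q, input_names, output_names)
  model <- mlp_model(weights, f_hidden, f_output, in_norm, out_norm)
  pred <- mlp_forward(model, inputs)
  model$training_r2 <- r2_score(pred, outputs)
  model
}

# --- weight-table I/O --------------------------------------------------------

#' Read trained weight tables from delimited text
#'
#' The exchange layout mirrors how trained networks are reported: the W1
#' file has one row per input plus a final `Bias` row, one column per hidden
#' neuron; the W2 file has one row per output, one column per hidden neuron
#' plus a final `Bias` column.
#'
#' @param w1_path,w2_path Paths to the two tables (CSV; first column holds
#'   the row labels).
#' @return An `mlp_weights` object (W2 transposed to internal hidden x
#'   outputs orientation).
#' @export
load_weight_tables <- function(w1_path, w2_path) {
  t1 <- utils::read.csv(w1_path, check.names = FALSE)
  t2 <- utils::read.csv(w2_path, check.names = FALSE)
  labels1 <- t1[[1L]]
  if (tolower(labels1[length(labels1)]) != "bias") {
    stop("W1 table: last row must be labelled 'Bias', found '",
         labels1[length(labels1)], "'")
  }
  m1 <- as.matrix(t1[, -1L, drop = FALSE])
  if (!is.numeric(m1)) stop("W1 table: non-numeric entries")
  W1 <- m1[-nrow(m1), , drop = FALSE]
  rownames(W1) <- labels1[-length(labels1)]
  B1 <- m1[nrow(m1), ]

  labels2 <- t2[[1L]]
  cols2 <- colnames(t2)[-1L]
  if (tolower(cols2[length(cols2)]) != "bias") {
    stop("W2 table: last column must be labelled 'Bias', found '",
         cols2[length(cols2)], "'")
  }
  m2 <- as.matrix(t2[, -1L, drop = FALSE])
  if (!is.numeric(m2)) stop("W2 table: non-numeric entries")
  W2 <- t(m2[, -ncol(m2), drop = FALSE])   # hidden x outputs
  colnames(W2) <- labels2
  B2 <- m2[, ncol(m2)]
  if (ncol(W1) != nrow(W2)) {
    stop("hidden-layer mismatch: W1 has ", ncol(W1), " columns, W2 has ",
         nrow(W2), " (transposed) rows")
  }
  mlp_weights(W1, B1, W2, B2, rownames(W1), labels2)
}

#' Write weight tables in the printed exchange layout
#'
#' Round-trips with [load_weight_tables()] bit-identically at the chosen
#' precision.
#'
#' @param weights An `mlp_weights` object.
#' @param w1_path,w2_path Output paths.
#' @param digits Decimal places; default 3, the precision of published
#'   weight tables.
#' @export
save_weight_tables <- function(weights, w1_path, w2_path, digits = 3L) {
  stopifnot(inherits(weights, "mlp_weights"))
  h <- weights$hidden_count
  fmt <- function(x) formatC(x, digits = digits, format = "f")
  w1 <- rbind(weights$W1, Bias = weights$B1)
  df1 <- data.frame(input = rownames(w1),
                    apply(w1, 2L, fmt), check.names = FALSE)
  colnames(df1)[-1L] <- paste0("hidden_", seq_len(h))
  utils::write.csv(df1, w1_path, row.names = FALSE, quote = FALSE)
  w2 <- cbind(t(weights$W2), Bias = weights$B2)
  df2 <- data.frame(output = weights$output_names,
                    apply(w2, 2L, fmt), check.names = FALSE)
  colnames(df2)[-1L] <- c(paste0("hidden_", seq_len(h)), "Bias")
  utils::write.csv(df2, w2_path, row.names = FALSE, quote = FALSE)
  invisible(c(w1 = w1_path, w2 = w2_path))
}
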