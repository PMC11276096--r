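#' Yoon's connection-weight sensitivity analysis
#'
#' Signed relative importance of each network input for each output,
#' computed purely from the connection weights of a trained feed-forward
#' network.  For input i and output j, the raw influence is the sum over
#' hidden neurons of the input-to-hidden times hidden-to-output weights,
#' `S_ij = sum_k W1[i, k] * W2[k, j]`, and the relative importance
#' normalizes each output column by the sum of absolute raw influences:
#' `RI_ij = 100 * S_ij / sum_i |S_ij|`.  Signed percentages in a column
#' therefore have absolute values summing to 100.  Bias terms do not enter;
#' the measure depends only on W1 and W2, never on the transfer functions
#' or normalizers.
#'
#' @param weights An `mlp_weights` object or an `mlp_model` (its weights are
#'   used).
#' @return A `sensitivity_report`: list with `ri` and `s` (inputs x outputs
#'   matrices of relative importances in percent and raw weight-product
#'   sums), `input_names`, `output_names`, and
#'   `denominator_convention = "absolute_sum"`.
#' @export
yoon_ri <- function(weights) {
  if (inherits(weights, "mlp_model")) weights <- weights$weights
  stopifnot(inherits(weights, "mlp_weights"))
  s <- weights$W1 %*% weights$W2    # inputs x outputs
  denom <- colSums(abs(s))
  if (any(denom == 0)) {
    stop("degenerate weights: all weight-product sums are zero for output ",
         weights$output_names[which(denom == 0)[1L]])
  }
  ri <- sweep(s, 2L, denom, "/") * 100
  dimnames(ri) <- dimnames(s) <- list(weights$input_names,
                                      weights$output_names)
  structure(list(ri = ri, s = s, input_names = weights$input_names,
                 output_names = weights$output_names,
                 denominator_convention = "absolute_sum"),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Yoon relative importance (%, signed; |column| sums to 100)\n")
  print(round(x$ri, 2))
  invisible(x)
}

#' Rank inputs by relative importance for one output
#'
#' @param report A `sensitivity_report`.
#' @param output Output name.
#' @return Data frame with `input` and `ri`, sorted by descending relative
#'   importance (stable: ties keep input order).
#' @export
rank_influences <- function(report, output) {
  stopifnot(inherits(report, "sensitivity_report"))
  if (!output %in% report$output_names) {
    stop("unknown output '", output, "'; have: ",
         paste(report$output_names, collapse = ", "))
  }
  ri <- report$ri[, output]
  ord <- order(-ri)   # order() is stable; ties keep input order
  data.frame(input = report$input_names[ord], ri = unname(ri[ord]),
             stringsAsFactors = FALSE)
}

#' Sensitivity report as a long data frame
#'
#' @param x A `sensitivity_report`.
#' @param ... Unused.
#' @return Data frame with `input`, `output`, `s` and `ri_percent`.
#' @export
as.data.frame.sensitivity_report <- function(x, ...) {
  data.frame(input = rep(x$input_names, times = length(x$output_names)),
             output = rep(x$output_names, each = length(x$input_names)),
             s = as.vector(x$s), ri_percent = as.vector(x$ri),
             stringsAsFactors = FALSE)
}
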