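# Seeded generators. Noise is gaussian truncated at zero by redraw (not
# clipping), so no point mass accumulates at 0 and moments stay close to the
# configured values for the small CVs typical of concentration data.

rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  for (i in 1:100) {
    neg <- out < 0
    if (!any(neg)) return(out)
    out[neg] <- stats::rnorm(sum(neg), mean, sd)
  }
  out[out < 0] <- 0  # pathological mean << 0; give up on redraw
  out
}

#' Simulate replicate-level measurements from summary statistics
#'
#' Emulates the structure of a triplicate targeted-profiling experiment:
#' for each (cultivar, analyte) summary, draws `n_replicates` values from
#' Normal(mean, sd) truncated at zero.  Non-detect summaries yield
#' `detected = FALSE` records (structural absence, no numeric value).
#'
#' @param summaries A `cultivar_summary` data frame (e.g. from
#'   [apple_summaries()]).
#' @param n_replicates Replicates per group. Default 3, the design of the
#'   worked-example study.
#' @param seed Integer seed; the full output stream is a deterministic
#'   function of it. `NULL` uses the current RNG state.
#' @return An `analyte_measurements` data frame.
#' @export
simulate_replicates <- function(summaries, n_replicates = 3L, seed = NULL) {
  stopifnot(n_replicates >= 1L)
  if (any(summaries$sd < 0, na.rm = TRUE)) stop("negative sd in summaries")
  gen <- function() {
    rows <- vector("list", nrow(summaries))
    for (i in seq_len(nrow(summaries))) {
      s <- summaries[i, ]
      if (s$detected) {
        vals <- rtruncnorm0(n_replicates, s$mean, s$sd)
        det <- TRUE
      } else {
        vals <- NA_real_
        det <- FALSE
      }
      rows[[i]] <- data.frame(cultivar = s$cultivar, analyte = s$analyte,
                              analyte_class = s$analyte_class,
                              replicate = seq_len(n_replicates),
                              value = vals, detected = det, unit = s$unit,
                              stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    class(out) <- c("analyte_measurements", "data.frame")
    out
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate a dose-response inhibition series
#'
#' Generates percent-inhibition readings from a Hill curve,
#' `inhibition(c) = 100 c^h / (c^h + ic50^h)`, plus zero-truncated gaussian
#' noise — the shape assumed when a radical-scavenging assay is read at a
#' ladder of extract concentrations to locate an IC50.
#'
#' @param ic50 True half-maximal concentration (> 0).
#' @param concentrations Strictly positive, strictly increasing tested
#'   concentrations.
#' @param hill Hill slope; default 1.
#' @param noise_sd Gaussian noise sd in percentage points.
#' @param seed Integer seed or `NULL`.
#' @return A `dose_response` object (see [estimate_ic50()]).
#' @export
simulate_dose_response <- function(ic50, concentrations, hill = 1,
                                   noise_sd = 0, seed = NULL) {
  stopifnot(ic50 > 0, hill > 0, noise_sd >= 0)
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (is.unsorted(concentrations, strictly = TRUE)) {
    stop("concentrations must be strictly increasing")
  }
  mu <- 100 * concentrations^hill / (concentrations^hill + ic50^hill)
  gen <- function() {
    stats::setNames(
      vapply(mu, function(m) rtruncnorm0(1L, m, noise_sd), numeric(1)), NULL)
  }
  inh <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  dose_response(concentrations, inh)
}

#' Define a generative input-to-antioxidant map
#'
#' A known function from the 12 phenolic inputs to the two antioxidant
#' endpoints (DPPH IC50, FRAP), used to generate training sets with a known
#' ground truth for function-recovery tests of the network trainer.  The map
#' is affine: `outputs = intercept + inputs %*% coefficients`, plus
#' zero-truncated gaussian noise.
#'
#' @param coefficients Numeric matrix, inputs x outputs; rownames are input
#'   names, colnames output names.
#' @param intercept Numeric vector, one per output.
#' @param noise_sd Per-output noise sd (recycled).
#' @return A `generative_map` object.
#' @seealso [default_generative_map()]
#' @export
generative_map <- function(coefficients, intercept, noise_sd = 0) {
  stopifnot(is.matrix(coefficients), length(intercept) == ncol(coefficients))
  noise_sd <- rep_len(noise_sd, ncol(coefficients))
  structure(list(coefficients = coefficients, intercept = intercept,
                 noise_sd = noise_sd), class = "generative_map")
}

#' Evaluate a generative map (noise-free)
#' @param map A `generative_map`.
#' @param inputs Numeric matrix with one column per input.
#' @return Matrix of noise-free outputs.
#' @export
evaluate_map <- function(map, inputs) {
  stopifnot(ncol(inputs) == nrow(map$coefficients))
  out <- sweep(inputs %*% map$coefficients, 2L, map$intercept, "+")
  colnames(out) <- colnames(map$coefficients)
  out
}

#' Default generative map for the 12-phenolic antioxidant problem
#'
#' Coefficient signs follow the direction of the published phenolic-vs-assay
#' correlations (e.g. more p-coumaric acid lowers the DPPH IC50, i.e.
#' stronger scavenging); magnitudes are scaled so each input moving across
#' its empirical range shifts DPPH IC50 by ~120 ug/mL and FRAP by
#' ~40 mg AAE/kg FW, and intercepts centre the outputs on the observed assay
#' means.  Default noise is ~5 percent of each output's observed range.
#'
#' @param noise_sd Per-output noise sd; default `c(DPPH = 25, FRAP = 8)`.
#' @return A `generative_map` over the 12 phenolic inputs.
#' @export
default_generative_map <- function(noise_sd = c(DPPH = 25, FRAP = 8)) {
  rng <- training_input_ranges()
  span <- pmax(rng[, "max"] - rng[, "min"], .Machine$double.eps)
  # direction of each input's association with scavenging (DPPH IC50 falls,
  # FRAP rises) as reported in the correlation screen
  dir_dpph <- c(A = -1, GA = -1, C = 1, CA = -1, pCA = -1, pCB2 = 1,
                E = 1, Q3ga = 1, Q3gl = 1, P = -1, Q3ru = 1, Q3rh = -1)
  dir_frap <- c(A = 1, GA = -1, C = -1, CA = -1, pCA = -1, pCB2 = -1,
                E = -1, Q3ga = 1, Q3gl = 1, P = -1, Q3ru = 1, Q3rh = 1)
  coef <- cbind(DPPH = -dir_dpph[rownames(rng)] * 120 / span,
                FRAP = dir_frap[rownames(rng)] * 40 / span)
  mid <- (rng[, "max"] + rng[, "min"]) / 2
  intercept <- c(DPPH = 450, FRAP = 280) - drop(mid %*% coef)
  generative_map(coef, intercept, noise_sd)
}

# Empirical input ranges: min/max over cultivars of mean +/- 2 sd, floored
# at 0, from the packaged phenolics table.
training_input_ranges <- function() {
  s <- apple_summaries("phenolics")
  inputs <- mlp_input_names()
  out <- matrix(NA_real_, length(inputs), 2L,
                dimnames = list(inputs, c("min", "max")))
  for (v in inputs) {
    sub <- s[s$analyte == v & s$detected, , drop = FALSE]
    out[v, "min"] <- max(0, min(sub$mean - 2 * sub$sd))
    out[v, "max"] <- max(sub$mean + 2 * sub$sd)
  }
  out
}

#' Simulate a paired training set for the antioxidant network
#'
#' Draws inputs uniformly within the empirical concentration ranges of the
#' packaged phenolics table (means +/- 2 sd across cultivars, floored at 0)
#' and produces outputs through a known [generative_map()] plus
#' zero-truncated noise.  The default `n_samples = 21` mirrors the scale of
#' the worked-example study (7 cultivars x 3 replicates).
#'
#' @param map A `generative_map`; default [default_generative_map()].
#' @param n_samples Number of rows. Default 21.
#' @param seed Integer seed or `NULL`.
#' @return List with numeric matrices `inputs` (n x 12) and `outputs` (n x 2).
#' @export
simulate_training_set <- function(map = default_generative_map(),
                                  n_samples = 21L, seed = NULL) {
  if (n_samples < 1L) stop("n_samples must be >= 1")
  rng <- training_input_ranges()
  rng <- rng[rownames(map$coefficients), , drop = FALSE]
  gen <- function() {
    x <- vapply(seq_len(nrow(rng)), function(i) {
      stats::runif(n_samples, rng[i, "min"], rng[i, "max"])
    }, numeric(n_samples))
    if (n_samples == 1L) x <- matrix(x, nrow = 1L)
    colnames(x) <- rownames(rng)
    y <- evaluate_map(map, x)
    for (j in seq_len(ncol(y))) {
      if (map$noise_sd[j] > 0) {
        y[, j] <- vapply(y[, j], function(m) rtruncnorm0(1L, m, map$noise_sd[j]),
                         numeric(1))
      }
    }
    list(inputs = x, outputs = y)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
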