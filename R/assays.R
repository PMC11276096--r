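#' DPPH radical scavenging capacity
#'
#' Percent scavenging from plate-reader absorbances:
#' `100 - (a_sample - a_correction) * 100 / a_control`, where the correction
#' well replaces the radical reagent with solvent (sample colour blank) and
#' the control carries the full radical absorbance.  Raw assay arithmetic is
#' preserved: values below 0 or above 100 are returned as-is with a warning.
#'
#' @param a_sample Absorbance of sample + radical.
#' @param a_correction Absorbance of the sample colour blank.
#' @param a_control Absorbance of the radical-only control (> 0).
#' @return Percent scavenging (vectorized).
#' @export
dpph_inhibition <- function(a_sample, a_correction, a_control) {
  if (any(a_control <= 0)) stop("a_control must be > 0")
  if (any(c(a_sample, a_correction) < 0)) stop("absorbances must be >= 0")
  out <- 100 - (a_sample - a_correction) * 100 / a_control
  if (any(out < 0 | out > 100)) {
    warning("scavenging outside [0, 100] reported as-is")
  }
  out
}

#' Construct a dose-response series
#'
#' @param concentrations Strictly increasing positive concentrations (ug/mL).
#' @param inhibitions Percent inhibition at each concentration.
#' @return A `dose_response` object.
#' @export
dose_response <- function(concentrations, inhibitions) {
  stopifnot(length(concentrations) == length(inhibitions),
            length(concentrations) >= 2L)
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (is.unsorted(concentrations, strictly = TRUE)) {
    stop("concentrations must be strictly increasing")
  }
  structure(list(concentrations = as.numeric(concentrations),
                 inhibitions = as.numeric(inhibitions)),
            class = "dose_response")
}

#' Estimate the IC50 of a dose-response series
#'
#' `"loglinear"` (default) interpolates inhibition linearly against
#' log10(concentration) between the two adjacent points bracketing 50% —
#' robust for the typical five-concentration ladder.  `"fourpl"` fits a
#' four-parameter logistic by least squares and returns its midpoint;
#' it needs at least 4 points.
#'
#' For bracketing only, inhibitions are clamped to [0, 100]; reported series
#' values are never altered.  If several adjacent pairs bracket 50% (noisy,
#' non-monotone data) the first is used with a warning.
#'
#' @param series A `dose_response` object.
#' @param method `"loglinear"` or `"fourpl"`.
#' @return Estimated IC50 on the concentration axis of the series.
#' @export
estimate_ic50 <- function(series, method = c("loglinear", "fourpl")) {
  method <- match.arg(method)
  stopifnot(inherits(series, "dose_response"))
  conc <- series$concentrations
  inh <- series$inhibitions
  if (method == "loglinear") {
    cl <- pmin(pmax(inh, 0), 100)
    exact <- which(cl == 50)
    if (length(exact) > 0L) return(conc[exact[1L]])
    lo <- cl[-length(cl)]; hi <- cl[-1L]
    brack <- which((lo - 50) * (hi - 50) < 0)
    if (length(brack) == 0L) stop("IC50 outside tested range")
    if (length(brack) > 1L) {
      warning("multiple bracketing pairs; using the first")
    }
    i <- brack[1L]
    lx <- log10(conc[i]); ux <- log10(conc[i + 1L])
    ly <- cl[i]; uy <- cl[i + 1L]
    10^(lx + (50 - ly) * (ux - lx) / (uy - ly))
  } else {
    if (length(conc) < 4L) stop("fourpl needs >= 4 points")
    start <- list(lower = min(inh), upper = max(inh),
                  ic50 = tryCatch(estimate_ic50(series, "loglinear"),
                                  error = function(e) stats::median(conc),
                                  warning = function(w) stats::median(conc)),
                  hill = 1)
    fit <- minpack.lm::nlsLM(
      inh ~ lower + (upper - lower) / (1 + (ic50 / conc)^hill),
      data = data.frame(conc = conc, inh = inh),
      start = start,
      lower = c(-Inf, -Inf, min(conc) / 100, 0.05),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    unname(stats::coef(fit)["ic50"])
  }
}

#' Fit a linear calibration curve
#'
#' Ordinary least squares of instrument response on standard concentration —
#' the calibration used to express results as gallic acid equivalents (TPC)
#' or ascorbic acid equivalents (FRAP).
#'
#' @param concentrations Standard concentrations (>= 2 distinct).
#' @param responses Instrument responses.
#' @param equivalent_unit `"GAE"` or `"AAE"` (metadata only).
#' @return A `calibration_curve` with `slope`, `intercept`, `r_squared`.
#' @export
fit_calibration <- function(concentrations, responses,
                            equivalent_unit = c("GAE", "AAE")) {
  equivalent_unit <- match.arg(equivalent_unit)
  stopifnot(length(concentrations) == length(responses))
  if (length(unique(concentrations)) < 2L) {
    stop("need >= 2 distinct standard concentrations")
  }
  fit <- stats::lm(responses ~ concentrations)
  slope <- unname(stats::coef(fit)[2L])
  if (slope == 0) stop("degenerate calibration: slope is 0")
  ss_tot <- sum((responses - mean(responses))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(standard_concentrations = concentrations,
                 responses = responses, slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2, equivalent_unit = equivalent_unit),
            class = "calibration_curve")
}

#' Quantify a sample against a calibration curve
#'
#' `((response - intercept) / slope) * dilution_factor`.  Negative
#' concentrations (responses below the blank) are returned with a warning.
#'
#' @param curve A `calibration_curve`.
#' @param response Sample response (vectorized).
#' @param dilution_factor Multiplicative dilution correction. Default 1.
#' @return Equivalent concentration in the curve's standard units.
#' @export
quantify <- function(curve, response, dilution_factor = 1) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("calibration slope is 0")
  out <- (response - curve$intercept) / curve$slope * dilution_factor
  if (any(out < 0)) warning("negative equivalent concentration")
  out
}
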