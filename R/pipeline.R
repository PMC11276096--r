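#' Pipeline configuration
#'
#' Defaults reproduce the conventions of the worked-example study: non-detects
#' entered as structural zeros, PCA and the phenolics-vs-assay correlations on
#' the 7 cultivar means, network of 11 hidden neurons trained at replicate
#' scale (21 samples).
#'
#' @param seed Integer seed for every stochastic stage.
#' @param nd_policy `"zero"` or `"exclude"`.
#' @param pca_unit `"means"` (one row per cultivar) or `"replicates"`
#'   (simulated replicate rows).
#' @param correlation_unit Unit for the phenolics-vs-assay correlation table;
#'   `"means"` matches the published convention.
#' @param hidden,restarts Network training parameters for the synthetic
#'   demonstration stage.
#' @param include_ann Run the synthetic training demonstration (the slowest
#'   stage).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, nd_policy = "zero",
                            pca_unit = c("means", "replicates"),
                            correlation_unit = c("means", "replicates"),
                            hidden = 11L, restarts = 5L,
                            include_ann = TRUE) {
  structure(list(seed = as.integer(seed), nd_policy = nd_policy,
                 pca_unit = match.arg(pca_unit),
                 correlation_unit = match.arg(correlation_unit),
                 hidden = as.integer(hidden), restarts = as.integer(restarts),
                 include_ann = isTRUE(include_ann)),
            class = "pipeline_config")
}

# Pivot simulated replicate-level measurements to a replicate x variable matrix.
replicate_matrix <- function(measurements, variables, nd_policy = "zero") {
  m <- measurements[measurements$analyte %in% variables, , drop = FALSE]
  v <- m$value
  v[!m$detected] <- if (nd_policy == "zero") 0 else NA_real_
  key <- paste(m$cultivar, m$replicate, sep = "_r")
  rows <- unique(key)
  out <- matrix(NA_real_, length(rows), length(variables),
                dimnames = list(rows, variables))
  out[cbind(match(key, rows), match(m$analyte, variables))] <- v
  keep <- colSums(!is.na(out) & out != 0) > 0
  out[is.na(out)] <- 0
  out[, keep, drop = FALSE]
}

#' Reproduce the full worked-example analysis
#'
#' Runs every stage of the analysis from the packaged tables: (a)
#' correlation-matrix PCA of the 13-phenolic and 15-acid/sugar cultivar-mean
#' matrices with explained variance and per-variable contributions; (b) the
#' phenolics-vs-antioxidant correlation table with t-based p-values; (c)
#' Yoon connection-weight sensitivity from the packaged trained network; and
#' (d) a seeded synthetic-data demonstration of the assay (IC50 recovery)
#' and, optionally, network-training stages.  Deterministic under a fixed
#' config.
#'
#' @param config A [pipeline_config()].
#' @return A `report_bundle` list.
#' @export
run_paper_reproduction <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))

  phen <- apple_summaries("phenolics")
  assays <- apple_summaries("assays")
  acids <- apple_summaries("organic_acids")
  sugars <- apple_summaries("sugars")
  acid_sugar <- rbind(acids, sugars)
  class(acid_sugar) <- class(acids)

  pca_input <- function(summaries, variables) {
    if (config$pca_unit == "means") {
      pivot_to_matrix(summaries, variables, config$nd_policy)
    } else {
      sim <- simulate_replicates(summaries, 3L, seed = config$seed)
      new_feature_matrix(replicate_matrix(sim, variables, config$nd_policy))
    }
  }
  fm_phen <- pca_input(phen, phenolic_pca_variables())
  fm_acid <- pca_input(acid_sugar, acid_sugar_pca_variables())
  pca_phen <- pca_cor(fm_phen)
  pca_acid <- pca_cor(fm_acid)

  # phenolics vs assay endpoints on cultivar means (published convention)
  fmx <- pivot_to_matrix(phen, phenolic_pca_variables(), config$nd_policy)
  cultivars <- rownames(fmx$values)
  endpoint <- function(an) {
    sub <- assays[assays$analyte == an, ]
    stats::setNames(sub$mean, sub$cultivar)[cultivars]
  }
  correlations <- do.call(rbind, lapply(c("DPPH_IC50", "FRAP"), function(an) {
    tab <- correlate_columns(fmx$values, endpoint(an))
    tab$endpoint <- an
    tab
  }))

  sens <- yoon_ri(do.call(load_weight_tables, as.list(apple_weight_paths())))

  demo_series <- simulate_dose_response(
    ic50 = 400, concentrations = c(100, 200, 400, 800, 1600),
    noise_sd = 2, seed = config$seed)
  assay_demo <- list(true_ic50 = 400,
                     estimated_ic50 = estimate_ic50(demo_series),
                     series = demo_series)

  ann_demo <- NULL
  if (config$include_ann) {
    train <- simulate_training_set(n_samples = 21L, seed = config$seed)
    model <- mlp_fit(train$inputs, train$outputs, hidden = config$hidden,
                     restarts = config$restarts, seed = config$seed + 1L)
    ann_demo <- list(model = model, training_r2 = model$training_r2,
                     sensitivity = yoon_ri(model))
  }

  structure(list(config = config,
                 summaries = list(phenolics = phen, assays = assays,
                                  organic_acids = acids, sugars = sugars),
                 pca = list(phenolics = pca_phen, acid_sugar = pca_acid,
                            phenolics_var2 = explained_variance(pca_phen, 2L),
                            acid_sugar_var3 = explained_variance(pca_acid, 3L)),
                 correlations = correlations,
                 sensitivity = sens,
                 assay_demo = assay_demo,
                 ann_demo = ann_demo),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle (seed ", x$config$seed, ")\n", sep = "")
  cat(sprintf(" phenolics PCA: PC1-2 capture %.1f%% of 13 variables\n",
              x$pca$phenolics_var2))
  cat(sprintf(" acid/sugar PCA: PC1-3 capture %.1f%% of %d variables\n",
              x$pca$acid_sugar_var3, x$pca$acid_sugar$n_variables))
  top <- rank_influences(x$sensitivity, "DPPH")
  cat(sprintf(" strongest DPPH influences: %s (%+.2f%%), %s (%+.2f%%)\n",
              top$input[1], top$ri[1],
              top$input[nrow(top)], top$ri[nrow(top)]))
  if (!is.null(x$ann_demo)) {
    cat(sprintf(" synthetic training r2: %s\n",
                paste(sprintf("%.4f", x$ann_demo$training_r2), collapse = ", ")))
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits delimited-text tables (PCA variance and contributions, correlation
#' table, sensitivity report) plus `summary.json`, a machine-readable record
#' of the headline numbers.  Regenerating with the same config yields
#' identical numeric content.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  for (which in c("phenolics", "acid_sugar")) {
    res <- bundle$pca[[which]]
    wr(data.frame(component = seq_along(res$eigenvalues),
                  eigenvalue = res$eigenvalues,
                  explained_percent = 100 * res$explained_fraction),
       paste0("pca_", which, "_variance.csv"))
    contrib <- do.call(rbind, lapply(1:3, function(j) {
      d <- variable_contributions(res, j); d$component <- j; d
    }))
    wr(contrib, paste0("pca_", which, "_contributions.csv"))
  }
  wr(bundle$correlations, "correlations.csv")
  wr(as.data.frame(bundle$sensitivity), "sensitivity.csv")

  summary <- list(
    seed = bundle$config$seed,
    phenolics_pc12_percent = bundle$pca$phenolics_var2,
    acid_sugar_pc123_percent = bundle$pca$acid_sugar_var3,
    pCA_DPPH = as.list(bundle$correlations[
      bundle$correlations$variable == "pCA" &
        bundle$correlations$endpoint == "DPPH_IC50",
      c("r", "n", "p_value")]),
    pCB2_DPPH = as.list(bundle$correlations[
      bundle$correlations$variable == "pCB2" &
        bundle$correlations$endpoint == "DPPH_IC50",
      c("r", "n", "p_value")]),
    yoon_ri = list(DPPH = as.list(bundle$sensitivity$ri[, "DPPH"]),
                   FRAP = as.list(bundle$sensitivity$ri[, "FRAP"])),
    assay_demo_ic50 = bundle$assay_demo$estimated_ic50)
  if (!is.null(bundle$ann_demo)) {
    summary$training_r2 <- as.list(bundle$ann_demo$training_r2)
  }
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
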