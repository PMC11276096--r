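# In-code fixtures shared across test files.

# Minimal well-formed long-format measurement table.
make_measurements <- function(cultivars = c("Gala", "Fuji"),
                              analytes = "CA",
                              values = NULL, n_rep = 3L) {
  grid <- expand.grid(replicate = seq_len(n_rep), cultivar = cultivars,
                      analyte = analytes, stringsAsFactors = FALSE)
  if (is.null(values)) values <- seq_len(nrow(grid))
  out <- data.frame(cultivar = grid$cultivar, analyte = grid$analyte,
                    analyte_class = "phenolic", replicate = grid$replicate,
                    value = values, detected = !is.na(values),
                    unit = "mg/kg FW", stringsAsFactors = FALSE)
  class(out) <- c("analyte_measurements", "data.frame")
  out
}

write_long_csv <- function(df, path = tempfile(fileext = ".csv")) {
  df$value <- ifelse(is.na(df$value), "n.d.", as.character(df$value))
  utils::write.csv(df[, c("cultivar", "analyte", "analyte_class",
                          "replicate", "value", "unit")],
                   path, row.names = FALSE, quote = FALSE)
  path
}

# A fixed small network used as a known generative function.
small_net <- function(m = 3L, h = 2L, q = 1L, seed = 99L) {
  withr::with_seed(seed, {
    mlp_weights(matrix(stats::runif(m * h, -1, 1), m, h),
                stats::runif(h, -0.5, 0.5),
                matrix(stats::runif(h * q, -1, 1), h, q),
                stats::runif(q, -0.5, 0.5))
  })
}

paper_weights <- function() {
  p <- apple_weight_paths()
  load_weight_tables(p["w1"], p["w2"])
}

cultivar_means <- function(table, analyte) {
  s <- apple_summaries(table)
  sub <- s[s$analyte == analyte, ]
  stats::setNames(ifelse(sub$detected, sub$mean, 0), sub$cultivar)
}
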