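test_that("long-table reading parses values, non-detects and rejects bad rows", {
  df <- make_measurements(values = c(1, 2, 3, 4, 5, 6))
  path <- write_long_csv(df)
  got <- read_long_table(path)
  expect_s3_class(got, "analyte_measurements")
  expect_equal(nrow(got), 6L)
  expect_equal(got$value, 1:6 * 1.0)
  expect_true(all(got$detected))

  # non-detect token -> detected = FALSE, value absent
  df$value[2] <- NA
  got <- read_long_table(write_long_csv(df))
  expect_false(got$detected[2])
  expect_true(is.na(got$value[2]))

  # duplicated replicate key
  dup <- df; dup$replicate[2] <- 1L; dup$value[2] <- 9
  expect_error(read_long_table(write_long_csv(dup)), "duplicate")

  # malformed numeric names the line
  bad <- tempfile(fileext = ".csv")
  writeLines(c("cultivar,analyte,analyte_class,replicate,value,unit",
               "Gala,CA,phenolic,1,3.5,mg/kg FW",
               "Gala,CA,phenolic,2,oops,mg/kg FW"), bad)
  expect_error(read_long_table(bad), "malformed value at data line 2")

  # missing column
  noval <- tempfile(fileext = ".csv")
  writeLines(c("cultivar,analyte,replicate", "Gala,CA,1"), noval)
  expect_error(read_long_table(noval), "missing required column")
})

test_that("summaries use the sample sd and honour the non-detect policy", {
  m <- make_measurements(cultivars = "Gala", values = c(1, 2, 3))
  s <- summarize_measurements(m)
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$n, 3L)

  # {5, n.d., n.d.}: zero policy averages over {5, 0, 0}
  m <- make_measurements(cultivars = "Gala", values = c(5, NA, NA))
  s0 <- summarize_measurements(m, "zero")
  expect_equal(s0$mean, 5 / 3)
  expect_equal(s0$sd, sd(c(5, 0, 0)))
  expect_equal(s0$n, 3L)
  # exclude policy drops them (leaving a singleton, which warns)
  expect_warning(sx <- summarize_measurements(m, "exclude"), "single value")
  expect_equal(sx$mean, 5)
  expect_equal(sx$n, 1L)

  # all-non-detect group flagged absent under exclude
  m <- make_measurements(cultivars = "Gala", values = c(NA, NA, NA))
  sx <- summarize_measurements(m, "exclude")
  expect_false(sx$detected)
  expect_true(is.na(sx$mean))

  # single value: sd = 0 with warning
  m <- make_measurements(cultivars = "Gala", values = 4, n_rep = 1L)
  expect_warning(s1 <- summarize_measurements(m), "single value")
  expect_equal(s1$mean, 4)
  expect_equal(s1$sd, 0)

  expect_warning(empty <- summarize_measurements(make_measurements()[0, ]),
                 "no measurements")
  expect_equal(nrow(empty), 0L)
})

test_that("letter display separates clearly different groups and is a valid
           compact display against the all-pairs Tukey oracle", {
  # two groups, means 0 and 10, sd ~0.1: separation >> critical range
  m <- make_measurements(cultivars = c("lo", "hi"),
                         values = c(0.0, 0.1, -0.1, 10.0, 10.1, 9.9))
  lt <- assign_letters(m)
  expect_equal(lt$letter[lt$cultivar == "lo"], "a")
  expect_equal(lt$letter[lt$cultivar == "hi"], "b")

  # identical groups all share "a"
  m <- make_measurements(cultivars = c("g1", "g2", "g3"),
                         values = rep(c(1, 2, 3), 3))
  lt <- assign_letters(m)
  expect_true(all(lt$letter == "a"))

  # property: share a letter iff Tukey p > alpha, across random 5-group cases
  for (seed in 1:8) {
    vals <- withr::with_seed(seed, rnorm(15, mean = rep(seed * c(0, 1, 2, 4, 8), each = 3)))
    m <- make_measurements(cultivars = paste0("g", 1:5), values = vals)
    lt <- assign_letters(m)
    labels <- setNames(lt$letter, lt$cultivar)
    fit <- aov(value ~ cultivar, data = transform(m, cultivar = factor(cultivar)))
    tuk <- TukeyHSD(fit)$cultivar
    for (pair in rownames(tuk)) {
      ab <- strsplit(pair, "-", fixed = TRUE)[[1]]
      share <- length(intersect(strsplit(labels[ab[1]], "")[[1]],
                                strsplit(labels[ab[2]], "")[[1]])) > 0
      expect_equal(share, tuk[pair, "p adj"] > 0.05,
                   label = paste("seed", seed, "pair", pair))
    }
  }

  # group with n < 2 errors, naming the group
  m <- rbind(make_measurements(cultivars = "g1", values = c(1, 2, 3)),
             make_measurements(cultivars = "g2", values = 5, n_rep = 1L))
  expect_error(suppressWarnings(assign_letters(m)), "g2")
})

test_that("pivoting drops all-non-detect variables and is invertible for retained cells", {
  phen <- apple_summaries("phenolics")
  all_vars <- c("A", "HBA", "GA", "pCA", "CA", "nCA", "C", "E", "pCB1",
                "pCB2", "Q3ga", "Q3gl", "Q3ru", "Q3rh", "P")
  fm <- pivot_to_matrix(phen, all_vars)
  expect_equal(dim(fm$values), c(7L, 13L))
  expect_setequal(fm$dropped_columns$column, c("HBA", "pCB1"))
  expect_true(all(fm$dropped_columns$reason == "zero variance / all n.d."))

  # retained cells round-trip to the summaries (n.d. -> 0)
  for (v in colnames(fm$values)) {
    sub <- phen[phen$analyte == v, ]
    expect_equal(fm$values[sub$cultivar, v],
                 setNames(ifelse(sub$detected, sub$mean, 0), sub$cultivar))
  }

  # acid/sugar matrix: galactose dropped, 15 retained
  ac <- rbind(apple_summaries("organic_acids"), apple_summaries("sugars"))
  fm2 <- pivot_to_matrix(ac, c("QA", "LA", "ShA", "GA", "SuA", "MA", "FA",
                               "OA", "P", "CA", "MI", "S", "Gal", "Glu",
                               "Fru", "Suc"))
  expect_equal(ncol(fm2$values), 15L)
  expect_equal(fm2$dropped_columns$column, "Gal")

  expect_error(pivot_to_matrix(phen, character()), "empty variable list")
  expect_error(pivot_to_matrix(phen, "nope"), "no summary")
})

test_that("standardization yields exact zero mean / unit variance and is recorded", {
  fm <- pivot_to_matrix(apple_summaries("phenolics"),
                        c("GA", "CA", "C", "E"))
  z <- standardize_features(fm)
  expect_true(z$standardized)
  expect_lt(max(abs(colMeans(z$values))), 1e-10)
  expect_lt(max(abs(apply(z$values, 2, sd) - 1)), 1e-10)
  # invertible via recorded centring/scale
  back <- sweep(sweep(z$values, 2, z$column_sds, "*"), 2, z$column_means, "+")
  expect_equal(unname(back), unname(fm$values), tolerance = 1e-12)
})

test_that("summary tables round-trip through delimited text", {
  s <- apple_summaries("assays")
  path <- tempfile(fileext = ".csv")
  write_summary_table(s, path)
  back <- read_summary_table(path)
  expect_equal(back$mean, s$mean, tolerance = 1e-6)
  expect_equal(back$detected, s$detected)
})
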