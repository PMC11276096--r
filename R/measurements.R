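#' Read a long-format analyte table
#'
#' Reads replicate-level analyte concentrations from delimited text with the
#' header `cultivar,analyte,analyte_class,replicate,value,unit`.  Values are
#' numeric concentrations or a non-detect token (default `"n.d."`); a
#' non-detect is a structural absence, not a zero, and is carried as
#' `detected = FALSE` with `value = NA` until a non-detect policy is applied
#' downstream.
#'
#' @param path Path to a delimited text file (UTF-8).
#' @param delim Field delimiter. `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @param nd_token Literal token marking a non-detect. Default `"n.d."`.
#' @return A data frame of class `analyte_measurements` with columns
#'   `cultivar`, `analyte`, `analyte_class`, `replicate` (integer), `value`
#'   (numeric, `NA` when not detected), `detected` (logical) and `unit`.
#' @export
read_long_table <- function(path, delim = NULL, nd_token = "n.d.") {
  stopifnot(file.exists(path))
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", check.names = TRUE,
                           strip.white = TRUE, quote = "\"",
                           fileEncoding = "UTF-8")
  required <- c("cultivar", "analyte", "analyte_class", "replicate", "value")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (!"unit" %in% names(raw)) raw$unit <- NA_character_

  detected <- raw$value != nd_token
  value <- rep(NA_real_, nrow(raw))
  value[detected] <- suppressWarnings(as.numeric(raw$value[detected]))
  bad <- which(detected & is.na(value))
  if (length(bad) > 0L) {
    stop("malformed value at data line ", bad[1L], ": '", raw$value[bad[1L]],
         "' is neither numeric nor the non-detect token '", nd_token, "'")
  }
  replicate <- suppressWarnings(as.integer(raw$replicate))
  bad <- which(is.na(replicate) | replicate < 1L)
  if (length(bad) > 0L) {
    stop("malformed replicate at data line ", bad[1L], ": '",
         raw$replicate[bad[1L]], "'")
  }
  if (any(value[detected] < 0)) {
    stop("negative concentration for detected measurement at data line ",
         which(detected & value < 0)[1L])
  }
  key <- paste(raw$cultivar, raw$analyte, replicate, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    parts <- strsplit(d, "\r", fixed = TRUE)[[1L]]
    stop("duplicate (cultivar, analyte, replicate) key: (",
         parts[1L], ", ", parts[2L], ", ", parts[3L], ")")
  }
  out <- data.frame(cultivar = raw$cultivar, analyte = raw$analyte,
                    analyte_class = raw$analyte_class, replicate = replicate,
                    value = value, detected = detected, unit = raw$unit,
                    stringsAsFactors = FALSE)
  class(out) <- c("analyte_measurements", "data.frame")
  out
}

#' Read a per-cultivar summary table
#'
#' Reads summary files with columns `cultivar,analyte,analyte_class,mean,sd,n,unit`
#' (the format in which the packaged worked-example tables ship).  Non-detect
#' rows carry the non-detect token in the `mean` and `sd` columns.
#'
#' @inheritParams read_long_table
#' @return A data frame of class `cultivar_summary` with numeric `mean`/`sd`
#'   (`NA` when not detected), integer `n`, and logical `detected`.
#' @export
read_summary_table <- function(path, delim = ",", nd_token = "n.d.") {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", strip.white = TRUE,
                           quote = "\"", fileEncoding = "UTF-8")
  required <- c("cultivar", "analyte", "mean", "sd", "n")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  detected <- raw$mean != nd_token
  num <- function(x, where) {
    out <- rep(NA_real_, length(x))
    out[detected] <- suppressWarnings(as.numeric(x[detected]))
    bad <- which(detected & is.na(out))
    if (length(bad) > 0L) {
      stop("malformed ", where, " at data line ", bad[1L], ": '", x[bad[1L]], "'")
    }
    out
  }
  out <- data.frame(
    cultivar = raw$cultivar, analyte = raw$analyte,
    analyte_class = if ("analyte_class" %in% names(raw)) raw$analyte_class else NA_character_,
    mean = num(raw$mean, "mean"), sd = num(raw$sd, "sd"),
    n = as.integer(raw$n), detected = detected,
    unit = if ("unit" %in% names(raw)) raw$unit else NA_character_,
    stringsAsFactors = FALSE)
  if (any(out$sd[out$detected] < 0, na.rm = TRUE)) stop("negative sd in summary file")
  class(out) <- c("cultivar_summary", "data.frame")
  out
}

#' Summarize replicate measurements per cultivar and analyte
#'
#' Computes the per-(cultivar, analyte) mean and sample standard deviation
#' (n - 1 denominator), the convention under which the worked-example tables
#' report "means (n = 3) +/- standard deviations".
#'
#' Non-detects are handled by `nd_policy`: `"zero"` (default) enters them as
#' concentration 0 before averaging; `"exclude"` drops them, and a group in
#' which nothing was detected is returned flagged `detected = FALSE` with
#' `mean = sd = NA`.
#'
#' @param measurements An `analyte_measurements` data frame
#'   (see [read_long_table()]).
#' @param nd_policy `"zero"` or `"exclude"`.
#' @return A `cultivar_summary` data frame. Groups with a single retained
#'   value get `sd = 0` with a warning.
#' @export
summarize_measurements <- function(measurements, nd_policy = c("zero", "exclude")) {
  nd_policy <- match.arg(nd_policy)
  if (nrow(measurements) == 0L) {
    warning("no measurements; returning empty summary")
    out <- data.frame(cultivar = character(), analyte = character(),
                      analyte_class = character(), mean = numeric(),
                      sd = numeric(), n = integer(), detected = logical(),
                      unit = character(), stringsAsFactors = FALSE)
    class(out) <- c("cultivar_summary", "data.frame")
    return(out)
  }
  groups <- split(seq_len(nrow(measurements)),
                  list(measurements$cultivar, measurements$analyte),
                  drop = TRUE)
  singleton <- FALSE
  rows <- lapply(groups, function(idx) {
    g <- measurements[idx, , drop = FALSE]
    v <- g$value
    v[!g$detected] <- if (nd_policy == "zero") 0 else NA_real_
    v <- v[!is.na(v)]
    any_detected <- any(g$detected)
    if (length(v) == 0L) {            # all non-detect under "exclude"
      m <- NA_real_; s <- NA_real_; n <- 0L
    } else {
      m <- mean(v)
      n <- length(v)
      if (n == 1L) { s <- 0; singleton <<- TRUE } else s <- stats::sd(v)
    }
    data.frame(cultivar = g$cultivar[1L], analyte = g$analyte[1L],
               analyte_class = g$analyte_class[1L], mean = m, sd = s, n = n,
               detected = any_detected, unit = g$unit[1L],
               stringsAsFactors = FALSE)
  })
  if (singleton) warning("group(s) with a single value: sd set to 0")
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$analyte, out$cultivar), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cultivar_summary", "data.frame")
  out
}

#' Assign compact-letter-display significance letters
#'
#' For each analyte, runs a one-way ANOVA of concentration on cultivar
#' followed by Tukey HSD pairwise comparisons at level `alpha`, and summarises
#' the comparisons as a compact letter display: cultivars sharing at least one
#' letter are not significantly different.  Letters start at `"a"` for the
#' smallest mean (ties broken by cultivar name).
#'
#' @param measurements An `analyte_measurements` data frame; every
#'   (cultivar, analyte) group needs at least 2 replicates and each analyte at
#'   least 2 cultivars.
#' @param alpha Significance level for the Tukey HSD family. Default 0.05.
#' @param nd_policy Non-detect policy passed to [summarize_measurements()];
#'   `"zero"` also enters non-detects as 0 in the ANOVA.
#' @return A `cultivar_summary` data frame with an added `letter` column.
#' @export
assign_letters <- function(measurements, alpha = 0.05,
                           nd_policy = c("zero", "exclude")) {
  nd_policy <- match.arg(nd_policy)
  summaries <- summarize_measurements(measurements, nd_policy)
  summaries$letter <- NA_character_
  for (an in unique(summaries$analyte)) {
    g <- measurements[measurements$analyte == an, , drop = FALSE]
    v <- g$value
    v[!g$detected] <- if (nd_policy == "zero") 0 else NA_real_
    keep <- !is.na(v)
    g <- g[keep, , drop = FALSE]; v <- v[keep]
    if (nrow(g) == 0L) next                       # all n.d., nothing to test
    counts <- table(g$cultivar)
    if (any(counts < 2L)) {
      stop("analyte '", an, "': group '", names(counts)[counts < 2L][1L],
           "' has fewer than 2 replicates")
    }
    if (length(counts) < 2L) stop("analyte '", an, "': fewer than 2 groups")
    fit <- stats::aov(v ~ cultivar, data = data.frame(v = v, cultivar = factor(g$cultivar)))
    tuk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$cultivar
    means <- tapply(v, g$cultivar, mean)
    letters <- compact_letter_display(rownames(tuk), tuk[, "p adj"], means, alpha)
    idx <- summaries$analyte == an & summaries$cultivar %in% names(letters)
    summaries$letter[idx] <- letters[summaries$cultivar[idx]]
  }
  summaries
}

# Insert-and-absorb compact letter display.
# pair_names: "B-A" style rownames from TukeyHSD; p: adjusted p-values;
# means: named group means (letter order: "a" = smallest mean).
compact_letter_display <- function(pair_names, p, means, alpha) {
  groups <- names(means)[order(means, names(means))]
  sig <- p < alpha
  pairs <- strsplit(pair_names, "-", fixed = TRUE)
  # columns: list of character vectors of group names sharing a letter
  cols <- list(groups)
  for (k in seq_along(pairs)) {
    if (!sig[k]) next
    a <- pairs[[k]][1L]; b <- pairs[[k]][2L]
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (a %in% col && b %in% col) {
        cols[[ci]] <- setdiff(col, a)
        cols[[length(cols) + 1L]] <- setdiff(col, b)
      }
    }
    # absorb columns that duplicate or are contained in another column
    keep <- rep(TRUE, length(cols))
    for (i in seq_along(cols)) {
      for (j in seq_along(cols)) {
        if (i == j || !keep[i] || !keep[j]) next
        subset_ij <- all(cols[[i]] %in% cols[[j]])
        equal_ij <- subset_ij && length(cols[[i]]) == length(cols[[j]])
        if (subset_ij && (!equal_ij || j < i)) keep[i] <- FALSE
      }
    }
    cols <- cols[keep]
  }
  # order letter columns by the smallest-mean member so "a" labels low means
  first_mean <- vapply(cols, function(col) min(means[col]), numeric(1))
  cols <- cols[order(first_mean)]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (ci in seq_along(cols)) {
    out[cols[[ci]]] <- paste0(out[cols[[ci]]], letters[ci])
  }
  # sort letters within each label
  vapply(out, function(s) paste(sort(strsplit(s, "")[[1L]]), collapse = ""),
         character(1))
}

#' Pivot cultivar summaries to a samples-by-variables matrix
#'
#' Builds the feature matrix consumed by the multivariate stages: rows are
#' cultivars, columns the requested analytes, cells the per-cultivar means.
#' Variables detected in no cultivar are dropped (reason
#' `"zero variance / all n.d."`) rather than entering as constant-zero
#' columns; partial non-detects become 0 under `nd_policy = "zero"`.
#'
#' @param summaries A `cultivar_summary` data frame.
#' @param variables Ordered character vector of analytes to include.
#' @param nd_policy `"zero"` or `"exclude"` (the latter errors if any retained
#'   cell would be missing).
#' @return A `feature_matrix` object; see [standardize_features()].
#' @export
pivot_to_matrix <- function(summaries, variables, nd_policy = c("zero", "exclude")) {
  nd_policy <- match.arg(nd_policy)
  if (length(variables) == 0L) stop("empty variable list")
  missing_vars <- setdiff(variables, summaries$analyte)
  if (length(missing_vars) > 0L) {
    stop("no summary for variable(s): ", paste(missing_vars, collapse = ", "))
  }
  cultivars <- unique(summaries$cultivar)
  values <- matrix(NA_real_, length(cultivars), length(variables),
                   dimnames = list(cultivars, variables))
  detected_any <- stats::setNames(rep(FALSE, length(variables)), variables)
  for (v in variables) {
    sub <- summaries[summaries$analyte == v, , drop = FALSE]
    detected_any[v] <- any(sub$detected)
    for (cu in cultivars) {
      row <- sub[sub$cultivar == cu, , drop = FALSE]
      if (nrow(row) == 0L) {
        stop("missing (cultivar, variable) pair: (", cu, ", ", v, ")")
      }
      values[cu, v] <- if (row$detected[1L]) row$mean[1L] else NA_real_
    }
  }
  dropped <- data.frame(column = variables[!detected_any],
                        reason = rep("zero variance / all n.d.",
                                     sum(!detected_any)),
                        stringsAsFactors = FALSE)
  values <- values[, detected_any, drop = FALSE]
  if (nd_policy == "zero") {
    values[is.na(values)] <- 0
  } else if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop("non-detect cell (", rownames(values)[idx[1L]], ", ",
         colnames(values)[idx[2L]], ") has no value under nd_policy = 'exclude'")
  }
  new_feature_matrix(values, dropped = dropped)
}

new_feature_matrix <- function(values, standardized = FALSE,
                               column_means = NULL, column_sds = NULL,
                               dropped = data.frame(column = character(),
                                                    reason = character())) {
  structure(list(values = values, standardized = standardized,
                 column_means = column_means, column_sds = column_sds,
                 dropped_columns = dropped),
            class = "feature_matrix")
}

#' Standardize a feature matrix to zero mean and unit variance
#'
#' Z-scores every column, recording the centring/scaling so the operation is
#' invertible.  Zero-variance columns are moved to `dropped_columns` instead
#' of producing divide-by-zero artifacts.  Standardization removes the
#' measurement scale, so columns in different units (mg/kg vs g/kg) are
#' legitimately mixed in one matrix.
#'
#' @param fm A `feature_matrix` (or plain numeric matrix).
#' @return A standardized `feature_matrix`.
#' @export
standardize_features <- function(fm) {
  if (is.matrix(fm)) fm <- new_feature_matrix(fm)
  stopifnot(inherits(fm, "feature_matrix"))
  if (fm$standardized) return(fm)
  x <- fm$values
  mu <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  dropped <- fm$dropped_columns
  if (any(const)) {
    dropped <- rbind(dropped,
                     data.frame(column = colnames(x)[const],
                                reason = "zero variance",
                                stringsAsFactors = FALSE))
    x <- x[, !const, drop = FALSE]; mu <- mu[!const]; sds <- sds[!const]
  }
  z <- scale(x, center = mu, scale = sds)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  new_feature_matrix(z, standardized = TRUE, column_means = mu,
                     column_sds = sds, dropped = dropped)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix: ", nrow(x$values), " samples x ", ncol(x$values),
      " variables", if (x$standardized) " (standardized)", "\n", sep = "")
  if (nrow(x$dropped_columns) > 0L) {
    cat("dropped:", paste0(x$dropped_columns$column, " [",
                           x$dropped_columns$reason, "]", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a cultivar summary table to delimited text
#'
#' @param summaries A `cultivar_summary` data frame.
#' @param path Output path.
#' @param nd_token Token written for non-detected groups.
#' @export
write_summary_table <- function(summaries, path, nd_token = "n.d.") {
  out <- as.data.frame(summaries)
  for (col in c("mean", "sd")) {
    out[[col]] <- ifelse(out$detected, format(out[[col]], trim = TRUE),
                         nd_token)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
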