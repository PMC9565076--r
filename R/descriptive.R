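#' Summary statistics with coefficient of variation
#'
#' Computes the descriptive row reported for each survey variable: n, mean,
#' sample SD (n-1 denominator), median, min, max and the coefficient of
#' variation CV = 100 * sd / mean (percent). Values are kept at full
#' precision; rounding is a presentation concern.
#'
#' @param x Numeric vector (NAs dropped with a count retained).
#' @param variable Variable name carried into the output.
#' @return One-row data frame: `variable, n, mean, sd, median, min, max, cv`.
#' @export
summarize_variable <- function(x, variable = deparse(substitute(x))) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) {
    stop_cd("insufficient_data",
            sprintf("variable '%s': need at least 2 observations", variable))
  }
  m <- mean(x)
  s <- stats::sd(x)
  cv <- if (m == 0) NA_real_ else 100 * s / m
  data.frame(variable = variable, n = length(x), mean = m, sd = s,
             median = stats::median(x), min = min(x), max = max(x), cv = cv,
             stringsAsFactors = FALSE)
}

#' Summary table over several dataset columns
#'
#' @param data Soil-wheat data frame.
#' @param variables Character vector of column names to summarise.
#' @return Data frame with one [summarize_variable()] row per variable.
#' @export
summary_table <- function(data,
                          variables = c("soil_cd", "ph", "caco3", "om",
                                        "clay", "silt", "sand", "ca", "fe",
                                        "mn", "p", "zn")) {
  variables <- intersect(variables, names(data))
  do.call(rbind, lapply(variables, function(v) {
    summarize_variable(data[[v]], v)
  }))
}

#' Regulatory exceedance screening
#'
#' Counts samples strictly above a regulatory limit, e.g. the maximum
#' permissible Cd concentrations of 1 mg/kg for agricultural soil (GB 15618)
#' and 0.1 mg/kg for wheat grain (GB 2762).
#'
#' @param values Numeric vector of concentrations (NAs dropped).
#' @param limit Positive regulatory limit; exceedance is `value > limit`.
#' @return List with `count`, `n` and `percent` (= 100 * count / n).
#' @export
exceedance <- function(values, limit) {
  if (!is.numeric(limit) || length(limit) != 1L || limit <= 0) {
    stop_cd("config_error", "limit must be a single positive number")
  }
  values <- values[!is.na(values)]
  if (!length(values)) stop_cd("insufficient_data", "no non-missing values")
  count <- sum(values > limit)
  list(count = count, n = length(values),
       percent = 100 * count / length(values))
}

#' Tessier fraction percentages for one sample
#'
#' Expresses the five sequential-extraction Cd fractions (exchangeable,
#' carbonate-bound, Fe-Mn-oxide-bound, organic-bound, residual) as percent of
#' the fraction sum, plus the non-residual share `100 - re_cd%` that proxies
#' bioavailable Cd. Percentages are taken on the fraction sum rather than on
#' total soil Cd so that extraction-recovery error cannot distort the
#' ordering.
#'
#' @param fractions Named numeric vector or one-row data frame containing
#'   `ex_cd, ca_cd, fm_cd, or_cd, re_cd` (mg/kg).
#' @return Named numeric vector of the five percentages plus `nonresidual`;
#'   the five fraction percentages sum to 100.
#' @export
fraction_percentages <- function(fractions) {
  if (is.data.frame(fractions)) fractions <- unlist(fractions[1, , drop = TRUE])
  missing <- setdiff(.fraction_cols, names(fractions))
  if (length(missing)) {
    stop_cd("missing_column", paste0("missing Tessier fraction column(s): ",
                                     paste(missing, collapse = ", ")))
  }
  f <- as.numeric(fractions[.fraction_cols])
  names(f) <- .fraction_cols
  tot <- sum(f)
  if (!is.finite(tot) || tot <= 0) {
    stop_cd("domain_error", "fraction sum must be positive")
  }
  pct <- 100 * f / tot
  c(pct, nonresidual = 100 - unname(pct["re_cd"]))
}

#' Per-sample Tessier percentage table
#'
#' @param data Soil-wheat data frame containing the five fraction columns.
#' @return Data frame with `sample_id`, the five percentages and
#'   `nonresidual`, one row per sample.
#' @export
fraction_table <- function(data) {
  missing <- setdiff(.fraction_cols, names(data))
  if (length(missing)) {
    stop_cd("missing_column", paste0("missing Tessier fraction column(s): ",
                                     paste(missing, collapse = ", ")))
  }
  rows <- lapply(seq_len(nrow(data)), function(i) {
    as.data.frame(as.list(fraction_percentages(data[i, .fraction_cols])))
  })
  out <- do.call(rbind, rows)
  cbind(data.frame(sample_id = data$sample_id, stringsAsFactors = FALSE), out)
}

#' Pearson correlation table with two-tailed significance flags
#'
#' For each requested (x, y) pair, computes the Pearson correlation on the
#' pairwise-complete cases, with the two-tailed p-value from the
#' t-distribution on n - 2 degrees of freedom, and flags significance at the
#' conventional 0.05 / 0.01 cutoffs.
#'
#' @param data Soil-wheat data frame.
#' @param pairs List of length-2 character vectors `c(x, y)`, or a two-column
#'   data frame / matrix of column names.
#' @return Data frame: `var_x, var_y, n, r, p_two_tailed, significance` where
#'   significance is one of `"", "*", "**"` (`*` p < 0.05, `**` p < 0.01).
#' @export
correlation_table <- function(data, pairs) {
  if (is.matrix(pairs) || is.data.frame(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)), function(i) as.character(unlist(pairs[i, 1:2])))
  }
  rows <- lapply(pairs, function(pr) {
    vx <- pr[[1]]; vy <- pr[[2]]
    for (v in c(vx, vy)) {
      if (!v %in% names(data)) {
        stop_cd("missing_column", paste0("no such column: ", v))
      }
    }
    ok <- stats::complete.cases(data[[vx]], data[[vy]])
    x <- data[[vx]][ok]; y <- data[[vy]][ok]
    if (length(x) < 3L) {
      stop_cd("insufficient_data", sprintf(
        "pair (%s, %s): need at least 3 complete cases", vx, vy))
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      zv <- if (stats::sd(x) == 0) vx else vy
      stop_cd("degenerate_error", paste0(
        "correlation undefined: zero variance in '", zv, "'"))
    }
    ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
    r <- unname(ct$estimate)
    p <- ct$p.value
    data.frame(var_x = vx, var_y = vy, n = length(x), r = r,
               p_two_tailed = p,
               significance = if (p < 0.01) "**" else if (p < 0.05) "*" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
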