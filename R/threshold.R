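#' Specification of a two-regime threshold regression
#'
#' Declares one threshold fit: which column is the response (typically
#' `log_bcf`), which is the regressor, and which is the threshold variable
#' `q` that splits the sample into regime 1 (`q <= gamma`) and regime 2
#' (`q > gamma`). Candidate thresholds are the distinct observed values of
#' `q`, trimmed so each regime keeps at least
#' `max(ceiling(trim_fraction * n), min_regime_size)` observations.
#'
#' @param response Response column name.
#' @param predictor Regressor column name (a character vector fits the same
#'   slope set in each regime; the default study models use one regressor).
#' @param threshold_var Threshold variable column name.
#' @param trim_fraction Fraction of the sample excluded from each tail of the
#'   candidate grid; must be in (0, 0.5). Default 0.15.
#' @param min_regime_size Minimum observations per regime; defaults to the
#'   number of regression coefficients + 1 so each regime is estimable with
#'   a residual degree of freedom.
#' @param include_intercept Include a per-regime intercept (default TRUE, as
#'   in the study's regime equations).
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(response, predictor, threshold_var,
                           trim_fraction = 0.15, min_regime_size = NULL,
                           include_intercept = TRUE) {
  if (!is.numeric(trim_fraction) || trim_fraction <= 0 || trim_fraction >= 0.5) {
    stop_cd("config_error", "trim_fraction must be in (0, 0.5)")
  }
  p <- length(predictor) + as.integer(include_intercept)
  if (is.null(min_regime_size)) min_regime_size <- p + 1L
  if (min_regime_size < p + 1L) {
    stop_cd("config_error", sprintf(
      "min_regime_size must be at least %d (coefficients + 1)", p + 1L))
  }
  structure(list(response = response, predictor = predictor,
                 threshold_var = threshold_var,
                 trim_fraction = trim_fraction,
                 min_regime_size = as.integer(min_regime_size),
                 include_intercept = isTRUE(include_intercept)),
            class = "threshold_spec")
}

#' Candidate threshold grid
#'
#' The grid is the set of distinct observed values of the threshold variable
#' at which a split `q <= gamma` versus `q > gamma` leaves both regimes with
#' at least `max(ceiling(trim_fraction * n), min_regime_size)` observations.
#' Tied observations always fall on the regime-1 side of their own value.
#'
#' @param q Numeric vector of threshold-variable values.
#' @param spec A [threshold_spec()].
#' @return Sorted numeric vector of admissible candidate thresholds.
#' @export
build_grid <- function(q, spec) {
  q <- q[!is.na(q)]
  n <- length(q)
  if (length(unique(q)) < 2L) {
    stop_cd("degenerate_threshold",
            "threshold variable has fewer than 2 distinct values")
  }
  qs <- sort(q)
  m <- max(ceiling(spec$trim_fraction * n), spec$min_regime_size)
  # k = number of observations with q <= candidate; candidates end a tie group
  k_end <- which(qs[-n] < qs[-1])
  keep <- k_end[k_end >= m & (n - k_end) >= m]
  if (!length(keep)) {
    stop_cd("degenerate_threshold",
            "no admissible threshold candidate after trimming")
  }
  qs[keep]
}

# Fast concentrated scan for a single regressor with intercept: O(n) via
# prefix sums after sorting by q. Returns per-candidate SSRs and, for each
# candidate, enough to reconstruct regime coefficients.
.scan_single <- function(y, x, q, spec) {
  n <- length(y)
  ord <- order(q, method = "radix")
  ys <- y[ord]; xs <- x[ord]; qs <- q[ord]
  m <- max(ceiling(spec$trim_fraction * n), spec$min_regime_size)
  k_end <- which(qs[-n] < qs[-1])
  ks <- k_end[k_end >= m & (n - k_end) >= m]
  if (!length(ks)) {
    stop_cd("degenerate_threshold",
            "no admissible threshold candidate after trimming")
  }
  cx <- cumsum(xs); cy <- cumsum(ys)
  cxx <- cumsum(xs * xs); cyy <- cumsum(ys * ys); cxy <- cumsum(xs * ys)

  moments <- function(sx, sy, sxx, syy, sxy, nn) {
    if (spec$include_intercept) {
      Sxx <- sxx - sx^2 / nn
      Sxy <- sxy - sx * sy / nn
      Syy <- syy - sy^2 / nn
    } else {
      Sxx <- sxx; Sxy <- sxy; Syy <- syy
    }
    list(Sxx = Sxx, Sxy = Sxy, Syy = Syy)
  }

  lo <- moments(cx[ks], cy[ks], cxx[ks], cyy[ks], cxy[ks], ks)
  hi <- moments(cx[n] - cx[ks], cy[n] - cy[ks], cxx[n] - cxx[ks],
                cyy[n] - cyy[ks], cxy[n] - cxy[ks], n - ks)
  tol <- 1e-12 * max(cxx[n], 1)
  if (any(lo$Sxx <= tol) || any(hi$Sxx <= tol)) {
    stop_cd("regime_singularity",
            "regressor is (numerically) constant within a candidate regime")
  }
  ssr_lo <- pmax(lo$Syy - lo$Sxy^2 / lo$Sxx, 0)
  ssr_hi <- pmax(hi$Syy - hi$Sxy^2 / hi$Sxx, 0)

  list(gamma = qs[ks], k = ks, n = n, ord = ord,
       ssr = ssr_lo + ssr_hi, ssr_lo = ssr_lo, ssr_hi = ssr_hi,
       sst_lo = pmax(lo$Syy, 0), sst_hi = pmax(hi$Syy, 0),
       slope_lo = lo$Sxy / lo$Sxx, slope_hi = hi$Sxy / hi$Sxx,
       mean_x_lo = cx[ks] / ks, mean_y_lo = cy[ks] / ks,
       mean_x_hi = (cx[n] - cx[ks]) / (n - ks),
       mean_y_hi = (cy[n] - cy[ks]) / (n - ks))
}

# Generic per-candidate OLS (used for multi-regressor specs).
.ols <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    stop_cd("regime_singularity", "singular design within a regime")
  }
  list(coef = fit$coefficients, ssr = sum(fit$residuals^2))
}

.design <- function(data, spec) {
  X <- as.matrix(data[, spec$predictor, drop = FALSE])
  if (spec$include_intercept) X <- cbind(`(Intercept)` = 1, X)
  X
}

#' Concentrated SSR at one candidate threshold
#'
#' Splits the sample at `q <= gamma` versus `q > gamma` and fits an
#' independent OLS regression in each regime; the concentrated sum of squared
#' residuals is the total over both regimes.
#'
#' @param data Data frame containing the spec's columns.
#' @param spec A [threshold_spec()].
#' @param gamma Candidate threshold; must be an admissible grid value from
#'   [build_grid()].
#' @return List with `ssr`, `beta_low`, `beta_high`, `n_low`, `n_high`.
#' @export
ssr_at <- function(data, spec, gamma) {
  data <- .complete_cases(data, spec)
  grid <- build_grid(data[[spec$threshold_var]], spec)
  if (!any(abs(grid - gamma) <= 1e-12 * pmax(abs(grid), 1))) {
    stop_cd("config_error",
            sprintf("gamma = %g is not an admissible grid candidate", gamma))
  }
  q <- data[[spec$threshold_var]]
  y <- data[[spec$response]]
  X <- .design(data, spec)
  low <- q <= gamma
  f1 <- .ols(y[low], X[low, , drop = FALSE])
  f2 <- .ols(y[!low], X[!low, , drop = FALSE])
  list(ssr = f1$ssr + f2$ssr, beta_low = f1$coef, beta_high = f2$coef,
       n_low = sum(low), n_high = sum(!low))
}

#' Single-regime OLS baseline (the no-threshold null)
#'
#' @param data Data frame containing the spec's columns.
#' @param spec A [threshold_spec()].
#' @return List with `coef`, `ssr_null`, `r2`.
#' @export
linear_baseline <- function(data, spec) {
  data <- .complete_cases(data, spec)
  y <- data[[spec$response]]
  X <- .design(data, spec)
  f <- .ols(y, X)
  sst <- if (spec$include_intercept) sum((y - mean(y))^2) else sum(y^2)
  list(coef = f$coef, ssr_null = f$ssr,
       r2 = if (sst > 0) 1 - f$ssr / sst else NA_real_)
}

.complete_cases <- function(data, spec) {
  cols <- unique(c(spec$response, spec$predictor, spec$threshold_var))
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stop_cd("missing_column",
            paste0("no such column(s): ", paste(missing, collapse = ", ")))
  }
  ok <- stats::complete.cases(data[, cols, drop = FALSE])
  if (any(!ok)) {
    message(sprintf("dropping %d incomplete case(s) for (%s ~ %s | %s)",
                    sum(!ok), spec$response,
                    paste(spec$predictor, collapse = "+"),
                    spec$threshold_var))
  }
  data[ok, , drop = FALSE]
}

#' Fit a two-regime threshold regression
#'
#' Estimates the threshold by concentrated least squares: for every
#' admissible candidate `gamma` in the grid of distinct observed values of
#' the threshold variable, independent OLS regressions are fitted on the
#' `q <= gamma` and `q > gamma` subsets, and `gamma_hat` minimises the total
#' SSR (ties broken toward the smallest candidate). The likelihood-ratio
#' sequence `LR(gamma) = n * (S(gamma) - S(gamma_hat)) / sigma2_hat` with
#' `sigma2_hat = S(gamma_hat) / n` is stored for confidence-set inversion.
#'
#' @param data Data frame; incomplete cases in the used columns are dropped
#'   (with a message).
#' @param spec A [threshold_spec()].
#' @return An object of class `threshold_fit` with elements `gamma_hat`,
#'   `beta_low`, `beta_high`, `n_low`, `n_high`, `ssr`, `sigma2`, `r2_low`,
#'   `r2_high`, `lr` (data frame `gamma, ssr, lr`), `ssr_null`, `r2_null`,
#'   `beta_null`, `sup_stat`, and placeholders `ci` / `boot_p` filled by
#'   [gamma_ci()] and [bootstrap_test()].
#' @export
fit_threshold <- function(data, spec) {
  data <- .complete_cases(data, spec)
  y <- data[[spec$response]]
  q <- data[[spec$threshold_var]]
  n <- length(y)
  base <- linear_baseline(data, spec)

  if (length(spec$predictor) == 1L && spec$include_intercept) {
    sc <- .scan_single(y, data[[spec$predictor]], q, spec)
    i <- which.min(sc$ssr)
    gamma_hat <- sc$gamma[i]
    beta_low <- c(`(Intercept)` = sc$mean_y_lo[i] - sc$slope_lo[i] * sc$mean_x_lo[i],
                  sc$slope_lo[i])
    beta_high <- c(`(Intercept)` = sc$mean_y_hi[i] - sc$slope_hi[i] * sc$mean_x_hi[i],
                   sc$slope_hi[i])
    names(beta_low)[2] <- names(beta_high)[2] <- spec$predictor
    n_low <- sc$k[i]; n_high <- n - sc$k[i]
    ssr_grid <- sc$ssr
    grid <- sc$gamma
    r2_low <- if (sc$sst_lo[i] > 0) 1 - sc$ssr_lo[i] / sc$sst_lo[i] else NA_real_
    r2_high <- if (sc$sst_hi[i] > 0) 1 - sc$ssr_hi[i] / sc$sst_hi[i] else NA_real_
  } else {
    grid <- build_grid(q, spec)
    at <- lapply(grid, function(g) ssr_at(data, spec, g))
    ssr_grid <- vapply(at, `[[`, numeric(1), "ssr")
    i <- which.min(ssr_grid)
    gamma_hat <- grid[i]
    best <- at[[i]]
    beta_low <- best$beta_low; beta_high <- best$beta_high
    n_low <- best$n_low; n_high <- best$n_high
    low <- q <= gamma_hat
    r2_low <- .r2_subset(data[low, , drop = FALSE], spec, beta_low)
    r2_high <- .r2_subset(data[!low, , drop = FALSE], spec, beta_high)
  }

  ssr_min <- ssr_grid[i]
  sigma2 <- ssr_min / n
  degenerate <- sigma2 <= 1e-12 * max(mean(y^2), 1)
  lr <- if (degenerate) rep(NA_real_, length(grid))
        else n * (ssr_grid - ssr_min) / sigma2
  sup_stat <- if (degenerate) NA_real_
              else n * (base$ssr_null - ssr_min) / sigma2

  structure(list(
    spec = spec, n = n,
    gamma_hat = gamma_hat,
    beta_low = beta_low, beta_high = beta_high,
    n_low = n_low, n_high = n_high,
    ssr = ssr_min, sigma2 = sigma2,
    r2_low = r2_low, r2_high = r2_high,
    lr = data.frame(gamma = grid, ssr = ssr_grid, lr = lr),
    q_values = sort(unique(q)),
    beta_null = base$coef, ssr_null = base$ssr_null, r2_null = base$r2,
    sup_stat = sup_stat, boot_p = NA_real_, ci = NULL,
    degenerate_variance = degenerate
  ), class = "threshold_fit")
}

.r2_subset <- function(sub, spec, beta) {
  y <- sub[[spec$response]]
  X <- .design(sub, spec)
  res <- y - drop(X %*% beta)
  sst <- if (spec$include_intercept) sum((y - mean(y))^2) else sum(y^2)
  if (sst > 0) 1 - sum(res^2) / sst else NA_real_
}

#' Likelihood-ratio sequence of a fitted threshold model
#'
#' `LR(gamma) = n * (S(gamma) - S(gamma_hat)) / sigma2_hat`, zero at the
#' estimate and non-negative everywhere.
#'
#' @param fit A [fit_threshold()] result.
#' @return Data frame with columns `gamma` and `lr`.
#' @export
lr_sequence <- function(fit) {
  stopifnot(inherits(fit, "threshold_fit"))
  if (isTRUE(fit$degenerate_variance)) {
    stop_cd("degenerate_variance",
            "residual variance is zero: LR sequence undefined")
  }
  fit$lr[, c("gamma", "lr")]
}

#' Likelihood-ratio inversion confidence set for the threshold
#'
#' The level-(1 - alpha) confidence set collects the grid candidates whose
#' LR statistic does not exceed the asymptotic critical value
#' `c(alpha) = -2 * log(1 - sqrt(1 - alpha))` (7.3523 at alpha = 0.05); it
#' always contains `gamma_hat`. Because every threshold between a candidate
#' and the next distinct observed value of the threshold variable induces
#' the same sample split, the LR curve is a step function of gamma, and the
#' inverted region in continuous gamma is the half-open interval from the
#' smallest accepted candidate up to the observed value following the
#' largest accepted candidate; `upper` reports that supremum. A flag marks
#' confidence sets whose accepted candidates are not contiguous in the grid
#' (they are reported un-convexified).
#'
#' @param fit A [fit_threshold()] result.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return List with `lower` (smallest accepted candidate), `upper`
#'   (supremum of the acceptance region in continuous gamma),
#'   `upper_candidate` (largest accepted grid candidate), `contiguous`,
#'   `set` (accepted candidates), `critical` and `alpha`.
#' @export
gamma_ci <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "threshold_fit"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_cd("config_error", "alpha must be in (0, 1)")
  }
  lr <- lr_sequence(fit)
  crit <- lr_critical_value(alpha)
  acc <- which(lr$lr <= crit)
  upper_cand <- max(lr$gamma[acc])
  qv <- fit$q_values
  nxt <- qv[qv > upper_cand]
  list(lower = min(lr$gamma[acc]),
       upper = if (length(nxt)) min(nxt) else upper_cand,
       upper_candidate = upper_cand,
       contiguous = all(diff(acc) == 1L),
       set = lr$gamma[acc], critical = crit, alpha = alpha)
}

#' Asymptotic critical value for LR threshold inversion
#'
#' @param alpha Significance level in (0, 1).
#' @return `-2 * log(1 - sqrt(1 - alpha))`.
#' @export
lr_critical_value <- function(alpha) {
  if (!is.numeric(alpha) || any(alpha <= 0) || any(alpha >= 1)) {
    stop_cd("config_error", "alpha must be in (0, 1)")
  }
  -2 * log(1 - sqrt(1 - alpha))
}

#' Residual-bootstrap test for the existence of a threshold
#'
#' Tests the single-regime null (equal coefficients in both regimes) against
#' the two-regime alternative with the sup-F statistic
#' `n * (SSR_null - S(gamma_hat)) / sigma2_hat`. Because the threshold is not
#' identified under the null, the distribution is approximated by a residual
#' bootstrap: responses are regenerated as null fitted values plus residuals
#' resampled with replacement, the design and threshold variable held fixed,
#' and the sup-F recomputed on each resample. The p-value is
#' `(1 + #{sup-F* >= observed}) / (n_boot + 1)`.
#'
#' @param data Data frame containing the spec's columns.
#' @param spec A [threshold_spec()].
#' @param n_boot Number of bootstrap resamples, at least 99 (default 499).
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return List with `sup_stat`, `boot_p`, `n_boot`, `seed` and the vector
#'   `boot_stats`.
#' @export
bootstrap_test <- function(data, spec, n_boot = 499L, seed = NULL) {
  if (!is.numeric(n_boot) || n_boot < 99) {
    stop_cd("config_error", "n_boot must be at least 99")
  }
  n_boot <- as.integer(n_boot)
  data <- .complete_cases(data, spec)
  fit <- fit_threshold(data, spec)
  if (isTRUE(fit$degenerate_variance)) {
    stop_cd("degenerate_variance",
            "residual variance is zero: bootstrap test undefined")
  }
  y <- data[[spec$response]]
  X <- .design(data, spec)
  null <- .ols(y, X)
  fitted0 <- drop(X %*% null$coef)
  resid0 <- y - fitted0
  n <- length(y)
  boot_data <- data

  boot_stats <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    ystar <- fitted0 + sample(resid0, n, replace = TRUE)
    boot_data[[spec$response]] <- ystar
    fb <- fit_threshold(boot_data, spec)
    fb$sup_stat
  }, numeric(1)))

  boot_p <- (1 + sum(boot_stats >= fit$sup_stat)) / (n_boot + 1)
  list(sup_stat = fit$sup_stat, boot_p = boot_p, n_boot = n_boot,
       seed = seed, boot_stats = boot_stats)
}

#' Build a threshold model from published coefficients
#'
#' Constructs a minimal `threshold_fit` from externally reported regime
#' equations (threshold estimate plus per-regime intercept and slope), so
#' that [predict.threshold_fit()] can evaluate published two-regime models
#' on new data without access to the raw data behind them.
#'
#' @param response,predictor,threshold_var Column names as in
#'   [threshold_spec()].
#' @param gamma Reported threshold estimate.
#' @param beta_low,beta_high `(intercept, slope)` of the `q <= gamma` and
#'   `q > gamma` equations.
#' @return An object of class `threshold_fit` supporting `predict()`; all
#'   estimation-dependent fields are `NA`.
#' @export
manual_threshold_fit <- function(response, predictor, threshold_var,
                                 gamma, beta_low, beta_high) {
  spec <- threshold_spec(response, predictor, threshold_var)
  beta_low <- stats::setNames(beta_low, c("(Intercept)", predictor))
  beta_high <- stats::setNames(beta_high, c("(Intercept)", predictor))
  structure(list(
    spec = spec, n = NA_integer_, gamma_hat = gamma,
    beta_low = beta_low, beta_high = beta_high,
    n_low = NA_integer_, n_high = NA_integer_,
    ssr = NA_real_, sigma2 = NA_real_,
    r2_low = NA_real_, r2_high = NA_real_,
    lr = data.frame(gamma = gamma, ssr = NA_real_, lr = NA_real_),
    q_values = gamma,
    beta_null = NULL, ssr_null = NA_real_, r2_null = NA_real_,
    sup_stat = NA_real_, boot_p = NA_real_, ci = NULL,
    degenerate_variance = FALSE
  ), class = "threshold_fit")
}

#' Predict from a fitted threshold model
#'
#' Evaluates the regime-1 equation where the threshold variable is at or
#' below `gamma_hat` and the regime-2 equation above it. Extrapolation
#' beyond the fitted range is allowed; an `"extrapolated"` attribute flags
#' such points.
#'
#' @param object A `threshold_fit`.
#' @param newdata Data frame with the spec's predictor and threshold-variable
#'   columns (the training data columns by name).
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.threshold_fit <- function(object, newdata, ...) {
  spec <- object$spec
  X <- .design(newdata, spec)
  q <- newdata[[spec$threshold_var]]
  low <- q <= object$gamma_hat
  out <- ifelse(low, drop(X %*% object$beta_low),
                drop(X %*% object$beta_high))
  rng <- range(object$lr$gamma)
  attr(out, "extrapolated") <- q < rng[1] | q > rng[2]
  out
}

#' @export
print.threshold_fit <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Two-regime threshold regression: %s ~ %s | threshold on %s\n",
              s$response, paste(s$predictor, collapse = " + "),
              s$threshold_var))
  cat(sprintf("  n = %d (regime 1: %d, regime 2: %d), gamma_hat = %.4g\n",
              x$n, x$n_low, x$n_high, x$gamma_hat))
  cat(sprintf("  regime 1 (q <= gamma): [%s], R2 = %.3f\n",
              paste(sprintf("%.4g", x$beta_low), collapse = ", "), x$r2_low))
  cat(sprintf("  regime 2 (q >  gamma): [%s], R2 = %.3f\n",
              paste(sprintf("%.4g", x$beta_high), collapse = ", "), x$r2_high))
  cat(sprintf("  SSR = %.6g (null %.6g), sup-F = %.4g",
              x$ssr, x$ssr_null, x$sup_stat))
  if (!is.na(x$boot_p)) cat(sprintf(", bootstrap p = %.4g", x$boot_p))
  cat("\n")
  invisible(x)
}

#' Fit the full battery of threshold models
#'
#' One fit per (response, predictor, threshold variable) combination, with
#' the bootstrap existence test and LR confidence set attached.
#' Combinations that fail (e.g. degenerate grids) are retained as rows with
#' an error message rather than aborting the batch; combinations with no
#' significant threshold are retained with their bootstrap p-value, since a
#' non-effect is a result.
#'
#' @param data Data frame with derived columns (see [add_derived()]).
#' @param responses Response column name(s); default `"log_bcf"`.
#' @param predictors Regressor column names tried one at a time.
#' @param threshold_vars Threshold-variable column names.
#' @param trim_fraction,min_regime_size,include_intercept Passed to
#'   [threshold_spec()].
#' @param n_boot Bootstrap resamples per fit (default 499).
#' @param alpha Significance level for the confidence set and the
#'   threshold-effect gate `boot_p <= alpha` (default 0.05).
#' @param seed Master seed; each combination gets a deterministic sub-seed.
#' @return Data frame with one row per combination; the fitted
#'   `threshold_fit` objects are attached as attribute `"fits"` (named
#'   `response~predictor|threshold_var`).
#' @export
fit_all <- function(data, responses = "log_bcf", predictors,
                    threshold_vars, trim_fraction = 0.15,
                    min_regime_size = NULL, include_intercept = TRUE,
                    n_boot = 499L, alpha = 0.05, seed = NULL) {
  combos <- expand.grid(response = responses, predictor = predictors,
                        threshold_var = threshold_vars,
                        stringsAsFactors = FALSE)
  if (!nrow(combos)) {
    return(structure(data.frame(), fits = list()))
  }
  seeds <- if (is.null(seed)) rep(list(NULL), nrow(combos))
           else as.list(sub_seeds(seed, n_streams = nrow(combos)))
  fits <- list()
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    resp <- combos$response[i]; pred <- combos$predictor[i]
    qv <- combos$threshold_var[i]
    key <- sprintf("%s~%s|%s", resp, pred, qv)
    base_row <- data.frame(
      response = resp, predictor = pred, threshold_var = qv,
      n = NA_integer_, gamma = NA_real_,
      intercept_low = NA_real_, slope_low = NA_real_, r2_low = NA_real_,
      n_low = NA_integer_,
      intercept_high = NA_real_, slope_high = NA_real_, r2_high = NA_real_,
      n_high = NA_integer_,
      ssr = NA_real_, ssr_null = NA_real_, r2_null = NA_real_,
      sup_stat = NA_real_, boot_p = NA_real_,
      ci_lower = NA_real_, ci_upper = NA_real_, ci_contiguous = NA,
      significant = NA, error = NA_character_,
      stringsAsFactors = FALSE)
    tryCatch({
      sp <- threshold_spec(resp, pred, qv, trim_fraction = trim_fraction,
                           min_regime_size = min_regime_size,
                           include_intercept = include_intercept)
      fit <- fit_threshold(data, sp)
      bt <- bootstrap_test(data, sp, n_boot = n_boot, seed = seeds[[i]])
      fit$boot_p <- bt$boot_p
      ci <- gamma_ci(fit, alpha = alpha)
      fit$ci <- ci
      fits[[key]] <<- fit
      base_row$n <- fit$n
      base_row$gamma <- fit$gamma_hat
      base_row$intercept_low <- unname(fit$beta_low[1])
      base_row$slope_low <- unname(fit$beta_low[2])
      base_row$r2_low <- fit$r2_low
      base_row$n_low <- fit$n_low
      base_row$intercept_high <- unname(fit$beta_high[1])
      base_row$slope_high <- unname(fit$beta_high[2])
      base_row$r2_high <- fit$r2_high
      base_row$n_high <- fit$n_high
      base_row$ssr <- fit$ssr
      base_row$ssr_null <- fit$ssr_null
      base_row$r2_null <- fit$r2_null
      base_row$sup_stat <- fit$sup_stat
      base_row$boot_p <- bt$boot_p
      base_row$ci_lower <- ci$lower
      base_row$ci_upper <- ci$upper
      base_row$ci_contiguous <- ci$contiguous
      base_row$significant <- bt$boot_p <= alpha
      base_row
    }, cdtransfer_error = function(e) {
      base_row$error <- conditionMessage(e)
      base_row
    })
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  out
}
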