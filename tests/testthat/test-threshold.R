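spec_yxq <- threshold_spec("y", "x", "q")

test_that("the candidate grid enumerates admissible trimmed splits", {
  sp <- threshold_spec("y", "x", "q", trim_fraction = 0.15,
                       min_regime_size = 3)
  g <- build_grid(1:20, sp)
  expect_identical(g, 3:17)

  expect_error(build_grid(rep(2, 10), sp),
               class = "cdtransfer_degenerate_threshold")

  # n = 22 at 15% trimming keeps at least ceiling(0.15*22) = 4 per regime
  set.seed(5)
  q22 <- runif(22)
  g22 <- build_grid(q22, sp)
  for (g1 in range(g22)) {
    expect_gte(sum(q22 <= g1), 4)
    expect_gte(sum(q22 > g1), 4)
  }
})

test_that("concentrated SSR at a candidate equals two independent OLS fits", {
  d <- data.frame(q = c(1, 2, 3, 4, 5, 6, 7, 8),
                  x = c(0.5, 1.1, -0.3, 2.0, 1.4, -0.8, 0.2, 1.7),
                  y = c(1.0, 2.3, 0.1, 3.9, -0.5, 1.8, 0.9, -1.2))
  sp <- threshold_spec("y", "x", "q", trim_fraction = 0.3,
                       min_regime_size = 3)
  g <- build_grid(d$q, sp)
  for (gam in g) {
    at <- ssr_at(d, sp, gam)
    f1 <- lm(y ~ x, d[d$q <= gam, ])
    f2 <- lm(y ~ x, d[d$q > gam, ])
    expect_equal(at$ssr, sum(resid(f1)^2) + sum(resid(f2)^2),
                 tolerance = 1e-10)
    expect_equal(unname(at$beta_low), unname(coef(f1)), tolerance = 1e-10)
    expect_equal(unname(at$beta_high), unname(coef(f2)), tolerance = 1e-10)
  }
  expect_error(ssr_at(d, sp, 0.5), class = "cdtransfer_config_error")
})

test_that("identical regimes with zero noise give zero SSR and equal betas", {
  set.seed(31)
  d <- data.frame(q = runif(30), x = rnorm(30))
  d$y <- 1.5 - 2 * d$x
  sp <- threshold_spec("y", "x", "q")
  g <- build_grid(d$q, sp)
  at <- ssr_at(d, sp, g[3])
  expect_equal(at$ssr, 0, tolerance = 1e-20)
  expect_equal(at$beta_low, at$beta_high, tolerance = 1e-9)
})

test_that("fit_threshold agrees with the exhaustive brute-force oracle", {
  for (seed in 1:12) {
    d <- random_small_data(seed)
    bf <- brute_force_threshold(d, "y", "x", "q")
    f <- fit_threshold(d, spec_yxq)
    expect_identical(f$gamma_hat, bf$gamma)
    expect_equal(f$ssr, bf$ssr, tolerance = 1e-9)
    expect_equal(f$lr$ssr, bf$ssr_all, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("a planted grid-point threshold is recovered exactly", {
  set.seed(77)
  n <- 200
  q <- c(sample(setdiff(1:10, 5), n - 1, replace = TRUE), 5) +
    round(runif(n, -0.4, 0.4), 3)
  q[n] <- 5.0  # ensure 5.0 is an observed (grid) value
  x <- q
  y <- ifelse(q <= 5, -x, x) + rnorm(n, 0, 0.1)
  d <- data.frame(q = q, x = x, y = y)
  f <- fit_threshold(d, spec_yxq)
  expect_identical(f$gamma_hat, 5.0)
  expect_lt(f$beta_low["x"], 0)
  expect_gt(f$beta_high["x"], 0)
})

test_that("the LR sequence follows its defining formula and is zero at the estimate", {
  # direct arithmetic: n = 22, S(gamma) = 12, S(gamma_hat) = 10
  expect_equal(22 * (12 - 10) / (10 / 22), 96.8)

  d <- random_small_data(3, n = 28)
  f <- fit_threshold(d, spec_yxq)
  lr <- lr_sequence(f)
  expect_equal(lr$lr, f$n * (f$lr$ssr - f$ssr) / (f$ssr / f$n),
               tolerance = 1e-12)
  expect_identical(min(lr$lr), 0)
  expect_true(all(lr$lr >= 0))
  expect_identical(lr$gamma[which.min(lr$lr)], f$gamma_hat)
})

test_that("zero residual variance is flagged and blocks LR and bootstrap", {
  set.seed(13)
  d <- data.frame(q = runif(30), x = rnorm(30))
  d$y <- 2 + 3 * d$x  # exact single-regime fit
  f <- fit_threshold(d, spec_yxq)
  expect_true(f$degenerate_variance)
  expect_error(lr_sequence(f), class = "cdtransfer_degenerate_variance")
  expect_error(bootstrap_test(d, spec_yxq, n_boot = 99, seed = 1),
               class = "cdtransfer_degenerate_variance")
})

test_that("LR inversion uses the closed-form critical values", {
  expect_equal(lr_critical_value(0.05), 7.352277, tolerance = 1e-6)
  expect_equal(lr_critical_value(0.05), -2 * log(1 - sqrt(0.95)),
               tolerance = 1e-12)
  expect_equal(lr_critical_value(0.10), -2 * log(1 - sqrt(0.90)),
               tolerance = 1e-12)
  expect_equal(round(lr_critical_value(0.10), 3), 5.939)
})

test_that("a flat LR sequence yields a confidence set spanning the grid", {
  fake <- manual_threshold_fit("y", "x", "q", gamma = 3,
                               beta_low = c(0, 1), beta_high = c(0, 1))
  fake$lr <- data.frame(gamma = as.numeric(1:5), ssr = rep(2, 5),
                        lr = rep(0, 5))
  fake$q_values <- as.numeric(0:6)
  fake$sigma2 <- 1
  ci <- gamma_ci(fake, 0.05)
  expect_identical(ci$lower, 1)
  expect_identical(ci$upper_candidate, 5)
  expect_identical(ci$upper, 6)  # next observed value above the grid
  expect_true(ci$contiguous)
  expect_identical(ci$set, as.numeric(1:5))
})

test_that("the confidence set always contains the estimate", {
  for (seed in c(2, 9, 17)) {
    d <- random_small_data(seed, n = 26)
    f <- fit_threshold(d, spec_yxq)
    if (f$degenerate_variance) next
    ci <- gamma_ci(f, 0.05)
    expect_true(f$gamma_hat %in% ci$set)
    expect_true(ci$lower <= f$gamma_hat && f$gamma_hat <= ci$upper)
  }
})

test_that("bootstrap existence test is deterministic and detects strong regimes", {
  cfg <- synthetic_config(n = 200, seed = 8, beta_low = c(0, -1),
                          beta_high = c(0, 1), noise_sd = 0.2)
  d <- generate_dataset(cfg)
  sp <- threshold_spec("log_bcf", "ph", "ph")
  b1 <- bootstrap_test(d, sp, n_boot = 199, seed = 123)
  b2 <- bootstrap_test(d, sp, n_boot = 199, seed = 123)
  expect_identical(b1$boot_p, b2$boot_p)
  expect_identical(b1$boot_stats, b2$boot_stats)
  expect_lte(b1$boot_p, 0.01)
  expect_error(bootstrap_test(d, sp, n_boot = 50, seed = 1),
               class = "cdtransfer_config_error")
})

test_that("prediction dispatches on the threshold variable and flags extrapolation", {
  # identity model: both regimes y = x
  idm <- manual_threshold_fit("y", "x", "q", gamma = 2,
                              beta_low = c(0, 1), beta_high = c(0, 1))
  nd <- data.frame(x = c(-1, 0.5, 3), q = c(1, 2, 4))
  expect_equal(unname(predict(idm, nd)), nd$x, ignore_attr = TRUE)

  d <- random_small_data(6, n = 24)
  f <- fit_threshold(d, spec_yxq)
  # piecewise consistency: regime-own fitted values equal per-regime OLS
  low <- d$q <= f$gamma_hat
  f1 <- lm(y ~ x, d[low, ]); f2 <- lm(y ~ x, d[!low, ])
  pr <- predict(f, d)
  expect_equal(unname(pr[low]), unname(fitted(f1)), tolerance = 1e-10)
  expect_equal(unname(pr[!low]), unname(fitted(f2)), tolerance = 1e-10)

  far <- data.frame(x = 100, q = 100)
  expect_true(attr(predict(f, far), "extrapolated"))
})

test_that("fit_all covers the requested cross and keeps failures as rows", {
  d <- generate_dataset(synthetic_config(n = 40, seed = 15))
  tab <- fit_all(d, predictors = "ph", threshold_vars = c("ph", "soil_cd"),
                 n_boot = 99, seed = 1)
  expect_identical(nrow(tab), 2L)
  expect_true(all(is.na(tab$error)))
  expect_length(attr(tab, "fits"), 2L)

  empty <- fit_all(d, predictors = character(0), threshold_vars = "ph",
                   n_boot = 99)
  expect_identical(nrow(empty), 0L)

  # a constant predictor cannot be fit in any regime: row retained with error
  d$flat <- 1
  bad <- fit_all(d, predictors = c("ph", "flat"), threshold_vars = "ph",
                 n_boot = 99, seed = 2)
  expect_identical(nrow(bad), 2L)
  expect_true(is.na(bad$error[bad$predictor == "ph"]))
  expect_false(is.na(bad$error[bad$predictor == "flat"]))
})
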