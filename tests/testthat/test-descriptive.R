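test_that("summary statistics match a hand-computed oracle", {
  x <- c(2.1, 3.7, 0.9, 5.5, 4.4)
  s <- summarize_variable(x, "hand")
  # brute-force formulas
  m <- sum(x) / 5
  sd_hand <- sqrt(sum((x - m)^2) / 4)
  expect_equal(s$mean, m)
  expect_equal(s$sd, sd_hand)
  expect_equal(s$cv, 100 * sd_hand / m)
  expect_equal(s$median, sort(x)[3])
  expect_identical(s$n, 5L)
  expect_true(s$min <= s$median && s$median <= s$max)
})

test_that("summary handles constants and refuses n < 2", {
  s <- summarize_variable(c(5, 5, 5, 5), "const")
  expect_identical(s$sd, 0)
  expect_identical(s$cv, 0)
  expect_error(summarize_variable(3.1, "single"),
               class = "cdtransfer_insufficient_data")
})

test_that("CV is invariant to unit rescaling", {
  set.seed(7)
  x <- rlnorm(40, 1, 0.6)
  expect_equal(summarize_variable(x, "a")$cv,
               summarize_variable(1000 * x, "b")$cv, tolerance = 1e-12)
})

test_that("exceedance is strict and reports percent of non-missing n", {
  x <- c(rep(2, 17), rep(0.5, 5))
  e <- exceedance(x, 1.0)
  expect_identical(e$count, 17L)
  expect_equal(e$percent, 100 * 17 / 22)
  expect_equal(exceedance(c(0.1, 0.2), 1.0)$percent, 0)
  # values exactly at the limit do not exceed it
  expect_identical(exceedance(c(1, 1, 2), 1.0)$count, 1L)
  expect_error(exceedance(numeric(0), 1),
               class = "cdtransfer_insufficient_data")
  expect_error(exceedance(x, -1), class = "cdtransfer_config_error")
})

test_that("Tessier percentages are shares of the fraction sum", {
  eq <- fraction_percentages(c(ex_cd = 1, ca_cd = 1, fm_cd = 1,
                               or_cd = 1, re_cd = 1))
  expect_equal(unname(eq[1:5]), rep(20, 5))
  expect_equal(unname(eq["nonresidual"]), 80)

  mean_comp <- fraction_percentages(c(ex_cd = 0.13, ca_cd = 0.30,
                                      fm_cd = 0.15, or_cd = 0.04,
                                      re_cd = 0.38))
  expect_equal(unname(mean_comp[c("ex_cd", "ca_cd", "fm_cd", "or_cd",
                                  "re_cd")]), c(13, 30, 15, 4, 38))
  expect_equal(unname(mean_comp["nonresidual"]), 62)

  only_res <- fraction_percentages(c(ex_cd = 0, ca_cd = 0, fm_cd = 0,
                                     or_cd = 0, re_cd = 2.2))
  expect_equal(unname(only_res["nonresidual"]), 0)

  expect_error(fraction_percentages(c(ex_cd = 1, ca_cd = 1)),
               class = "cdtransfer_missing_column")
})

test_that("fraction percentages always sum to 100", {
  d <- generate_dataset(synthetic_config(n = 50, seed = 21))
  tab <- fraction_table(d)
  sums <- rowSums(tab[, c("ex_cd", "ca_cd", "fm_cd", "or_cd", "re_cd")])
  expect_equal(sums, rep(100, 50), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("Pearson correlations match the textbook formula", {
  d <- data.frame(a = c(1.2, 2.8, 3.1, 4.9, 6.0),
                  b = c(0.8, 2.1, 2.2, 4.4, 4.9))
  res <- correlation_table(d, list(c("a", "b")))
  # hand formula
  n <- 5
  r_hand <- sum((d$a - mean(d$a)) * (d$b - mean(d$b))) /
    sqrt(sum((d$a - mean(d$a))^2) * sum((d$b - mean(d$b))^2))
  t_hand <- r_hand * sqrt((n - 2) / (1 - r_hand^2))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = n - 2)
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$p_two_tailed, p_hand, tolerance = 1e-12)
  expect_identical(res$n, 5L)
})

test_that("correlation flags, symmetry and affine invariance behave", {
  d <- data.frame(x = 1:10, y = 2 * (1:10))
  res <- correlation_table(d, list(c("x", "y")))
  expect_equal(res$r, 1.0, tolerance = 1e-12)
  expect_identical(res$significance, "**")

  set.seed(99)
  ind <- data.frame(u = rnorm(500), v = rnorm(500))
  ri <- correlation_table(ind, list(c("u", "v")))
  expect_lt(abs(ri$r), 0.1)
  expect_gt(ri$p_two_tailed, 0.01)

  sym <- correlation_table(ind, list(c("u", "v"), c("v", "u")))
  expect_equal(sym$r[1], sym$r[2], tolerance = 1e-12)

  ind$w <- 3 + 2.5 * ind$v  # positive-slope affine transform
  aff <- correlation_table(ind, list(c("u", "v"), c("u", "w")))
  expect_equal(aff$r[1], aff$r[2], tolerance = 1e-12)

  ind$z <- 1
  expect_error(correlation_table(ind, list(c("u", "z"))),
               class = "cdtransfer_degenerate_error")
})
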