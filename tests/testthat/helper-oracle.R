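# Independent brute-force oracle for the concentrated least-squares
# threshold search: exhaustive scan over admissible splits, each regime
# fitted with lm(). Deliberately naive and kept separate from the package's
# prefix-sum implementation.
brute_force_threshold <- function(data, response, predictor, threshold_var,
                                  trim = 0.15, min_size = 3L) {
  q <- data[[threshold_var]]
  n <- nrow(data)
  m <- max(ceiling(trim * n), min_size)
  cands <- sort(unique(q))
  ok <- vapply(cands, function(g) sum(q <= g) >= m && sum(q > g) >= m,
               logical(1))
  cands <- cands[ok]
  ssr <- vapply(cands, function(g) {
    lo <- data[q <= g, , drop = FALSE]
    hi <- data[q > g, , drop = FALSE]
    f1 <- stats::lm(stats::reformulate(predictor, response), data = lo)
    f2 <- stats::lm(stats::reformulate(predictor, response), data = hi)
    sum(stats::resid(f1)^2) + sum(stats::resid(f2)^2)
  }, numeric(1))
  i <- which.min(ssr)
  list(gamma = cands[i], ssr = ssr[i], candidates = cands, ssr_all = ssr)
}

# Random small dataset with a planted split, for oracle-equivalence checks.
random_small_data <- function(seed, n = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(12:30, 1)
  q <- round(runif(n, 0, 10), 2)
  x <- rnorm(n)
  g <- runif(1, 3, 7)
  y <- ifelse(q <= g, 0.5 + 1.2 * x, -0.3 - 0.8 * x) + rnorm(n, 0, 0.5)
  data.frame(y = y, x = x, q = q)
}

# Study-like generator shorthand used across tests.
study_config <- function(n = 22L, seed = 1L, ...) {
  synthetic_config(n = n, seed = seed, ...)
}
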