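test_that("written datasets round-trip through CSV at full precision", {
  d <- generate_dataset(synthetic_config(n = 22, seed = 11))
  out <- withr::local_tempdir()
  write_results(list(dataset = d), out, seed = 11)
  back <- read_dataset(file.path(out, "dataset.csv"), schema_mode = "lenient")
  expect_equal(nrow(back), 22L)
  for (cc in setdiff(cd_schema()$column, "sample_id")) {
    expect_equal(back[[cc]], d[[cc]], tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_identical(back$sample_id, d$sample_id)
})

test_that("rewriting the same tables is byte-identical", {
  d <- generate_dataset(synthetic_config(n = 10, seed = 4))
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  write_results(list(dataset = d), out1, config = list(n = 10), seed = 4)
  write_results(list(dataset = d), out2, config = list(n = 10), seed = 4)
  expect_identical(readBin(file.path(out1, "dataset.csv"), "raw", 1e6),
                   readBin(file.path(out2, "dataset.csv"), "raw", 1e6))
  expect_identical(readLines(file.path(out1, "manifest.json")),
                   readLines(file.path(out2, "manifest.json")))
})

test_that("schema validation rejects missing mandatory columns and bad cells", {
  d <- generate_dataset(synthetic_config(n = 8, seed = 2))
  out <- withr::local_tempdir()
  d_bad <- d[, setdiff(names(d), "grain_cd")]
  utils::write.csv(d_bad, file.path(out, "nograin.csv"), row.names = FALSE)
  expect_error(read_dataset(file.path(out, "nograin.csv")),
               class = "cdtransfer_schema_error")

  d_txt <- d
  d_txt$soil_cd <- as.character(d_txt$soil_cd)
  d_txt$soil_cd[3] <- "oops"
  utils::write.csv(d_txt, file.path(out, "badcell.csv"), row.names = FALSE)
  expect_error(read_dataset(file.path(out, "badcell.csv"), "strict"),
               class = "cdtransfer_parse_error")
  lenient <- read_dataset(file.path(out, "badcell.csv"), "lenient")
  expect_true(is.na(lenient$soil_cd[3]))
  expect_gt(length(attr(lenient, "validation")), 0L)
})

test_that("header aliases map field-style column names onto the schema", {
  d <- generate_dataset(synthetic_config(n = 6, seed = 9))
  out <- withr::local_tempdir()
  ren <- d
  names(ren)[names(ren) == "ex_cd"] <- "Ex-Cd"
  names(ren)[names(ren) == "soil_cd"] <- "Soil Cd"
  names(ren)[names(ren) == "caco3"] <- "CaCO3"
  utils::write.csv(ren, file.path(out, "alias.csv"), row.names = FALSE)
  back <- read_dataset(file.path(out, "alias.csv"), "lenient")
  expect_equal(back$soil_cd, d$soil_cd, tolerance = 1e-12)
  expect_equal(back$ex_cd, d$ex_cd, tolerance = 1e-12)
})

test_that("texture closure is enforced with a configurable tolerance", {
  d <- generate_dataset(synthetic_config(n = 5, seed = 3))
  d$clay[1] <- d$clay[1] + 0.4  # sum now 100.4: inside default 0.5
  expect_silent(validate_dataset(d, "strict"))
  d$clay[1] <- d$clay[1] + 0.3  # sum now 100.7
  expect_error(validate_dataset(d, "strict"),
               class = "cdtransfer_validation_error")
  expect_silent(validate_dataset(d, "strict", texture_tol = 1.0))
})

test_that("BCF is the grain/soil concentration ratio and scale-invariant", {
  expect_identical(compute_bcf(1.0, 1.0), 1.0)
  expect_equal(compute_bcf(0.05, 1.25), 0.04)
  expect_identical(compute_bcf(0, 2.0), 0)
  expect_error(compute_bcf(0.1, 0), class = "cdtransfer_domain_error")
  set.seed(42)
  g <- runif(50, 0.01, 1); s <- runif(50, 0.5, 10); k <- runif(50, 0.1, 100)
  expect_equal(compute_bcf(k * g, k * s), compute_bcf(g, s),
               tolerance = 1e-12)
})

test_that("log10 transform is strict about its domain", {
  expect_identical(log10_strict(1.0), 0)
  expect_equal(log10_strict(0.04), -1.39794, tolerance = 1e-6)
  expect_error(log10_strict(0), class = "cdtransfer_domain_error")
  err <- tryCatch(log10_strict(c(1, -2), ids = c("S1", "S2")),
                  error = identity)
  expect_match(conditionMessage(err), "S2")
})
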