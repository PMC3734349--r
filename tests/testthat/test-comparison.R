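test_that("log Bayes factor semantics: sign, tie, antisymmetry", {
  tie <- log_bayes_factor(-100, -100)
  expect_equal(tie$logBF, 0)
  expect_true(is.na(tie$dominant_model))

  r <- log_bayes_factor(-90, -95)
  expect_equal(r$logBF, 5)
  expect_identical(r$dominant_model, "M_aL")

  expect_equal(log_bayes_factor(-90, -95)$logBF,
               -log_bayes_factor(-95, -90)$logBF)
  expect_error(log_bayes_factor(NaN, 0), "finite")
})

test_that("evidence categories follow the 3 / 20 thresholds", {
  expect_identical(classify_evidence(2), "weak")
  expect_identical(classify_evidence(10), "positive")
  expect_identical(classify_evidence(25), "strong")
  # boundary behavior: thresholds belong to the lower category
  expect_identical(classify_evidence(3), "weak")
  expect_identical(classify_evidence(20), "positive")
  expect_identical(classify_evidence(3 + 1e-9), "positive")
  expect_identical(classify_evidence(20 + 1e-9), "strong")
  expect_error(classify_evidence(-1), "non-negative")
})

test_that("two-model RFX BMS is exact, symmetric and normalized", {
  # identical evidences: symmetry forces Pe = (1/2, 1/2)
  r <- rfx_bms(matrix(0, 5, 2))
  expect_equal(unname(r$Pe), c(0.5, 0.5))
  expect_true(r$exact)

  with_fixture_seed(5, {
    le <- matrix(rnorm(20, sd = 2), 10, 2)
    r2 <- rfx_bms(le)
    expect_equal(sum(r2$Pe), 1, tolerance = 1e-9)
    # exact Beta closed form
    expect_equal(unname(r2$Pe[1]),
                 pbeta(0.5, r2$alpha[[1]], r2$alpha[[2]], lower.tail = FALSE))
    # label permutation permutes outputs
    r3 <- rfx_bms(le[, 2:1])
    expect_equal(unname(r3$Pe), unname(r2$Pe[2:1]), tolerance = 1e-12)
  })
})

test_that("sampled exceedance probabilities match a brute-force Dirichlet oracle", {
  with_fixture_seed(17, {
    le <- matrix(rnorm(30), 10, 3)
  })
  r <- rfx_bms(le, n_samples = 1e5, seed = 7)
  expect_equal(sum(r$Pe), 1, tolerance = 1e-12)
  # independent Monte-Carlo oracle on the fitted concentrations
  pe_mc <- with_fixture_seed(99, {
    draws <- matrix(rgamma(2e5 * 3, shape = rep(r$alpha, each = 2e5)), 2e5, 3)
    tabulate(max.col(draws), 3) / 2e5
  })
  expect_lt(max(abs(unname(r$Pe) - pe_mc)), 0.01)
  # determinism under the same seed
  expect_identical(r$Pe, rfx_bms(le, n_samples = 1e5, seed = 7)$Pe)
})

test_that("RFX BMS reads TSV log evidences and writes JSON", {
  le <- matrix(c(1, 0, 2, 0.5, 0.2, 1.5), 3, 2,
               dimnames = list(NULL, c("M_aL", "M_aR")))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write.table(le, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  r <- rfx_bms(tsv)
  expect_named(r$Pe, c("M_aL", "M_aR"))
  expect_gt(r$Pe[["M_aL"]], 0.5)
  js <- withr::local_tempfile(fileext = ".json")
  write_rfx_json(r, js)
  back <- jsonlite::read_json(js)
  expect_equal(back$Pe$M_aL, unname(r$Pe[1]), tolerance = 1e-12)
  expect_error(rfx_bms(le[, 1, drop = FALSE]), "2 models")
})
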