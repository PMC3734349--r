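test_that("sign-test z and p reproduce the study's printed statistics", {
  # (k, n) -> z at two decimals, from the pooled and per-run feedback counts
  cases <- list(
    list(k = 97, n = 168, z = 1.93, p = 0.027, pd = 3),
    list(k = 53, n = 84, z = 2.29, p = 0.01, pd = 2),
    list(k = 44, n = 84, z = 0.33, p = NA, pd = 3),
    list(k = 32, n = 56, z = 0.94, p = 0.175, pd = 3),  # z printed as 0.9
    list(k = 29, n = 56, z = 0.13, p = 0.447, pd = 3),
    list(k = 36, n = 56, z = 2.00, p = 0.023, pd = 3)
  )
  for (cs in cases) {
    st <- sign_test(k = cs$k, n = cs$n)
    expect_equal(round(st$z, 2), cs$z)
    if (!is.na(cs$p)) expect_equal(round(st$p, cs$pd), cs$p)
  }
})

test_that("the normal approximation tracks the exact binomial tail", {
  # small-sample case by exhaustive enumeration: P(K >= 8), K ~ Bin(10, 1/2)
  exact <- sum(choose(10, 8:10)) / 2^10
  expect_equal(exact, 56 / 1024)
  st <- sign_test(k = 8, n = 10)
  expect_lt(abs(st$p - exact), 0.02)
  # convergence at n = 500, k/n = 0.55
  exact500 <- pbinom(274, 500, 0.5, lower.tail = FALSE)
  expect_lt(abs(sign_test(k = 275, n = 500)$p - exact500), 0.005)
  # zeros are excluded, vector interface
  st2 <- sign_test(c(1, -1, 0, 2, 0, 3))
  expect_equal(st2$n, 4)
  expect_equal(st2$k, 3)
  expect_error(sign_test(numeric(0)), "at least one")
})

test_that("descriptive summaries use interpolated quartiles", {
  d <- describe(c(1, 2, 3, 4, 5))
  expect_equal(d$m, 3)
  expect_equal(describe(rep(7, 10))$iqr, 0)
  x <- with_fixture_seed(91, rnorm(1e4))
  dd <- describe(x)
  expect_lt(abs(dd$m), 0.05)
  expect_lt(abs(dd$iqr - 1.349), 0.05)
})

test_that("the permutation slope test is calibrated and detects trends", {
  expect_equal(formals(permutation_slope_test)$n_perm, 999)
  # strong increasing trend across runs
  with_fixture_seed(92, {
    vals <- c(rnorm(20, 0, 0.5), rnorm(20, 5, 0.5), rnorm(20, 10, 0.5))
  })
  runs <- rep(1:3, each = 20)
  expect_lte(permutation_slope_test(vals, runs, seed = 1)$p, 0.05)
  # exchangeable null: p roughly uniform (coarse check over 40 repeats)
  ps <- vapply(1:40, function(s) {
    v <- with_fixture_seed(300 + s, rnorm(30))
    permutation_slope_test(v, rep(1:3, each = 10), n_perm = 199,
                           seed = s)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_gte(min(ps), 1 / 200)  # p never below 1/(n_perm + 1)
  expect_error(permutation_slope_test(1:5, rep(1, 5)), "two distinct runs")
})

test_that("percent signal change and CNR follow their definitions", {
  w <- matrix(100, 20, 2)
  w[11:20, 1] <- 101
  psc <- percent_signal_change(w, 11:20, 1:10)
  expect_equal(unname(psc), c(1, 0))
  expect_error(percent_signal_change(w, 1:10, 5:15), "disjoint")
  expect_error(percent_signal_change(matrix(0, 20, 2), 11:20, 1:10), "zero")

  with_fixture_seed(93, {
    base <- rnorm(30)
  })
  s <- sd(resid(lm(base ~ seq_along(base))))
  w2 <- matrix(c(base, base + 2 * s), ncol = 1)
  v <- cnr(w2, 31:60, 1:30)
  expect_equal(unname(v), 2, tolerance = 1e-9)
  expect_equal(unname(cnr(cbind(c(base, base)), 31:60, 1:30)), 0,
               tolerance = 1e-9)
  # CNR grows monotonically with injected effect size
  effects <- c(0.5, 1, 2, 4)
  cnrs <- vapply(effects, function(a) {
    unname(cnr(cbind(c(base, base + a)), 31:60, 1:30))
  }, numeric(1))
  expect_true(all(diff(cnrs) > 0))
})

test_that("differential feedback is sign-aligned and antisymmetric", {
  expect_equal(differential_feedback(1, 1, "aL")$aligned, 0)
  # aL with contralateral (right) increase counts as success
  expect_gt(differential_feedback(0.1, 0.5, "aL")$aligned, 0)
  expect_gt(differential_feedback(0.5, 0.1, "aR")$aligned, 0)
  a <- differential_feedback(0.3, -0.2, "aL")
  b <- differential_feedback(-0.2, 0.3, "aL")
  expect_equal(a$raw, -b$raw)
  expect_equal(a$aligned, -b$aligned)
  expect_error(differential_feedback(Inf, 0, "aL"), "finite")
})

test_that("Jarque-Bera flags heavy tails but accepts Gaussian samples", {
  # symmetric, near-Gaussian-kurtosis sample: statistic close to zero
  expect_lt(jarque_bera(qnorm(ppoints(1000)))$statistic, 1)
  ok <- vapply(1:40, function(s) {
    jarque_bera(with_fixture_seed(400 + s, rnorm(1e4)))$p > 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.9)
  heavy <- with_fixture_seed(94, rt(1e4, df = 2))
  expect_lt(jarque_bera(heavy)$p, 0.001)
  expect_error(jarque_bera(rnorm(5)), "at least 8")
  expect_error(jarque_bera(rep(1, 10)), "degenerate")
})
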