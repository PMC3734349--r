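test_that("streaming and offline cleaning are bit-identical", {
  with_fixture_seed(21, {
    x <- matrix(rnorm(300 * 2), 300, 2) + 0.05 * (1:300)
  })
  off <- clean_series(x)$series
  # feed scan by scan in two chunks through explicit state threading
  st <- cleaner_init(2)
  out <- matrix(0, 300, 2)
  for (i in 1:150) {
    step <- clean_sample(x[i, ], st); out[i, ] <- step$values; st <- step$state
  }
  mid <- clean_series(x[151:300, ], state = st)
  out[151:300, ] <- mid$series
  expect_identical(out, off)
})

test_that("constant input is removed after warm-up", {
  x <- matrix(7, 100, 1)
  out <- clean_series(x)$series
  expect_lt(max(abs(out[10:100])), 1e-6)
})

test_that("pure linear drift is removed (slope oracle)", {
  x <- matrix(0.1 * (1:200), 200, 1)
  out <- clean_series(x)$series
  slope <- coef(lm.fit(cbind(1, 1:200), out))[2]
  expect_lt(abs(slope), 0.005)
})

test_that("injected spikes are clipped without disturbing neighbors", {
  with_fixture_seed(22, {
    x <- rnorm(200)
  })
  xs <- x; xs[100] <- xs[100] + 10  # 10-SD spike
  a <- clean_series(matrix(x, ncol = 1))$series
  b <- clean_series(matrix(xs, ncol = 1))$series
  expect_lte(abs(b[100]), 3)
  neighbors <- setdiff(80:120, 100)
  expect_lt(max(abs((b - a)[neighbors])), 0.05 * 10)
})

test_that("non-finite samples are rejected with scan and region", {
  st <- cleaner_init(2)
  st <- clean_sample(c(1, 2), st)$state
  expect_error(clean_sample(c(1, NA), st), "scan 2.*region 2")
})
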