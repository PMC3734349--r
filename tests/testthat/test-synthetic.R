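test_that("standard layouts have the published block arithmetic", {
  loc <- make_design("localizer")
  expect_equal(loc$n_scans, 210)  # 21 blocks x 10 s at TR = 1 s
  expect_equal(nrow(loc$blocks), 21)
  expect_true(all(loc$blocks$duration == 10))

  nf <- make_design("neurofeedback", n_trials = 8)
  expect_equal(nrow(nf$trials), 8)
  expect_identical(nf$trials$condition, rep(c("aL", "aR"), 4))
  # trial 2 starts one trial-plus-intertrial period (90 + 60 + 5 s) after 1
  expect_equal(nf$trials$onset_scan[2] - nf$trials$onset_scan[1], 155)
  # the regulation window of a trial is 90 scans: 5 baseline + 4 regulation
  tw <- extract_trial_window(
    roi_timeseries(matrix(0, nf$n_scans, 4), 1, fixture_regions), 1, nf)
  expect_equal(nrow(tw$values), 90)
  expect_equal(sum(tw$blocks$label == "baseline"), 5)
  expect_equal(sum(tw$blocks$label == "aL"), 4)
})

test_that("noiseless generation reduces to the forward model", {
  d <- make_design("neurofeedback", n_trials = 1)
  sim <- simulate_session(d, noise = noise_spec(white_sd = 0, ar = 0,
                                                drift = 0, spike_p = 0),
                          seed = 1)
  expect_equal(sim$series$values, 100 * (1 + sim$clean_percent$values / 100),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("generation is seed-deterministic and leaves global RNG alone", {
  d <- make_design("neurofeedback", n_trials = 1)
  set.seed(123); before <- rnorm(1)
  set.seed(123)
  a <- simulate_session(d, seed = 5)$series$values
  after <- rnorm(1)
  b <- simulate_session(d, seed = 5)$series$values
  expect_identical(a, b)
  expect_identical(before, after)  # private RNG stream
  expect_false(identical(a, simulate_session(d, seed = 6)$series$values))
})

test_that("spike counts fall in the binomial band of the spike probability", {
  d <- experiment_design(1, matrix(0, 2500, 2))
  ns <- noise_spec(white_sd = 0.5, ar = 0, drift = 0, spike_p = 0.005,
                   spike_amp = 8)
  truth <- default_truth(b = 0, c = 0)
  sim <- simulate_session(d, truth = truth, noise = ns, seed = 31)
  # spikes of 8 sd on white noise: count samples beyond 4 sd
  n_big <- sum(abs(sim$series$values - 100) > 4 * 0.5)
  n <- length(sim$series$values)
  band <- qbinom(c(0.005, 0.995), n, 0.005)
  expect_gte(n_big, band[1])
  expect_lte(n_big, band[2])
})

test_that("volume embedding recovers the series by mask-mean extraction", {
  with_fixture_seed(41, {
    series <- roi_timeseries(matrix(rnorm(20 * 4), 20, 4), 1,
                             fixture_regions)
  })
  vols <- simulate_volumes(series, voxel_sd = 0)
  expect_equal(unname(vols$roi_sizes),
               c(16, 16, 24, 24))  # VC ~16, SPL ~24 voxels
  for (r in 1:4) {
    m <- vols$masks[[r]] == 1
    extracted <- vapply(1:20, function(t) mean(vols$volume[, , , t][m]),
                        numeric(1))
    expect_equal(extracted, unname(series$values[, r]), tolerance = 1e-12)
  }

  # with voxel noise sigma over k voxels the residual sd shrinks ~ sigma/sqrt(k)
  sds <- vapply(1:20, function(s) {
    v <- simulate_volumes(series, voxel_sd = 1, seed = s)
    m <- v$masks[[3]] == 1  # SPL_L, 24 voxels
    extracted <- vapply(1:20, function(t) mean(v$volume[, , , t][m]),
                        numeric(1))
    sd(extracted - series$values[, 3])
  }, numeric(1))
  expect_gt(mean(sds), (1 / sqrt(24)) * 0.8)
  expect_lt(mean(sds), (1 / sqrt(24)) * 1.2)
})
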