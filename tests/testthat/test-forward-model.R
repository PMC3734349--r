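test_that("neuronal drift implements the bilinear state equation", {
  # rest is a fixed point
  skel <- validate_model(fixture_pair$aL)
  params <- skeleton_to_params(skel, fixture_theta(skel))
  expect_equal(unname(neuronal_drift(rep(0, 4), 0, params)), rep(0, 4))

  # pure driving input
  p2 <- connectivity_params(diag(-0.5, 2), C = matrix(c(1, 0), 2, 1))
  expect_equal(unname(neuronal_drift(c(0, 0), 1, p2)), c(1, 0))

  # random 4-region system vs direct matrix arithmetic
  with_fixture_seed(11, {
    A <- matrix(rnorm(16, 0, 0.2), 4, 4); diag(A) <- -0.6
    B <- array(rnorm(16, 0, 0.1), dim = c(4, 4, 1))
    C <- matrix(rnorm(4, 0, 0.3), 4, 1)
    pr <- connectivity_params(A, B, C)
    z <- c(0.1, 0.2, 0.3, 0.4)
    expect_equal(unname(neuronal_drift(z, 1, pr)),
                 drop((A + B[, , 1]) %*% z + C), tolerance = 1e-12)
  })

  expect_error(neuronal_drift(rep(0, 3), 0, params), "regions")
  expect_error(neuronal_drift(rep(0, 4), c(0, 0), params), "inputs")
})

test_that("hemodynamic drift has the rest fixed point and plausible inflow", {
  h <- hemodynamic_params()
  rest <- c(z = 0, s = 0, f = 1, v = 1, q = 1)
  expect_equal(unname(hemodynamic_drift(rest, h)), rep(0, 4))

  driven <- c(z = 1, s = 0, f = 1, v = 1, q = 1)
  d <- hemodynamic_drift(driven, h)
  expect_equal(unname(d), c(1, 0, 0, 0))

  expect_error(hemodynamic_drift(c(z = 0, s = 0, f = -1, v = 1, q = 1), h),
               "positive")

  # brute-force fine-step Euler integration of a 1 s neuronal pulse:
  # inflow should peak between 2 and 8 s
  dt <- 0.001
  st <- as.list(rest)
  fmax_t <- 0; fmax <- 1
  for (i in seq_len(15000)) {
    t <- i * dt
    st$z <- if (t <= 1) 1 else 0
    dd <- hemodynamic_drift(st, h)
    st$s <- st$s + dt * dd[["ds"]]
    st$f <- st$f + dt * dd[["df"]]
    st$v <- st$v + dt * dd[["dv"]]
    st$q <- st$q + dt * dd[["dq"]]
    if (st$f > fmax) { fmax <- st$f; fmax_t <- t }
  }
  expect_gt(fmax_t, 2)
  expect_lt(fmax_t, 8)
})

test_that("BOLD observation matches hand arithmetic and is monotone in q", {
  h <- hemodynamic_params(k1 = 2.8, k2 = 2, k3 = 0.6)
  expect_equal(bold_observation(1, 1, h), 0)
  expect_equal(bold_observation(1, 0.9, h), 0.04 * (2.8 * 0.1 + 2 * 0.1),
               tolerance = 1e-12)
  q <- seq(0.8, 1.2, by = 0.05)
  y <- vapply(q, function(qq) bold_observation(1, qq, h), numeric(1))
  expect_true(all(diff(y) < 0))
})

test_that("simulation is quiet at rest, stable, and converges with step", {
  skel <- validate_model(fixture_pair$aL)
  params <- skeleton_to_params(skel, fixture_theta(skel))
  expect_lt(max_eigen_real(params), 0)

  d <- make_design("neurofeedback", n_trials = 1)
  dwin <- inversion_design(d, 1:90)

  # nothing drives the system without input weights
  p0 <- skeleton_to_params(skel, fixture_theta(skel, cc = 0))
  expect_equal(max(abs(simulate_timeseries(p0, dwin)$values)), 0)

  y1 <- simulate_timeseries(params, dwin, dt = 0.125)$values
  y2 <- simulate_timeseries(params, dwin, dt = 0.0625)$values
  expect_lt(max(abs(y1 - y2)), 1e-4)

  # step-halving error ratio consistent with a 4th-order integrator
  y4 <- simulate_timeseries(params, dwin, dt = 0.03125)$values
  e12 <- max(abs(y1 - y2)); e24 <- max(abs(y2 - y4))
  expect_gt(e12 / e24, 8)
})

test_that("small-amplitude response is linear in the input weight", {
  skel <- validate_model(fixture_pair$aL)
  d <- inversion_design(make_design("neurofeedback", n_trials = 1), 1:90)
  y1 <- simulate_timeseries(
    skeleton_to_params(skel, fixture_theta(skel, b_td = 0, cc = 0.005)), d)$values
  y2 <- simulate_timeseries(
    skeleton_to_params(skel, fixture_theta(skel, b_td = 0, cc = 0.01)), d)$values
  expect_lt(max(abs(y2 / 2 - y1)), 0.05 * max(abs(y1)))
})

test_that("shifting the design by one TR shifts the output by one sample", {
  skel <- validate_model(fixture_pair$aL)
  params <- skeleton_to_params(skel, fixture_theta(skel))
  d <- make_design("neurofeedback", n_trials = 1)
  u <- inversion_design(d, 1:90)$inputs
  u_shift <- rbind(0, u[-nrow(u), , drop = FALSE])
  d1 <- experiment_design(1, u)
  d2 <- experiment_design(1, u_shift)
  y1 <- simulate_timeseries(params, d1)$values
  y2 <- simulate_timeseries(params, d2)$values
  expect_equal(y2[-1, ], y1[-nrow(y1), ], tolerance = 1e-12)
})

test_that("divergent dynamics raise an error naming the divergence time", {
  # strongly positive coupling makes the pair unstable
  A <- matrix(c(-0.5, 1.2, 1.2, -0.5), 2, 2)
  params <- connectivity_params(A, C = matrix(c(1, 0), 2, 1))
  d <- experiment_design(1, matrix(1, 60, 1))
  expect_error(simulate_timeseries(params, d), "unstable")
})
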