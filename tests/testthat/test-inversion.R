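test_that("default priors shrink free couplings and exclude structural zeros", {
  skel <- validate_model(fixture_pair$aL)
  pr <- default_priors(skel)
  expect_true(all(pr$theta_mean == 0))
  expect_equal(prior_variance(pr, "A", "SPL_R", "VC_R"), 0.25)
  # structurally absent interhemispheric connection: zero variance, never free
  expect_equal(prior_variance(pr, "A", "VC_L", "VC_R"), 0)
  expect_equal(prior_variance(pr, "B", "SPL_L", "VC_L"), 0)

  # two models differing only in modulation placement share A/C priors
  fam <- model_family()
  p1 <- default_priors(validate_model(fam[[1]]))
  p2 <- default_priors(validate_model(fam[[2]]))
  a1 <- grep("^(self|A|C)", p1$theta_names)
  a2 <- grep("^(self|A|C)", p2$theta_names)
  expect_identical(p1$theta_names[a1], p2$theta_names[a2])
  expect_identical(diag(p1$theta_cov)[a1], diag(p2$theta_cov)[a2])
})

test_that("a zero iteration budget returns the prior, unconverged", {
  tr <- fixture_trial(101)
  fit <- invert(tr$y, fixture_pair$aL, tr$design, max_iter = 0)
  pr <- default_priors(validate_model(fixture_pair$aL))
  expect_equal(fit$posterior_mean, pr$theta_mean)
  expect_equal(fit$posterior_cov, pr$theta_cov)
  expect_false(fit$converged)
  expect_identical(fit$n_iterations, 0L)
  expect_true(is.finite(fit$F))
})

test_that("free energy equals the analytic log evidence on a linear-Gaussian surrogate", {
  s <- fixture_linear_surrogate()
  predict_fn <- function(th) s$X %*% th
  # at the exact conjugate posterior
  Fq <- free_energy(s$y, predict_fn, s$priors, s$post_mean, s$post_cov,
                    lambda = s$priors$lambda_mean, lambda_var = 0)
  expect_lt(abs(Fq - s$log_evidence), 1e-6)
  # and the engine attains it
  fit <- vl_fit(s$y, predict_fn, s$priors, max_iter = 60, tol = 1e-7)
  expect_lt(abs(fit$F - s$log_evidence), 1e-6)
  expect_lt(max(abs(fit$posterior_mean - s$post_mean)), 1e-5)
})

test_that("free energy with posterior = prior is the pure accuracy term", {
  s <- fixture_linear_surrogate(seed = 7, Tn = 30)
  predict_fn <- function(th) s$X %*% th
  p <- s$priors
  F1 <- free_energy(s$y, predict_fn, p, p$theta_mean, p$theta_cov,
                    lambda = p$lambda_mean, lambda_var = 0)
  # KL = 0, so F is the expected log likelihood; duplicating the data
  # (and the design) doubles it exactly
  s2X <- rbind(s$X, s$X)
  F2 <- free_energy(rbind(s$y, s$y), function(th) s2X %*% th, p,
                    p$theta_mean, p$theta_cov,
                    lambda = p$lambda_mean, lambda_var = 0)
  expect_equal(F2, 2 * F1, tolerance = 1e-10)
})

test_that("the free-energy trajectory is monotone and deterministic", {
  tr <- fixture_trial(102)
  fit1 <- invert(tr$y, fixture_pair$aL, tr$design)
  fit2 <- invert(tr$y, fixture_pair$aL, tr$design)
  expect_identical(fit1$F, fit2$F)  # bit-identical, no internal randomness
  expect_true(all(diff(fit1$F_trajectory) > -1e-8))
  expect_lte(fit1$n_iterations, 44)
})

test_that("simulated parameters are recovered within credible intervals", {
  # moderate-size recovery check; the full 50-replicate calibration runs in
  # the acceptance suite
  hits <- 0L; total <- 0L
  for (s in 1:6) {
    tr <- fixture_trial(200 + s, condition = if (s %% 2) "aL" else "aR")
    fit <- invert(tr$y, fixture_pair[[tr$condition]], tr$design,
                  max_iter = 200)
    free <- grep("^(A|B|C)", fit$theta_names)
    mu <- fit$posterior_mean[free]
    sd <- sqrt(diag(fit$posterior_cov)[free])
    tv <- tr$theta[free]
    cover <- abs(mu - tv) <= qnorm(0.975) * sd
    hits <- hits + sum(cover); total <- total + length(cover)
  }
  expect_gte(hits / total, 0.80)
})

test_that("posterior summaries use the conditional-probability convention", {
  fit <- structure(
    list(posterior_mean = c(a = 0, b = 1.96, c = 0.5),
         posterior_cov = diag(c(1, 1, 0)),
         theta_names = c("a", "b", "c")),
    class = "dcm_fit")
  s <- summarize_posterior(fit, threshold = 0)
  expect_equal(s$prob[1], 0.5)
  expect_equal(s$prob[2], pnorm(1.96), tolerance = 1e-6)
  expect_equal(s$prob[3], 1)  # degenerate posterior
  s2 <- summarize_posterior(fit, threshold = 0.6)
  expect_equal(s2$prob[3], 0)
})

test_that("a short window triggers the identifiability warning", {
  tr <- fixture_trial(103)
  expect_warning(
    invert(tr$y[1:20, ], fixture_pair$aL,
           experiment_design(1, tr$design$inputs[1:20, , drop = FALSE]),
           max_iter = 1),
    "below twice")
})
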