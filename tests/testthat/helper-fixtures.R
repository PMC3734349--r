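# shared fixtures, all built in code

fixture_pair <- attention_pair()

# ground-truth free-parameter vector for a model skeleton: reciprocal
# intrinsic coupling 0.3 Hz, top-down modulation 0.4 Hz, input 0.3 Hz
fixture_theta <- function(skel, a = 0.3, b_td = 0.4, b_bu = 0, cc = 0.3) {
  th <- stats::setNames(numeric(length(skel$theta_names)), skel$theta_names)
  th[grep("^A:", names(th))] <- a
  th[grep("^B.*SPL_.->VC_.$", names(th))] <- b_td
  th[grep("^B.*VC_.->SPL_.$", names(th))] <- b_bu
  th[grep("^C", names(th))] <- cc
  th
}

# one 90-scan trial: model-generated signal plus iid noise (the inversion
# module's own noise assumption), used for recovery/calibration checks
fixture_trial <- function(seed, condition = "aL", noise_sd = 0.5) {
  d <- make_design("neurofeedback", n_trials = 1,
                   start_condition = condition)
  dwin <- inversion_design(d, 1:90)
  spec <- fixture_pair[[condition]]
  skel <- validate_model(spec)
  th <- fixture_theta(skel)
  clean <- simulate_timeseries(skeleton_to_params(skel, th), dwin)
  y <- with_fixture_seed(seed, {
    clean$values + matrix(rnorm(length(clean$values), 0, noise_sd),
                          nrow(clean$values))
  })
  list(y = y, design = dwin, condition = condition, theta = th, skel = skel)
}

with_fixture_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# linear-Gaussian surrogate with known analytic evidence
fixture_linear_surrogate <- function(seed = 42, Tn = 40, p = 3,
                                     sigma2 = 0.7) {
  with_fixture_seed(seed, {
    X <- matrix(rnorm(Tn * p), Tn, p)
    S0 <- diag(c(1, 0.5, 2)[seq_len(p)], p)
    theta_true <- c(0.5, -1, 0.2)[seq_len(p)]
    y <- matrix(X %*% theta_true + rnorm(Tn, 0, sqrt(sigma2)), Tn, 1)
    priors <- list(theta_mean = rep(0, p), theta_cov = S0,
                   lambda_mean = log(1 / sigma2), lambda_var = 0,
                   confounds = "none")
    Vy <- X %*% S0 %*% t(X) + sigma2 * diag(Tn)
    log_evidence <- as.numeric(
      -0.5 * (Tn * log(2 * pi) + determinant(Vy)$modulus +
                t(y) %*% solve(Vy, y)))
    P <- crossprod(X) / sigma2 + solve(S0)
    Sg <- solve(P)
    mu <- as.numeric(Sg %*% (crossprod(X, y) / sigma2))
    list(X = X, y = y, priors = priors, log_evidence = log_evidence,
         post_mean = mu, post_cov = Sg, sigma2 = sigma2)
  })
}

fixture_regions <- c("VC_L", "VC_R", "SPL_L", "SPL_R")
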