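#' Default priors for a candidate model
#'
#' Zero-mean shrinkage priors on all free couplings: off-diagonal A, B and C
#' entries get variance 1/4 (sd 0.5 Hz); the self-decay log-scales get a
#' tight variance of 1/64 around the nominal -0.5 Hz decay. Structurally
#' absent connections are not free parameters at all, i.e. they carry zero
#' prior variance and are never updated ([prior_variance()] reports 0 for
#' them). The per-region log noise precision gets a weak Gaussian prior, and
#' a per-window confound basis (constant + linear drift) is attached; the
#' confounds are projected out of both data and model prediction.
#'
#' @param skel a `dcm_skeleton` from [validate_model()] (a [model_spec()] is
#'   accepted and validated on the fly).
#' @param a_var,b_var,c_var prior variances of the free off-diagonal A, B
#'   and C entries (Hz^2).
#' @param self_var prior variance of the self-decay log-scale.
#' @param lambda_mean,lambda_var prior mean and variance of the per-region
#'   log noise precision. `lambda_var = 0` fixes the noise level.
#' @param confounds `"linear"` (constant + linear drift per window, the
#'   default), `"constant"`, or `"none"`.
#'
#' @return An object of class `dcm_priors`.
#' @export
default_priors <- function(skel, a_var = 1 / 4, b_var = 1 / 4, c_var = 1 / 4,
                           self_var = 1 / 64, lambda_mean = 0,
                           lambda_var = 16,
                           confounds = c("linear", "constant", "none")) {
  if (inherits(skel, "model_spec")) skel <- validate_model(skel)
  stopifnot(inherits(skel, "dcm_skeleton"))
  nm <- skel$theta_names
  v <- numeric(length(nm))
  v[grep("^self:", nm)] <- self_var
  v[grep("^A:", nm)] <- a_var
  v[grep("^B\\.", nm)] <- b_var
  v[grep("^C\\.", nm)] <- c_var
  structure(
    list(theta_mean = stats::setNames(numeric(length(nm)), nm),
         theta_cov = diag(v, length(v)), theta_names = nm,
         lambda_mean = lambda_mean, lambda_var = lambda_var,
         confounds = match.arg(confounds), skeleton = skel),
    class = "dcm_priors"
  )
}

#' Prior variance of one connectivity entry
#'
#' Reports the prior variance of `from -> to` in matrix `field`; entries
#' absent from the model structure have variance 0.
#'
#' @param priors a [default_priors()] object.
#' @param field `"A"`, `"B"` or `"C"` (for `"C"`, `from` is the input name).
#' @param from,to region (or input) labels.
#' @return Prior variance (0 for structurally absent connections).
#' @export
prior_variance <- function(priors, field, from, to) {
  stopifnot(inherits(priors, "dcm_priors"))
  nm <- switch(field,
               A = paste0("A:", from, "->", to),
               B = paste0("B.attention:", from, "->", to),
               C = paste0("C.attention:", to),
               stop("field must be A, B or C"))
  i <- match(nm, priors$theta_names)
  if (is.na(i)) 0 else diag(priors$theta_cov)[i]
}

# confound basis for a window of length T, as an orthonormal matrix
confound_basis <- function(T, kind) {
  X <- switch(kind,
              none = NULL,
              constant = matrix(1, T, 1),
              linear = cbind(1, seq_len(T) - (T + 1) / 2))
  if (is.null(X)) return(NULL)
  qr.Q(qr(X))
}

# project confounds out of each column of Y
project_confounds <- function(Y, Q) {
  if (is.null(Q)) return(Y)
  Y - Q %*% (t(Q) %*% Y)
}

# log-evidence bound for one Gauss-Newton state.
# e: T x n projected residual matrix; J: (T*n) x p Jacobian (projected),
# rows region-major blocks; Sigma: p x p posterior covariance;
# lambda: n-vector of log precisions; lambda_var: posterior variances of
# lambda (0 when fixed); T_eff: effective time points per region.
vl_F <- function(e, J, Sigma, mu, priors_mean, prior_prec, prior_logdet,
                 lambda, lambda_var, lambda0, lambda_v0, T_eff) {
  n <- ncol(e)
  Tn <- nrow(e)
  p <- length(mu)
  acc <- 0
  for (r in seq_len(n)) {
    rows <- ((r - 1) * Tn + 1):(r * Tn)
    S <- sum(e[, r]^2)
    if (p > 0) S <- S + sum((J[rows, , drop = FALSE] %*% Sigma) *
                              J[rows, , drop = FALSE])
    acc <- acc + 0.5 * T_eff * (lambda[r] - log(2 * pi)) -
      0.5 * exp(lambda[r]) * S
  }
  kl_theta <- 0
  if (p > 0) {
    d <- mu - priors_mean
    ld_post <- determinant(Sigma, logarithm = TRUE)$modulus
    kl_theta <- 0.5 * (sum(diag(prior_prec %*% Sigma)) +
                         drop(t(d) %*% prior_prec %*% d) - p +
                         prior_logdet - ld_post)
  }
  kl_lambda <- 0
  if (lambda_v0 > 0) {
    kl_lambda <- sum(0.5 * (lambda_var / lambda_v0 +
                              (lambda - lambda0)^2 / lambda_v0 - 1 +
                              log(lambda_v0 / pmax(lambda_var, 1e-300))))
  }
  as.numeric(acc - kl_theta - kl_lambda)
}

# Newton update of per-region log precisions given residuals and curvature;
# a zero prior variance pins the noise level at its prior mean
update_lambda <- function(lambda, e, J, Sigma, T_eff, lambda0, v0) {
  n <- ncol(e)
  if (v0 <= 0) {
    return(list(lambda = rep(lambda0, n), lambda_var = rep(0, n)))
  }
  Tn <- nrow(e)
  p <- ncol(Sigma)
  Svec <- numeric(n)
  for (r in seq_len(n)) {
    rows <- ((r - 1) * Tn + 1):(r * Tn)
    S <- sum(e[, r]^2)
    if (p > 0) S <- S + sum((J[rows, , drop = FALSE] %*% Sigma) *
                              J[rows, , drop = FALSE])
    Svec[r] <- S
  }
  lvar <- numeric(n)
  for (r in seq_len(n)) {
    l <- lambda[r]
    for (k in 1:8) {
      g <- 0.5 * T_eff - 0.5 * exp(l) * Svec[r]
      h <- -0.5 * exp(l) * Svec[r]
      if (v0 > 0) {
        g <- g - (l - lambda0) / v0
        h <- h - 1 / v0
      }
      step <- max(min(-g / h, 4), -4)
      l <- l + step
      if (abs(step) < 1e-8) break
    }
    lambda[r] <- l
    lvar[r] <- if (v0 > 0) -1 / (-0.5 * exp(l) * Svec[r] - 1 / v0) else 0
  }
  list(lambda = lambda, lambda_var = lvar)
}

# central finite-difference Jacobian of a T x n prediction wrt theta,
# returned as (T*n) x p with region-major row blocks, confound-projected
fd_jacobian <- function(predict_fn, theta, base_dim, Q, h_rel = 1e-4) {
  p <- length(theta)
  J <- matrix(0, prod(base_dim), p)
  for (i in seq_len(p)) {
    h <- h_rel * max(1, abs(theta[i]))
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    gp <- predict_fn(tp)
    gm <- predict_fn(tm)
    if (is.null(gp) || is.null(gm)) {
      stop("prediction failed while differentiating parameter ", i)
    }
    J[, i] <- as.numeric(project_confounds((gp - gm) / (2 * h), Q))
  }
  J
}

#' Variational Laplace fit of a nonlinear Gaussian observation model
#'
#' Generic engine behind [invert()]: Gauss-Newton ascent on the free-energy
#' bound F with Levenberg-style damping (trust factor doubled on a rejected
#' step, halved on acceptance), central finite-difference Jacobians, and an
#' EM update of per-region log noise precisions. Deterministic: identical
#' inputs reproduce F bit-identically.
#'
#' @param y scans-by-regions data matrix.
#' @param predict_fn function mapping a free-parameter vector to a
#'   scans-by-regions prediction matrix, or `NULL` when the parameters are
#'   dynamically inadmissible (treated as a rejected step).
#' @param priors a list with `theta_mean`, `theta_cov`, `lambda_mean`,
#'   `lambda_var`, `confounds` (see [default_priors()]).
#' @param max_iter iteration cap (default 44, the real-time budget). With
#'   `max_iter = 0` the posterior equals the prior.
#' @param tol convergence tolerance: stop once |dF| < tol on two
#'   consecutive iterations (default 0.05 nats).
#' @param h_rel relative finite-difference step (default 1e-4).
#' @param damp0 initial damping factor.
#'
#' @return An object of class `dcm_fit`: `posterior_mean`, `posterior_cov`,
#'   `lambda` (posterior mean log precision per region), `lambda_var`, `F`,
#'   `F_trajectory` (starting value followed by one value per iteration),
#'   `n_iterations`, `converged`.
#' @export
vl_fit <- function(y, predict_fn, priors, max_iter = 44, tol = 0.05,
                   h_rel = 1e-4, damp0 = 1) {
  y <- as.matrix(y)
  Tn <- nrow(y)
  n <- ncol(y)
  m0 <- priors$theta_mean
  p <- length(m0)
  S0 <- priors$theta_cov
  lambda0 <- priors$lambda_mean
  v0 <- priors$lambda_var
  Q <- confound_basis(Tn, priors$confounds %||% "linear")
  T_eff <- Tn - if (is.null(Q)) 0 else ncol(Q)
  if (p > 0 && Tn < 2 * p) {
    warning("window length ", Tn, " is below twice the number of free ",
            "parameters (", p, ")")
  }

  P0 <- if (p > 0) solve(S0) else matrix(0, 0, 0)
  prior_logdet <- if (p > 0) determinant(S0, logarithm = TRUE)$modulus else 0
  Ry <- project_confounds(y, Q)

  theta <- m0
  g <- predict_fn(theta)
  if (is.null(g)) stop("prediction failed at the prior mean")
  e <- Ry - project_confounds(g, Q)
  if (any(!is.finite(e))) stop("non-finite residuals at the prior mean")

  lambda <- rep(lambda0, n)
  lambda_var <- rep(0, n)

  fit_F <- function(e, J, Sigma, theta, lambda, lambda_var) {
    vl_F(e, J, Sigma, theta, m0, P0, prior_logdet, lambda, lambda_var,
         lambda0, v0, T_eff)
  }

  if (max_iter == 0 || p == 0) {
    # budget exhausted before any update: posterior (theta and noise) = prior
    J <- if (p > 0) fd_jacobian(predict_fn, theta, dim(e), Q, h_rel) else
      matrix(0, Tn * n, 0)
    F0 <- fit_F(e, J, S0, theta, lambda, rep(v0, n))
    return(structure(
      list(posterior_mean = theta, posterior_cov = S0, lambda = lambda,
           lambda_var = rep(v0, n), F = F0, F_trajectory = F0,
           n_iterations = 0L, converged = FALSE,
           theta_names = names(m0)),
      class = "dcm_fit"))
  }

  damp <- damp0
  J <- fd_jacobian(predict_fn, theta, dim(e), Q, h_rel)
  Pi_diag <- rep(exp(lambda), each = Tn)
  H <- crossprod(J, J * Pi_diag) + P0
  Sigma <- solve(H)
  up <- update_lambda(lambda, e, J, Sigma, T_eff, lambda0, v0)
  lambda <- up$lambda
  lambda_var <- up$lambda_var
  F_cur <- fit_F(e, J, Sigma, theta, lambda, lambda_var)
  traj <- F_cur
  small_steps <- 0L
  converged <- FALSE
  it <- 0L

  while (it < max_iter) {
    it <- it + 1L
    J <- tryCatch(fd_jacobian(predict_fn, theta, dim(e), Q, h_rel),
                  error = function(err) NULL)
    if (is.null(J)) break
    Pi_diag <- rep(exp(lambda), each = Tn)
    H <- crossprod(J, J * Pi_diag) + P0
    Sigma_H <- tryCatch(solve(H), error = function(err) NULL)
    if (is.null(Sigma_H)) break
    grad <- crossprod(J, as.numeric(e) * Pi_diag) - P0 %*% (theta - m0)
    accepted <- FALSE
    for (attempt in 1:16) {
      Hd <- H + damp * diag(diag(H), p)
      dtheta <- tryCatch(solve(Hd, grad), error = function(e) NULL)
      if (!is.null(dtheta)) {
        theta_new <- theta + as.numeric(dtheta)
        names(theta_new) <- names(m0)
        g_new <- tryCatch(predict_fn(theta_new), error = function(e) NULL)
        if (!is.null(g_new) && all(is.finite(g_new))) {
          e_new <- Ry - project_confounds(g_new, Q)
          Sigma_new <- Sigma_H
          up <- update_lambda(lambda, e_new, J, Sigma_new, T_eff, lambda0, v0)
          F_new <- fit_F(e_new, J, Sigma_new, theta_new, up$lambda,
                         up$lambda_var)
          if (is.finite(F_new) && F_new > F_cur) {
            theta <- theta_new
            e <- e_new
            Sigma <- Sigma_new
            lambda <- up$lambda
            lambda_var <- up$lambda_var
            dF <- F_new - F_cur
            F_cur <- F_new
            damp <- max(damp / 2, 1e-8)
            accepted <- TRUE
            break
          }
        }
      }
      damp <- damp * 2
      if (damp > 1e10) break
    }
    traj <- c(traj, F_cur)
    dF <- if (accepted) dF else 0
    if (abs(dF) < tol) small_steps <- small_steps + 1L else small_steps <- 0L
    if (small_steps >= 2L) {
      converged <- TRUE
      break
    }
    if (!accepted && damp > 1e10) break
  }

  structure(
    list(posterior_mean = theta, posterior_cov = Sigma, lambda = lambda,
         lambda_var = lambda_var, F = F_cur, F_trajectory = traj,
         n_iterations = it, converged = converged,
         theta_names = names(m0)),
    class = "dcm_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dcm_fit <- function(x, ...) {
  cat("DCM fit: F =", format(x$F, digits = 6), "nats,",
      x$n_iterations, "iterations,",
      if (x$converged) "converged" else "not converged", "\n")
  invisible(x)
}

# prediction closure for one candidate model on one design window
dcm_predictor <- function(skel, design, hemo = hemodynamic_params(),
                          dt = design$TR / 8, z_bound = 10) {
  force(skel); force(design); force(hemo); force(dt); force(z_bound)
  function(theta) {
    params <- skeleton_to_params(skel, theta)
    out <- tryCatch(
      simulate_timeseries(params, design, hemo, dt = dt, z_bound = z_bound),
      error = function(e) NULL)
    if (is.null(out)) NULL else out$values
  }
}

#' Invert one candidate model against one data window
#'
#' Fits the bilinear DCM implied by `model` to an ROI time-series window by
#' variational Laplace under an iteration budget. Free parameters are the
#' couplings the model structure declares (self-decay log-scales,
#' off-diagonal A, B and C entries); hemodynamic constants are fixed at
#' their nominal values. Per-window constant and linear-drift confounds are
#' projected out of data and prediction alike.
#'
#' @param y a [roi_timeseries()] or scans-by-regions matrix (the window).
#' @param model a [model_spec()] or `dcm_skeleton`.
#' @param design a [experiment_design()] covering the window, with a single
#'   input channel matching the model (see [inversion_design()]).
#' @param priors a [default_priors()] object (defaults built from `model`).
#' @param max_iter iteration cap; default 44, the real-time budget.
#' @param tol free-energy convergence tolerance (nats), default 0.05.
#' @param hemo hemodynamic constants, fixed during inversion.
#' @param dt integration step (s).
#' @param ... passed to [vl_fit()].
#'
#' @return A `dcm_fit` (see [vl_fit()]), with the model name attached.
#' @export
invert <- function(y, model, design, priors = NULL, max_iter = 44,
                   tol = 0.05, hemo = hemodynamic_params(),
                   dt = design$TR / 8, ...) {
  if (inherits(y, "roi_timeseries")) y <- y$values
  skel <- if (inherits(model, "model_spec")) validate_model(model) else model
  stopifnot(inherits(skel, "dcm_skeleton"))
  if (is.null(priors)) priors <- default_priors(skel)
  pred <- dcm_predictor(skel, design, hemo, dt)
  fit <- vl_fit(y, pred, priors, max_iter = max_iter, tol = tol, ...)
  fit$model <- skel$spec$name
  fit
}

#' Free energy of a given posterior under a model
#'
#' Evaluates the variational (Laplace) bound on the log model evidence for
#' an arbitrary posterior: expected log-likelihood of the confound-projected
#' residuals minus the KL divergence from posterior to prior. With a linear
#' predictor, fixed noise (`lambda_var = 0`) and the exact conjugate
#' posterior this equals the analytic log evidence.
#'
#' @param y scans-by-regions data matrix (or [roi_timeseries()]).
#' @param predict_fn prediction function over the free parameters.
#' @param priors a priors list (see [vl_fit()]).
#' @param q_mean,q_cov posterior mean and covariance of the free parameters.
#' @param lambda per-region log noise precision (posterior mean).
#' @param lambda_var posterior variance of `lambda` (0 = fixed noise).
#' @param h_rel relative finite-difference step for the Jacobian.
#'
#' @return Free energy in nats.
#' @export
free_energy <- function(y, predict_fn, priors, q_mean, q_cov,
                        lambda = priors$lambda_mean, lambda_var = 0,
                        h_rel = 1e-4) {
  if (inherits(y, "roi_timeseries")) y <- y$values
  y <- as.matrix(y)
  Tn <- nrow(y)
  n <- ncol(y)
  q_cov <- as.matrix(q_cov)
  ev <- eigen(q_cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(abs(ev), 1))) {
    stop("posterior covariance must be positive semi-definite")
  }
  Q <- confound_basis(Tn, priors$confounds %||% "linear")
  T_eff <- Tn - if (is.null(Q)) 0 else ncol(Q)
  g <- predict_fn(q_mean)
  e <- project_confounds(y, Q) - project_confounds(g, Q)
  p <- length(q_mean)
  J <- if (p > 0) fd_jacobian(predict_fn, q_mean, dim(e), Q, h_rel) else
    matrix(0, Tn * n, 0)
  P0 <- if (p > 0) solve(priors$theta_cov) else matrix(0, 0, 0)
  prior_logdet <- if (p > 0) {
    determinant(priors$theta_cov, logarithm = TRUE)$modulus
  } else 0
  lambda <- rep(lambda, length.out = n)
  lambda_var <- rep(lambda_var, length.out = n)
  vl_F(e, J, q_cov, q_mean, priors$theta_mean, P0, prior_logdet,
       lambda, lambda_var, priors$lambda_mean, priors$lambda_var, T_eff)
}

#' Posterior summaries with tail probabilities
#'
#' For each free parameter, the posterior mean, standard deviation, and the
#' Gaussian posterior probability that the effect magnitude exceeds a
#' threshold, `P(|theta| > threshold)`. A zero-variance (structural)
#' parameter yields a probability of exactly 0 or 1.
#'
#' @param fit a `dcm_fit` from [invert()] or [vl_fit()].
#' @param threshold effect-size threshold (default 0).
#'
#' @return Data frame with columns `parameter`, `mean`, `sd`, `prob`.
#' @export
summarize_posterior <- function(fit, threshold = 0) {
  stopifnot(inherits(fit, "dcm_fit"))
  mu <- fit$posterior_mean
  sdv <- sqrt(pmax(diag(as.matrix(fit$posterior_cov)), 0))
  # probability the effect exceeds the threshold in the direction of its
  # posterior mean (conditional probability convention)
  prob <- ifelse(
    sdv == 0,
    as.numeric(abs(mu) > threshold),
    pnorm((abs(mu) - threshold) / sdv)
  )
  data.frame(parameter = fit$theta_names %||% names(mu) %||%
               paste0("theta", seq_along(mu)),
             mean = as.numeric(mu), sd = sdv, prob = as.numeric(prob),
             row.names = NULL)
}
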