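#' Connectivity parameters of a bilinear neuronal model
#'
#' Bundles the coupling matrices of the bilinear neural state equation
#' \deqn{\dot z = (A + \sum_j u_j B^{(j)}) z + C u,}
#' where \eqn{z} is the vector of regional neuronal activities and \eqn{u}
#' the vector of experimental inputs. All couplings are rates in Hz.
#'
#' @param A n-by-n matrix of intrinsic coupling rates (Hz). The diagonal
#'   holds the self-decay of each region and must be strictly negative.
#' @param B n-by-n-by-m array of modulatory coupling changes (Hz), one slice
#'   per input channel. A single matrix is promoted to one slice.
#' @param C n-by-m matrix of direct input weights (Hz per unit input).
#' @param region_labels character vector of region names (length n).
#' @param input_labels character vector of input channel names (length m).
#'
#' @return An object of class `dcm_params`.
#' @export
connectivity_params <- function(A, B = NULL, C = NULL,
                                region_labels = NULL, input_labels = NULL) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (ncol(A) != n) stop("A must be square, got ", n, " x ", ncol(A))
  if (any(diag(A) >= 0)) {
    stop("diagonal of A must be strictly negative (self-decay)")
  }
  if (is.null(C)) C <- matrix(0, n, 1)
  C <- as.matrix(C)
  m <- ncol(C)
  if (nrow(C) != n) stop("C has ", nrow(C), " rows but there are ", n, " regions")
  if (is.null(B)) B <- array(0, dim = c(n, n, m))
  if (is.matrix(B)) B <- array(B, dim = c(n, n, 1))
  if (!all(dim(B) == c(n, n, m))) {
    stop("B must be an ", n, " x ", n, " x ", m,
         " array consistent with A and C, got ", paste(dim(B), collapse = " x "))
  }
  if (is.null(region_labels)) region_labels <- paste0("R", seq_len(n))
  if (is.null(input_labels)) input_labels <- paste0("u", seq_len(m))
  if (length(region_labels) != n) stop("region_labels must have length ", n)
  if (length(input_labels) != m) stop("input_labels must have length ", m)
  dimnames(A) <- list(region_labels, region_labels)
  dimnames(C) <- list(region_labels, input_labels)
  structure(
    list(n_regions = n, A = A, B = B, C = C,
         region_labels = region_labels, input_labels = input_labels),
    class = "dcm_params"
  )
}

#' Balloon-Windkessel hemodynamic constants
#'
#' Classical balloon-model constants for one region. The BOLD observation
#' coefficients default to the standard 1.5 T parameterization
#' `k1 = 7 rho`, `k2 = 2`, `k3 = 2 rho - 0.2`.
#'
#' @param kappa signal decay rate (1/s).
#' @param gamma autoregulatory feedback rate (1/s).
#' @param tau mean transit time (s).
#' @param alpha Grubb vessel stiffness exponent (0 < alpha < 1).
#' @param rho resting oxygen extraction fraction (0 < rho < 1).
#' @param V0 resting venous blood volume fraction.
#' @param k1,k2,k3 BOLD observation coefficients.
#'
#' @return An object of class `hemo_params`.
#' @export
hemodynamic_params <- function(kappa = 0.64, gamma = 0.32, tau = 2.0,
                               alpha = 0.32, rho = 0.32, V0 = 0.04,
                               k1 = 7 * rho, k2 = 2, k3 = 2 * rho - 0.2) {
  stopifnot(kappa > 0, gamma > 0, tau > 0, V0 > 0, k1 > 0, k2 > 0)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (rho <= 0 || rho >= 1) stop("rho must lie in (0, 1)")
  structure(
    list(kappa = kappa, gamma = gamma, tau = tau, alpha = alpha, rho = rho,
         V0 = V0, k1 = k1, k2 = k2, k3 = k3),
    class = "hemo_params"
  )
}

# per-region constants as the n x 9 matrix the C++ integrator expects
hemo_matrix <- function(h, n) {
  if (inherits(h, "hemo_params")) h <- rep(list(h), n)
  if (length(h) != n) stop("need one hemo_params per region")
  t(vapply(h, function(x) {
    c(x$kappa, x$gamma, x$tau, x$alpha, x$rho, x$V0, x$k1, x$k2, x$k3)
  }, numeric(9)))
}

#' Neuronal drift of the bilinear state equation
#'
#' Evaluates \eqn{\dot z = (A + \sum_j u_j B^{(j)}) z + C u}.
#'
#' @param z numeric vector of regional neuronal activities.
#' @param u numeric vector of input values.
#' @param params a [connectivity_params()] object.
#'
#' @return Numeric vector of derivatives, one per region.
#' @export
neuronal_drift <- function(z, u, params) {
  stopifnot(inherits(params, "dcm_params"))
  n <- params$n_regions
  m <- length(params$input_labels)
  if (length(z) != n) {
    stop("z has length ", length(z), " but params declares ", n, " regions")
  }
  if (length(u) != m) {
    stop("u has length ", length(u), " but params declares ", m, " inputs")
  }
  Aeff <- params$A
  for (j in seq_len(m)) {
    if (u[j] != 0) Aeff <- Aeff + u[j] * params$B[, , j]
  }
  drop(Aeff %*% z + params$C %*% u)
}

#' Hemodynamic drift (balloon-Windkessel) for one region
#'
#' State equations: \eqn{\dot s = z - \kappa s - \gamma(f - 1)},
#' \eqn{\dot f = s}, \eqn{\tau \dot v = f - v^{1/\alpha}},
#' \eqn{\tau \dot q = f E(f,\rho)/\rho - v^{1/\alpha} q / v} with oxygen
#' extraction \eqn{E(f,\rho) = 1 - (1-\rho)^{1/f}}.
#'
#' @param state named numeric vector or list with elements `z`, `s`, `f`,
#'   `v`, `q` for a single region.
#' @param h a [hemodynamic_params()] object.
#'
#' @return Named numeric vector `c(ds, df, dv, dq)`.
#' @export
hemodynamic_drift <- function(state, h) {
  stopifnot(inherits(h, "hemo_params"))
  state <- as.list(state)
  z <- state$z; s <- state$s; f <- state$f; v <- state$v; q <- state$q
  if (!(f > 0 && v > 0 && q > 0)) {
    stop("f, v and q must stay strictly positive (integration step too large?)")
  }
  fv <- v^(1 / h$alpha)
  E <- 1 - (1 - h$rho)^(1 / f)
  c(ds = z - h$kappa * s - h$gamma * (f - 1),
    df = s,
    dv = (f - fv) / h$tau,
    dq = (f * E / h$rho - fv * q / v) / h$tau)
}

#' BOLD observation equation
#'
#' \eqn{y = V_0 [k_1 (1-q) + k_2 (1 - q/v) + k_3 (1 - v)]}, the fractional
#' signal change relative to baseline.
#'
#' @param v normalized venous volume (> 0).
#' @param q normalized deoxyhemoglobin content (> 0).
#' @param h a [hemodynamic_params()] object.
#'
#' @return Fractional BOLD signal change (0 at rest).
#' @export
bold_observation <- function(v, q, h) {
  stopifnot(inherits(h, "hemo_params"))
  if (any(v <= 0) || any(q <= 0)) stop("v and q must be strictly positive")
  h$V0 * (h$k1 * (1 - q) + h$k2 * (1 - q / v) + h$k3 * (1 - v))
}

#' Largest real part of the intrinsic coupling eigenvalues
#'
#' A negative value certifies that the unforced neuronal dynamics decay to
#' rest; assert this before simulating.
#'
#' @param params a [connectivity_params()] object.
#' @return Largest real part among the eigenvalues of `A`.
#' @export
max_eigen_real <- function(params) {
  max(Re(eigen(params$A, only.values = TRUE)$values))
}

#' ROI time-series container
#'
#' @param values scans-by-regions numeric matrix.
#' @param TR repetition time in seconds (> 0).
#' @param region_labels character vector naming the columns.
#'
#' @return An object of class `roi_timeseries` with fields `values`, `TR`,
#'   `region_labels` and `scan_onsets` (volume onset times in seconds).
#' @export
roi_timeseries <- function(values, TR, region_labels = colnames(values)) {
  values <- as.matrix(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("ROI time series must not contain missing or non-finite values")
  }
  if (!is.numeric(TR) || length(TR) != 1 || TR <= 0) stop("TR must be > 0")
  if (is.null(region_labels)) region_labels <- paste0("R", seq_len(ncol(values)))
  if (length(region_labels) != ncol(values)) {
    stop("region_labels length (", length(region_labels),
         ") must equal the number of columns (", ncol(values), ")")
  }
  colnames(values) <- region_labels
  structure(
    list(values = values, TR = TR, region_labels = region_labels,
         scan_onsets = (seq_len(nrow(values)) - 1) * TR),
    class = "roi_timeseries"
  )
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat("ROI time series:", nrow(x$values), "scans x", ncol(x$values),
      "regions, TR =", x$TR, "s\n")
  cat("regions:", paste(x$region_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Simulate noiseless BOLD time series from a DCM
#'
#' Integrates the coupled neuronal and hemodynamic differential equations
#' from rest with fixed-step RK4, holding inputs constant within each scan
#' (zero-order hold), and samples the BOLD observation at each volume onset.
#'
#' @param params a [connectivity_params()] object.
#' @param design an [experiment_design()] covering the scan window.
#' @param hemo a [hemodynamic_params()] object, or a list of one per region.
#' @param dt integration step in seconds; must divide the TR. Default TR/8.
#' @param z_bound divergence guard: an error is raised if any neuronal state
#'   exceeds this magnitude.
#' @param percent report signal as percent of baseline (default) rather than
#'   as a baseline fraction.
#'
#' @return A [roi_timeseries()] of simulated BOLD (percent signal change).
#' @export
simulate_timeseries <- function(params, design, hemo = hemodynamic_params(),
                                dt = design$TR / 8, z_bound = 10,
                                percent = TRUE) {
  stopifnot(inherits(params, "dcm_params"), inherits(design, "dcm_design"))
  if (dt > design$TR) stop("dt must not exceed the TR")
  nsub <- round(design$TR / dt)
  U <- design$inputs
  if (ncol(U) != length(params$input_labels)) {
    stop("design provides ", ncol(U), " input channels but params declares ",
         length(params$input_labels))
  }
  H <- hemo_matrix(hemo, params$n_regions)
  res <- sim_bold_cpp(params$A, as.numeric(params$B), params$C, U, H,
                      design$TR, nsub, z_bound)
  if (!res$ok) {
    stop("unstable dynamics: |z| exceeded ", z_bound, " near t = ",
         res$t_div, " s")
  }
  vals <- res$bold
  if (percent) vals <- vals * 100
  roi_timeseries(vals, design$TR, params$region_labels)
}
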