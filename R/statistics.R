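#' One-tailed sign test with continuity-corrected normal approximation
#'
#' Tests whether the median exceeds zero from the count of positive values.
#' Exact zeros are excluded. The z statistic uses a continuity correction of
#' one half: \eqn{z = (k - 0.5 - n/2) / \sqrt{n/4}}, and the p-value is the
#' upper Gaussian tail of the unrounded z.
#'
#' @param values numeric vector, or `NULL` when `k` and `n` are given
#'   directly.
#' @param k number of positive values (used with `n` when `values` is
#'   `NULL`).
#' @param n number of non-zero values.
#'
#' @return An object of class `sign_test_result` with fields `k`, `n`, `z`,
#'   `p`.
#' @export
sign_test <- function(values = NULL, k = NULL, n = NULL) {
  if (!is.null(values)) {
    values <- values[values != 0]
    n <- length(values)
    k <- sum(values > 0)
  }
  if (is.null(k) || is.null(n)) stop("provide values, or k and n")
  if (n < 1) stop("sign test needs at least one non-zero value")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  z <- (k - 0.5 - n / 2) / sqrt(n / 4)
  p <- pnorm(z, lower.tail = FALSE)
  structure(list(k = k, n = n, z = z, p = p), class = "sign_test_result")
}

#' @export
print.sign_test_result <- function(x, ...) {
  cat(sprintf("sign test: sign = %d of n = %d, z = %.2f, p = %.3f\n",
              x$k, x$n, x$z, x$p))
  invisible(x)
}

#' Descriptive statistics used for feedback distributions
#'
#' Median, first quartile, upper quartile and interquartile range, with
#' quartiles by linear interpolation (quantile type 7).
#'
#' @param values numeric vector (at least one value).
#' @return List with fields `m`, `fq`, `sq`, `iqr`.
#' @export
describe <- function(values) {
  if (length(values) < 1) stop("describe needs at least one value")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  list(m = q[2], fq = q[1], sq = q[3], iqr = q[3] - q[1])
}

#' Permutation test for a trend across runs
#'
#' Regresses a per-run statistic (median, or sign-test z) on the run index
#' and tests the observed slope against a null built by permuting values
#' across runs. One-tailed: p is the proportion of permuted slopes at least
#' as large as the observed one, with the +1 correction.
#'
#' @param values numeric vector of per-trial values.
#' @param run_labels run membership of each value (coerced to a factor whose
#'   level order defines the run index).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @param statistic `"median"` or `"z"` (sign-test z per run).
#'
#' @return List with `slope` (observed), `p`, `per_run` (observed per-run
#'   statistics), `n_perm`.
#' @export
permutation_slope_test <- function(values, run_labels, n_perm = 999,
                                   seed = 1, statistic = c("median", "z")) {
  statistic <- match.arg(statistic)
  run_labels <- factor(run_labels)
  R <- nlevels(run_labels)
  if (R < 2) stop("need at least two distinct runs")
  stat_fn <- switch(statistic,
                    median = function(v) median(v),
                    z = function(v) sign_test(v)$z)
  slope_of <- function(v) {
    per_run <- tapply(v, run_labels, stat_fn)
    unname(coef(lm.fit(cbind(1, seq_len(R)), as.numeric(per_run)))[2])
  }
  obs <- slope_of(values)
  per_run <- tapply(values, run_labels, stat_fn)
  count <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      slope_of(sample(values)) >= obs
    }, logical(1)))
  })
  list(slope = obs, p = (1 + count) / (n_perm + 1),
       per_run = as.numeric(per_run), n_perm = n_perm)
}

#' Percent signal change per region
#'
#' `100 * (mean(condition) - mean(baseline)) / mean(baseline)`, with the
#' baseline mean taken on the raw (pre-cleaning) signal.
#'
#' @param window a [roi_timeseries()] or scans-by-regions matrix of raw
#'   signal.
#' @param condition_scans,baseline_scans disjoint, non-empty scan index
#'   sets.
#'
#' @return Named numeric vector of percent signal change per region.
#' @export
percent_signal_change <- function(window, condition_scans, baseline_scans) {
  if (inherits(window, "roi_timeseries")) window <- window$values
  check_scan_sets(window, condition_scans, baseline_scans)
  mb <- colMeans(window[baseline_scans, , drop = FALSE])
  if (any(mb == 0)) stop("baseline mean is zero; percent change undefined")
  mc <- colMeans(window[condition_scans, , drop = FALSE])
  100 * (mc - mb) / mb
}

check_scan_sets <- function(window, condition_scans, baseline_scans) {
  if (length(condition_scans) < 1 || length(baseline_scans) < 1) {
    stop("condition and baseline scan sets must be non-empty")
  }
  if (length(intersect(condition_scans, baseline_scans)) > 0) {
    stop("condition and baseline scan sets must be disjoint")
  }
  if (max(condition_scans, baseline_scans) > nrow(window)) {
    stop("scan indices exceed the window")
  }
  invisible(TRUE)
}

#' Contrast-to-noise ratio per region
#'
#' Condition-minus-baseline mean divided by the standard deviation of the
#' baseline residuals after removing a linear trend from the baseline
#' scans.
#'
#' @inheritParams percent_signal_change
#' @return Named numeric vector of CNR per region.
#' @export
cnr <- function(window, condition_scans, baseline_scans) {
  if (inherits(window, "roi_timeseries")) window <- window$values
  check_scan_sets(window, condition_scans, baseline_scans)
  if (length(baseline_scans) < 2) stop("need at least two baseline scans")
  X <- cbind(1, baseline_scans)
  res <- qr.resid(qr(X), window[baseline_scans, , drop = FALSE])
  sds <- apply(res, 2, sd)
  if (any(sds == 0)) stop("zero baseline variance; CNR undefined")
  mc <- colMeans(window[condition_scans, , drop = FALSE])
  mb <- colMeans(window[baseline_scans, , drop = FALSE])
  (mc - mb) / sds
}

#' Differential (left minus right) activity feedback value
#'
#' The classical activity-based baseline: the left-minus-right percent
#' signal change, sign-aligned so that a positive value means
#' condition-appropriate lateralization. Covert attention raises activity in
#' the contralateral hemisphere, so under the default convention an aL trial
#' is successful when the right hemisphere dominates (raw difference
#' negative, aligned value positive), and mirrored for aR.
#'
#' @param psc_left,psc_right percent signal change of the left and right
#'   region.
#' @param condition `"aL"` or `"aR"`.
#' @param contralateral logical; if `TRUE` (default) success means the
#'   hemisphere contralateral to the attended side dominates.
#'
#' @return List with `raw` (left minus right) and `aligned` (success-signed
#'   value).
#' @export
differential_feedback <- function(psc_left, psc_right,
                                  condition = c("aL", "aR"),
                                  contralateral = TRUE) {
  condition <- match.arg(condition)
  if (!is.finite(psc_left) || !is.finite(psc_right)) {
    stop("percent signal changes must be finite")
  }
  raw <- psc_left - psc_right
  s <- if (condition == "aL") -1 else 1
  if (!contralateral) s <- -s
  list(raw = raw, aligned = s * raw)
}

#' Jarque-Bera test of normality
#'
#' `JB = n/6 (S^2 + K^2/4)` with sample skewness S and excess kurtosis K;
#' the p-value comes from the chi-squared distribution with 2 degrees of
#' freedom.
#'
#' @param values numeric vector (n >= 8).
#' @return List with `statistic`, `p`, `skewness`, `kurtosis`.
#' @export
jarque_bera <- function(values) {
  n <- length(values)
  if (n < 8) stop("Jarque-Bera test needs at least 8 values")
  x <- values - mean(values)
  m2 <- mean(x^2)
  if (m2 == 0) stop("degenerate (zero-variance) sample")
  S <- mean(x^3) / m2^1.5
  K <- mean(x^4) / m2^2 - 3
  jb <- n / 6 * (S^2 + K^2 / 4)
  list(statistic = jb, p = pchisq(jb, df = 2, lower.tail = FALSE),
       skewness = S, kurtosis = K)
}
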