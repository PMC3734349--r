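#' Settings of the causal ROI-signal cleaner
#'
#' Three strictly causal stages applied per region at every scan:
#' \enumerate{
#'   \item drift removal: an exponentially-weighted running linear fit
#'     (recursive least squares on a constant + time basis with forgetting
#'     factor `2^(-1/half_life)`) is subtracted, so constants and slow
#'     ramps are tracked and removed without lag bias;
#'   \item spike clipping: residuals more than `spike_sd` robust standard
#'     deviations (1.4826 times the running MAD) away from the running
#'     median over the trailing `spike_window` scans are replaced by that
#'     running median (the drift tracker is updated with the clipped
#'     value, so a spike does not corrupt the running fit);
#'   \item high-frequency smoothing: a two-tap exponential moving average
#'     with weight `ema_weight` on the current sample.
#' }
#'
#' @param half_life drift-tracker half-life in scans (default 50).
#' @param spike_sd robust-SD clipping threshold (default 3).
#' @param spike_window trailing window for the running median/MAD
#'   (default 50 scans).
#' @param spike_warmup minimum samples before clipping engages (default 10).
#' @param ema_weight EMA weight on the current sample (default 0.6).
#'
#' @return An object of class `cleaner_settings`.
#' @export
cleaner_settings <- function(half_life = 50, spike_sd = 3, spike_window = 50,
                             spike_warmup = 10, ema_weight = 0.6) {
  stopifnot(half_life > 0, spike_sd > 0, spike_window >= 2,
            ema_weight > 0, ema_weight <= 1)
  structure(list(half_life = half_life, spike_sd = spike_sd,
                 spike_window = spike_window, spike_warmup = spike_warmup,
                 ema_weight = ema_weight),
            class = "cleaner_settings")
}

#' Initialize cleaner filter state
#'
#' @param n_regions number of ROI channels.
#' @param settings a [cleaner_settings()] object.
#' @return Opaque filter state for [clean_sample()].
#' @export
cleaner_init <- function(n_regions, settings = cleaner_settings()) {
  stopifnot(inherits(settings, "cleaner_settings"))
  structure(
    list(settings = settings, n_regions = n_regions, t = 0L,
         # RLS per region: 2x2 information matrix and 2-vector
         Phi = rep(list(diag(1e-8, 2)), n_regions),
         psi = rep(list(numeric(2)), n_regions),
         buf = rep(list(numeric(0)), n_regions),
         ema = numeric(n_regions)),
    class = "cleaner_state"
  )
}

#' Clean one scan of ROI values (streaming)
#'
#' Strictly causal: the output at scan t depends only on scans up to t.
#' Feeding scans one at a time reproduces bit-identically the output of
#' [clean_series()] on the full series.
#'
#' @param x numeric vector of raw ROI values at one scan.
#' @param state filter state from [cleaner_init()] (threaded through calls).
#'
#' @return List with `values` (cleaned vector) and `state` (updated).
#' @export
clean_sample <- function(x, state) {
  stopifnot(inherits(state, "cleaner_state"))
  if (length(x) != state$n_regions) {
    stop("expected ", state$n_regions, " region values, got ", length(x))
  }
  if (any(!is.finite(x))) {
    stop("non-finite input at scan ", state$t + 1L, ", region ",
         paste(which(!is.finite(x)), collapse = ", "))
  }
  s <- state$settings
  a <- 2^(-1 / s$half_life)
  t <- state$t + 1L
  phi <- c(1, t)
  out <- numeric(state$n_regions)
  for (r in seq_len(state$n_regions)) {
    Phi <- state$Phi[[r]]
    psi <- state$psi[[r]]
    pred <- if (t == 1L) x[r] else if (t == 2L) {
      psi[1] / Phi[1, 1]  # one sample cannot determine a slope yet
    } else {
      co <- tryCatch(solve(Phi, psi), error = function(e) c(psi[1] / Phi[1, 1], 0))
      sum(phi * co)
    }
    res <- x[r] - pred
    # robust spike clipping on the drift-removed residual; the running
    # median/MAD buffer keeps the raw residuals so the scale estimate can
    # adapt to genuine signal swings instead of clipping them forever
    buf <- state$buf[[r]]
    clipped <- res
    if (length(buf) >= s$spike_warmup) {
      med <- median(buf)
      madv <- 1.4826 * median(abs(buf - med))
      if (madv > 0 && abs(res - med) > s$spike_sd * madv) clipped <- med
    }
    buf <- c(buf, res)
    if (length(buf) > s$spike_window) buf <- buf[-1]
    # spike-protected drift update
    xp <- pred + clipped
    state$Phi[[r]] <- a * Phi + tcrossprod(phi)
    state$psi[[r]] <- a * psi + phi * xp
    state$buf[[r]] <- buf
    ema <- s$ema_weight * clipped + (1 - s$ema_weight) * state$ema[r]
    state$ema[r] <- ema
    out[r] <- ema
  }
  state$t <- t
  list(values = out, state = state)
}

#' Clean a full ROI time series offline
#'
#' Runs [clean_sample()] over every scan in order, so offline and streaming
#' use are bit-identical.
#'
#' @param series a [roi_timeseries()] or scans-by-regions matrix.
#' @param settings a [cleaner_settings()] object.
#' @param state optional pre-initialized state (continues a stream).
#'
#' @return List with `series` (cleaned, same container type as the input)
#'   and `state` (final filter state).
#' @export
clean_series <- function(series, settings = cleaner_settings(),
                         state = NULL) {
  vals <- if (inherits(series, "roi_timeseries")) series$values else
    as.matrix(series)
  if (is.null(state)) state <- cleaner_init(ncol(vals), settings)
  out <- matrix(0, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  for (i in seq_len(nrow(vals))) {
    step <- clean_sample(vals[i, ], state)
    out[i, ] <- step$values
    state <- step$state
  }
  cleaned <- if (inherits(series, "roi_timeseries")) {
    roi_timeseries(out, series$TR, series$region_labels)
  } else out
  list(series = cleaned, state = state)
}
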