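#' Window specification for trial extraction and the sliding-window sweep
#'
#' @param length_scans window length in scans (default 90: five baseline
#'   blocks interleaved with four regulation blocks of 10 s at TR = 1 s,
#'   i.e. one full trial).
#' @param step_scans shift between sliding-window placements (default 20).
#'
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(length_scans = 90, step_scans = 20) {
  if (length_scans < 30) stop("window length must be at least 30 scans")
  if (step_scans < 1) stop("step must be at least 1 scan")
  structure(list(length_scans = length_scans, step_scans = step_scans),
            class = "window_spec")
}

#' Number of sliding-window placements
#'
#' `floor((run_length - length) / step) + 1` windows fit on a run.
#'
#' @param run_length run length in scans.
#' @param length_scans window length.
#' @param step_scans window step.
#' @return Integer number of placements (0 when the window does not fit).
#' @export
n_window_placements <- function(run_length, length_scans, step_scans = 20) {
  if (length_scans > run_length) return(0L)
  as.integer(floor((run_length - length_scans) / step_scans) + 1)
}

#' Extract one trial's regulation window
#'
#' Returns the trial-long segment (by default 90 scans: the baseline and
#' regulation blocks; rest and display scans are excluded) together with
#' its condition label and the block metadata falling inside the window.
#'
#' @param series a [roi_timeseries()] (usually cleaned) covering the trial.
#' @param trial_index 1-based trial number.
#' @param design the session [make_design()] (carries the trial table).
#' @param spec a [window_spec()].
#'
#' @return List with `values` (window matrix), `scans` (indices into the
#'   session), `condition`, `blocks`, `design` (single-input window design
#'   for inversion).
#' @export
extract_trial_window <- function(series, trial_index, design,
                                 spec = window_spec()) {
  stopifnot(inherits(design, "dcm_design"))
  vals <- if (inherits(series, "roi_timeseries")) series$values else
    as.matrix(series)
  if (is.null(design$trials)) stop("design carries no trial table")
  row <- design$trials[design$trials$trial == trial_index, ]
  if (nrow(row) != 1) stop("unknown trial index ", trial_index)
  scans <- row$onset_scan + seq_len(spec$length_scans) - 1
  if (max(scans) > nrow(vals)) {
    stop("trial ", trial_index, " window extends past the available data (",
         max(scans), " > ", nrow(vals), " scans)")
  }
  t0 <- (row$onset_scan - 1) * design$TR
  t1 <- t0 + spec$length_scans * design$TR
  blocks <- design$blocks[design$blocks$onset >= t0 - 1e-9 &
                            design$blocks$onset < t1 - 1e-9, , drop = FALSE]
  list(values = vals[scans, , drop = FALSE], scans = scans,
       condition = row$condition, blocks = blocks,
       design = inversion_design(design, scans))
}

# round half away from zero, the display convention for the feedback value
round_display <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Compute the feedback signal for one trial window
#'
#' Inverts both candidate models of the pair on the window; the feedback
#' signal is the log Bayes factor `F(M_aL) - F(M_aR)`. A trial succeeds
#' when the condition-appropriate model dominates (positive logBF for aL,
#' negative for aR); an exact tie counts as failure. The display value is
#' the log Bayes factor rounded half away from zero, shown as UP for aL
#' trials and DOWN for aR trials; each success adds 1 CHF to the cumulative
#' reward.
#'
#' @param window window values (matrix or [roi_timeseries()]).
#' @param design single-input window design (see [extract_trial_window()]).
#' @param condition `"aL"` or `"aR"`.
#' @param pair model pair from [attention_pair()].
#' @param trial_index trial number recorded in the event.
#' @param reward_so_far cumulative reward before this trial (CHF).
#' @param max_iter,tol inversion budget and tolerance.
#' @param ... passed to [invert()].
#'
#' @return An object of class `feedback_event`: `trial_index`, `condition`,
#'   `logBF`, `pooled_logBF` (sign-aligned: aR values inverted),
#'   `display_word`, `display_value`, `success`, `valid`, `reward_total`,
#'   `n_iterations` and `converged` per model.
#' @export
compute_feedback <- function(window, design, condition = c("aL", "aR"),
                             pair = attention_pair(), trial_index = 1L,
                             reward_so_far = 0, max_iter = 44, tol = 0.05,
                             ...) {
  condition <- match.arg(condition)
  if (inherits(window, "roi_timeseries")) window <- window$values
  fits <- lapply(pair, function(m) {
    tryCatch(invert(window, m, design, max_iter = max_iter, tol = tol, ...),
             error = function(e) NULL)
  })
  if (any(vapply(fits, is.null, logical(1)))) {
    return(structure(
      list(trial_index = trial_index, condition = condition, logBF = NA_real_,
           pooled_logBF = NA_real_, display_word = NA_character_,
           display_value = NA_real_, success = FALSE, valid = FALSE,
           reward_total = reward_so_far,
           n_iterations = c(NA_integer_, NA_integer_),
           converged = c(FALSE, FALSE)),
      class = "feedback_event"))
  }
  logBF <- fits[[1]]$F - fits[[2]]$F
  success <- (condition == "aL" && logBF > 0) ||
    (condition == "aR" && logBF < 0)
  structure(
    list(trial_index = trial_index, condition = condition, logBF = logBF,
         pooled_logBF = if (condition == "aR") -logBF else logBF,
         display_word = if (condition == "aL") "UP" else "DOWN",
         display_value = round_display(logBF),
         success = success, valid = TRUE,
         reward_total = reward_so_far + as.numeric(success),
         n_iterations = vapply(fits, `[[`, integer(1), "n_iterations"),
         converged = vapply(fits, `[[`, logical(1), "converged")),
    class = "feedback_event")
}

#' @export
print.feedback_event <- function(x, ...) {
  cat(sprintf("trial %d [%s]: %s (%+d)  logBF = %.2f  %s  reward = %d CHF\n",
              x$trial_index, x$condition, x$display_word %||% "?",
              as.integer(x$display_value %||% 0), x$logBF,
              if (isTRUE(x$success)) "success" else "failure",
              as.integer(x$reward_total)))
  invisible(x)
}

#' Run a full neurofeedback session through the streaming pipeline
#'
#' Processes the raw ROI stream scan by scan through the causal cleaner,
#' and after each trial's regulation window is complete inverts the model
#' pair on the cleaned window and emits one feedback event (the inversion
#' budget defaults to 44 iterations per model, so the feedback is always
#' produced; an unconverged fit is flagged, never dropped). The cumulative
#' reward increases by 1 CHF per successful trial.
#'
#' @param series raw session [roi_timeseries()].
#' @param design session [make_design()] with a trial table.
#' @param pair model pair from [attention_pair()].
#' @param spec a [window_spec()].
#' @param cleaner a [cleaner_settings()].
#' @param max_iter,tol inversion budget and tolerance.
#' @param ... passed to [invert()].
#'
#' @return An object of class `session_log`: list of `feedback_event`s with
#'   attributes `reward_total` and `n_trials`.
#' @export
run_session <- function(series, design, pair = attention_pair(),
                        spec = window_spec(), cleaner = cleaner_settings(),
                        max_iter = 44, tol = 0.05, ...) {
  stopifnot(inherits(series, "roi_timeseries"),
            inherits(design, "dcm_design"))
  if (is.null(design$trials)) stop("design carries no trial table")
  vals <- series$values
  state <- cleaner_init(ncol(vals), cleaner)
  cleaned <- matrix(0, nrow(vals), ncol(vals))
  events <- list()
  reward <- 0
  next_trial <- 1L
  trials <- design$trials
  for (i in seq_len(nrow(vals))) {
    step <- clean_sample(vals[i, ], state)
    cleaned[i, ] <- step$values
    state <- step$state
    while (next_trial <= nrow(trials) &&
           i >= trials$onset_scan[next_trial] + spec$length_scans - 1) {
      win <- extract_trial_window(cleaned[seq_len(i), , drop = FALSE],
                                  next_trial, design, spec)
      ev <- compute_feedback(win$values, win$design, win$condition, pair,
                             trial_index = next_trial,
                             reward_so_far = reward,
                             max_iter = max_iter, tol = tol, ...)
      reward <- ev$reward_total
      events[[length(events) + 1L]] <- ev
      next_trial <- next_trial + 1L
    }
  }
  structure(events, class = "session_log", reward_total = reward,
            n_trials = length(events))
}

#' @export
print.session_log <- function(x, ...) {
  cat("Session log:", length(x), "trials, total reward",
      attr(x, "reward_total"), "CHF\n")
  for (ev in x) print(ev)
  invisible(x)
}

#' Sliding-window optimization sweep
#'
#' For each candidate window length, slides a window across a run in fixed
#' steps, inverts the model pair on every placement, and scores how often
#' the dominant model matches the window's condition. Each window is
#' labelled by the majority condition among its regulation scans; the
#' condition-aligned log Bayes factors (aR windows inverted) are summarized
#' by the one-tailed sign test.
#'
#' @param series cleaned run [roi_timeseries()].
#' @param design run design (e.g. a localizer [make_design()]).
#' @param lengths window lengths in scans (default 30 to 210 in steps
#'   of 20).
#' @param step placement step in scans (default 20).
#' @param pair model pair.
#' @param max_iter,tol inversion budget and tolerance.
#' @param ... passed to [invert()].
#'
#' @return A data frame of class `sweep_report`: one row per window length
#'   with `n_windows`, `n_correct`, `sign`, `z`, `p`, `mean_iterations`,
#'   `sd_iterations`.
#' @export
window_sweep <- function(series, design, lengths = seq(30, 210, by = 20),
                         step = 20, pair = attention_pair(), max_iter = 44,
                         tol = 0.05, ...) {
  vals <- if (inherits(series, "roi_timeseries")) series$values else
    as.matrix(series)
  if (nrow(vals) < max(lengths)) {
    stop("run (", nrow(vals), " scans) shorter than the largest window")
  }
  cond_per_scan <- scan_conditions(design)
  rows <- lapply(lengths, function(W) {
    starts <- seq(1, nrow(vals) - W + 1, by = step)
    aligned <- numeric(0)
    iters <- integer(0)
    n_correct <- 0L
    n_windows <- 0L
    for (s0 in starts) {
      scans <- s0:(s0 + W - 1)
      cond <- majority_condition(cond_per_scan[scans])
      if (is.na(cond)) next
      n_windows <- n_windows + 1L
      ev <- compute_feedback(vals[scans, , drop = FALSE],
                             inversion_design(design, scans), cond, pair,
                             trial_index = n_windows, max_iter = max_iter,
                             tol = tol, ...)
      if (isTRUE(ev$success)) n_correct <- n_correct + 1L
      aligned <- c(aligned, ev$pooled_logBF)
      iters <- c(iters, ev$n_iterations)
    }
    st <- if (length(aligned[aligned != 0]) > 0) sign_test(aligned) else
      list(k = 0L, z = NA_real_, p = NA_real_)
    data.frame(length_scans = W, n_windows = n_windows,
               n_correct = n_correct, sign = st$k, z = st$z, p = st$p,
               mean_iterations = mean(iters), sd_iterations = sd(iters))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_report", "data.frame")
  out
}

# condition label per scan from the block table ("aL"/"aR"/NA)
scan_conditions <- function(design) {
  out <- rep(NA_character_, design$n_scans)
  bl <- design$blocks[design$blocks$label %in% c("aL", "aR"), , drop = FALSE]
  for (k in seq_len(nrow(bl))) {
    from <- floor(bl$onset[k] / design$TR) + 1
    to <- min(design$n_scans, ceiling((bl$onset[k] + bl$duration[k]) / design$TR))
    out[from:to] <- bl$label[k]
  }
  out
}

majority_condition <- function(labels) {
  nL <- sum(labels == "aL", na.rm = TRUE)
  nR <- sum(labels == "aR", na.rm = TRUE)
  if (nL == 0 && nR == 0) return(NA_character_)
  if (nL == nR) return(NA_character_)
  if (nL > nR) "aL" else "aR"
}

#' Canonical hemodynamic response function
#'
#' Double-gamma HRF (peak at 6 s, undershoot at 16 s, undershoot ratio
#' 1/6), scaled to unit peak.
#'
#' @param t time in seconds.
#' @return HRF values at `t`.
#' @export
canonical_hrf <- function(t) {
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h / max(dgamma(seq(0, 30, by = 0.01), shape = 6, rate = 1) -
            dgamma(seq(0, 30, by = 0.01), shape = 16, rate = 1) / 6)
}

#' Simple GLM localizer for ROI definition
#'
#' Per-voxel least-squares fit of a task regressor (block boxcar convolved
#' with the canonical HRF) plus constant and linear drift; voxels with a
#' significant positive one-sided t statistic survive a Bonferroni-corrected
#' threshold and form the binary ROI mask.
#'
#' @param Y scans-by-voxels matrix of voxel time series.
#' @param design run design whose non-baseline task blocks define the
#'   boxcar (labels other than `baseline`, `rest`, `display`).
#' @param alpha family-wise error level (default 0.05, Bonferroni over
#'   voxels).
#'
#' @return List with `mask` (logical per voxel), `tstat`, `p_corrected`,
#'   `threshold` (t threshold applied), `df`.
#' @export
glm_localizer <- function(Y, design, alpha = 0.05) {
  Y <- as.matrix(Y)
  Tn <- nrow(Y)
  task_labels <- setdiff(unique(design$blocks$label),
                         c("baseline", "rest", "display"))
  if (length(task_labels) == 0) stop("design has no task blocks")
  box <- blocks_to_input(design$blocks, task_labels, design$n_scans,
                         design$TR)[seq_len(Tn)]
  hrf <- canonical_hrf(seq(0, 30, by = design$TR))
  reg <- stats::convolve(box, rev(hrf), type = "open")[seq_len(Tn)]
  X <- cbind(task = reg, const = 1, drift = seq_len(Tn))
  if (qr(X)$rank < ncol(X)) stop("rank-deficient localizer design")
  fit <- lm.fit(X, Y)
  df <- Tn - ncol(X)
  rss <- colSums(as.matrix(fit$residuals)^2)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(XtXinv[1, 1] * rss / df)
  beta <- as.matrix(fit$coefficients)[1, ]
  tstat <- ifelse(se > 0, beta / se, 0)
  p <- stats::pt(tstat, df = df, lower.tail = FALSE)
  p_corr <- pmin(p * ncol(Y), 1)
  thr <- stats::qt(alpha / ncol(Y), df = df, lower.tail = FALSE)
  list(mask = p_corr < alpha, tstat = unname(tstat),
       p_corrected = unname(p_corr), threshold = thr, df = df)
}
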