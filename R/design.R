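#' Experiment design container
#'
#' Holds the input time courses (piecewise constant at scan resolution), the
#' block table, and the trial layout of one run or session.
#'
#' @param TR repetition time in seconds.
#' @param inputs scans-by-channels matrix of input values; each row is held
#'   constant over its scan (zero-order hold).
#' @param blocks data frame with columns `onset` (s), `duration` (s) and
#'   `label` (one of `baseline`, `aL`, `aR`, `rest`, `display`, `stim`).
#'   Blocks must not overlap and must tile the run.
#' @param input_labels names of the input channels.
#' @param trials optional data frame with columns `trial`, `onset_scan`
#'   (1-based scan index of the trial window start) and `condition`.
#' @param layout free-form tag, e.g. `"neurofeedback"` or `"localizer"`.
#'
#' @return An object of class `dcm_design`.
#' @export
experiment_design <- function(TR, inputs, blocks = NULL,
                              input_labels = colnames(inputs),
                              trials = NULL, layout = "custom") {
  inputs <- as.matrix(inputs)
  if (is.null(input_labels)) input_labels <- paste0("u", seq_len(ncol(inputs)))
  colnames(inputs) <- input_labels
  if (!is.null(blocks)) {
    blocks <- blocks[order(blocks$onset), , drop = FALSE]
    ends <- blocks$onset + blocks$duration
    if (any(blocks$onset[-1] < ends[-length(ends)] - 1e-9)) {
      stop("blocks must not overlap")
    }
  }
  structure(
    list(TR = TR, n_scans = nrow(inputs), inputs = inputs,
         input_labels = input_labels, blocks = blocks, trials = trials,
         layout = layout),
    class = "dcm_design"
  )
}

#' @export
print.dcm_design <- function(x, ...) {
  cat("Experiment design (", x$layout, "): ", x$n_scans, " scans, TR = ",
      x$TR, " s, inputs: ", paste(x$input_labels, collapse = ", "), "\n",
      sep = "")
  if (!is.null(x$trials)) cat(nrow(x$trials), "trials\n")
  invisible(x)
}

# boxcar input column from a block table, at scan resolution
blocks_to_input <- function(blocks, labels, n_scans, TR) {
  u <- numeric(n_scans)
  sel <- blocks[blocks$label %in% labels, , drop = FALSE]
  for (k in seq_len(nrow(sel))) {
    from <- floor(sel$onset[k] / TR) + 1
    to <- min(n_scans, ceiling((sel$onset[k] + sel$duration[k]) / TR))
    u[from:to] <- 1
  }
  u
}

#' Build a standard study design
#'
#' `"neurofeedback"`: each trial is five 10 s baseline blocks interleaved
#' with four 10 s regulation blocks (90 scans at TR = 1 s), followed by 60 s
#' of rest (feedback computation) and 5 s of feedback display; attention
#' left/right conditions alternate across trials, 8 trials per run.
#' `"localizer"`: 11 baseline blocks interleaved with 10 attention blocks,
#' all 10 s, i.e. a 210-scan run with alternating aL/aR attention blocks.
#'
#' Two input channels are generated (`att_L`, `att_R`), one per attention
#' condition; for model inversion they are usually collapsed into the single
#' attention input a candidate model declares (see [inversion_design()]).
#'
#' @param layout `"neurofeedback"` or `"localizer"`.
#' @param n_trials number of neurofeedback trials (default 8 per run).
#' @param TR repetition time in seconds (default 1).
#' @param start_condition condition of the first trial / attention block.
#' @param block_s block duration in seconds (default 10).
#' @param conditions condition sequence recycled over the localizer's 10
#'   attention blocks; a single value gives a single-condition run, as used
#'   by the sliding-window sweep.
#'
#' @return A [experiment_design()] object.
#' @export
make_design <- function(layout = c("neurofeedback", "localizer"),
                        n_trials = 8, TR = 1, start_condition = c("aL", "aR"),
                        block_s = 10, conditions = NULL) {
  layout <- match.arg(layout)
  start_condition <- match.arg(start_condition)
  conds <- c(start_condition, setdiff(c("aL", "aR"), start_condition))

  if (layout == "localizer") {
    att <- rep_len(conditions %||% conds, 10)
    labels <- character(0)
    for (k in 1:10) labels <- c(labels, "baseline", att[k])
    labels <- c(labels, "baseline")
    blocks <- data.frame(onset = (seq_along(labels) - 1) * block_s,
                         duration = block_s, label = labels)
    n_scans <- round(length(labels) * block_s / TR)
    trials <- NULL
  } else {
    blocks <- NULL
    labels <- character(0)
    trial_rows <- list()
    t0 <- 0
    for (tr in seq_len(n_trials)) {
      cond <- conds[(tr - 1) %% 2 + 1]
      trial_rows[[tr]] <- data.frame(trial = tr,
                                     onset_scan = round(t0 / TR) + 1,
                                     condition = cond)
      lab <- c(rbind(rep("baseline", 4), rep(cond, 4)), "baseline")
      bl <- data.frame(onset = t0 + (seq_along(lab) - 1) * block_s,
                       duration = block_s, label = lab)
      rest <- data.frame(onset = max(bl$onset + bl$duration),
                         duration = 60, label = "rest")
      disp <- data.frame(onset = rest$onset + 60, duration = 5,
                         label = "display")
      blocks <- rbind(blocks, bl, rest, disp)
      t0 <- disp$onset + disp$duration
    }
    n_scans <- round(t0 / TR)
    trials <- do.call(rbind, trial_rows)
  }

  inputs <- cbind(att_L = blocks_to_input(blocks, "aL", n_scans, TR),
                  att_R = blocks_to_input(blocks, "aR", n_scans, TR))
  experiment_design(TR, inputs, blocks, trials = trials, layout = layout)
}

#' Collapse a design to the single attention channel of a candidate model
#'
#' Candidate network models declare one external input (attention); the
#' generated designs carry separate left/right channels. This helper sums
#' them into one `attention` channel and optionally restricts the design to
#' a window of scans.
#'
#' @param design a [experiment_design()].
#' @param scans optional integer vector of scan indices (contiguous window).
#'
#' @return A [experiment_design()] with a single `attention` input.
#' @export
inversion_design <- function(design, scans = NULL) {
  stopifnot(inherits(design, "dcm_design"))
  u <- rowSums(design$inputs)
  if (!is.null(scans)) {
    if (max(scans) > design$n_scans) stop("scan window exceeds the design")
    u <- u[scans]
  }
  experiment_design(design$TR, matrix(u, ncol = 1,
                                      dimnames = list(NULL, "attention")),
                    layout = paste0(design$layout, "-window"))
}
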