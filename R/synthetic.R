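#' Noise specification for synthetic sessions
#'
#' The noise structure the real-time cleaner must cope with: white noise
#' passed through an AR(1) filter, a linear scanner drift, and sparse
#' large-amplitude spikes.
#'
#' @param white_sd innovation standard deviation, in percent of the
#'   baseline signal level (default 0.5).
#' @param ar AR(1) coefficient in [0, 1) (default 0.3).
#' @param drift linear drift slope, percent of baseline per scan
#'   (default 0.01).
#' @param spike_p per-scan, per-region spike probability (default 0.005).
#' @param spike_amp spike amplitude in units of `white_sd` (default 8);
#'   spike signs are random.
#'
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(white_sd = 0.5, ar = 0.3, drift = 0.01,
                       spike_p = 0.005, spike_amp = 8) {
  stopifnot(white_sd >= 0, ar >= 0, ar < 1, spike_p >= 0, spike_p <= 1)
  structure(list(white_sd = white_sd, ar = ar, drift = drift,
                 spike_p = spike_p, spike_amp = spike_amp),
            class = "noise_spec")
}

#' Ground-truth generative parameters of the attention network
#'
#' A two-input-channel truth model: the attention-left channel drives the
#' right SPL and modulates the right top-down SPL-to-VC coupling, and the
#' attention-right channel mirrors this on the left hemisphere. Modulation
#' is applied to the top-down connection only so that the regulated
#' dynamics stay stable (with both directions modulated at these
#' magnitudes the coupled pair would have a positive eigenvalue); the
#' candidate models may still free both directions and will recover a
#' bottom-up modulation near zero.
#'
#' @param a intrinsic reciprocal VC-SPL coupling (Hz, default 0.3).
#' @param b modulatory increase of the top-down coupling (Hz, default 0.4).
#' @param c direct attention input weight (Hz, default 0.3).
#' @param self self-decay rate magnitude (Hz, default 0.5).
#'
#' @return A [connectivity_params()] object with input channels
#'   `att_L`, `att_R`.
#' @export
default_truth <- function(a = 0.3, b = 0.4, c = 0.3, self = 0.5) {
  regions <- dcm_regions()
  n <- length(regions)
  idx <- function(r) match(r, regions)
  A <- diag(-self, n)
  for (h in c("L", "R")) {
    A[idx(paste0("VC_", h)), idx(paste0("SPL_", h))] <- a
    A[idx(paste0("SPL_", h)), idx(paste0("VC_", h))] <- a
  }
  B <- array(0, dim = c(n, n, 2))
  C <- matrix(0, n, 2)
  # att_L acts on the right hemisphere, att_R on the left
  B[idx("VC_R"), idx("SPL_R"), 1] <- b
  C[idx("SPL_R"), 1] <- c
  B[idx("VC_L"), idx("SPL_L"), 2] <- b
  C[idx("SPL_L"), 2] <- c
  connectivity_params(A, B, C, regions, c("att_L", "att_R"))
}

#' Simulate a synthetic session with ground truth
#'
#' Forward-simulates BOLD from a two-channel truth model over a full design
#' (attention-left blocks engage the right hemisphere's input and
#' modulation, attention-right blocks the left's), then adds AR(1)-filtered
#' white noise, linear drift, and Bernoulli spikes. The raw signal is
#' returned on a scanner-like scale: `baseline * (1 + BOLD/100)` plus noise
#' in percent-of-baseline units.
#'
#' @param design a [make_design()] layout.
#' @param truth a [default_truth()]-style [connectivity_params()] with one
#'   input channel per design input.
#' @param noise a [noise_spec()].
#' @param seed RNG seed (required; every stochastic step derives from it).
#' @param hemo hemodynamic constants.
#' @param baseline raw baseline signal level (default 100, so raw units are
#'   percent of baseline).
#' @param dt integration step (s).
#'
#' @return List with `series` (raw [roi_timeseries()]), `clean_percent`
#'   (the noiseless percent-signal time series), and `truth` (a record of
#'   every generative setting, for recovery tests).
#' @export
simulate_session <- function(design, truth = default_truth(),
                             noise = noise_spec(), seed = 1,
                             hemo = hemodynamic_params(), baseline = 100,
                             dt = design$TR / 8) {
  stopifnot(inherits(design, "dcm_design"), inherits(noise, "noise_spec"))
  clean <- simulate_timeseries(truth, design, hemo, dt = dt)
  Tn <- nrow(clean$values)
  n <- ncol(clean$values)
  eps <- with_seed(seed, {
    e <- matrix(rnorm(Tn * n, 0, noise$white_sd), Tn, n)
    if (noise$ar > 0 && Tn > 1) {
      for (i in 2:Tn) e[i, ] <- noise$ar * e[i - 1, ] + e[i, ]
    }
    if (noise$spike_p > 0) {
      hit <- matrix(runif(Tn * n) < noise$spike_p, Tn, n)
      sgn <- matrix(sign(runif(Tn * n) - 0.5), Tn, n)
      e <- e + hit * sgn * noise$spike_amp * noise$white_sd
    }
    e
  })
  drift <- noise$drift * (seq_len(Tn) - 1)
  raw <- baseline * (1 + clean$values / 100) + eps + drift
  list(
    series = roi_timeseries(raw, design$TR, truth$region_labels),
    clean_percent = clean,
    truth = list(params = truth, noise = noise, seed = seed,
                 baseline = baseline, hemo = hemo, dt = dt,
                 layout = design$layout)
  )
}

#' Synthetic 4D volumes with region masks
#'
#' Embeds each region's time course into a small voxel grid: every voxel of
#' a region's mask carries the region time course plus independent voxel
#' noise; background voxels are noise only. Mask-mean extraction therefore
#' recovers the ROI series up to averaged voxel noise. Default mask sizes
#' follow typical localizer-defined ROIs (about 24 voxels for SPL, 16 for
#' VC).
#'
#' @param series a [roi_timeseries()] with the four canonical regions.
#' @param grid 3-vector of volume dimensions (default `c(16, 16, 4)`).
#' @param voxel_sd independent voxel noise standard deviation (signal
#'   units; default 0).
#' @param seed RNG seed for voxel noise.
#'
#' @return List with `volume` (4D array x-y-z-t), `masks` (named list of
#'   binary 3D arrays), `roi_sizes`.
#' @export
simulate_volumes <- function(series, grid = c(16, 16, 4), voxel_sd = 0,
                             seed = 1) {
  stopifnot(inherits(series, "roi_timeseries"))
  n <- ncol(series$values)
  Tn <- nrow(series$values)
  boxes <- list(
    VC_L = list(x = 2:5, y = 2:3, z = 1:2),    # 16 voxels
    VC_R = list(x = 10:13, y = 2:3, z = 1:2),  # 16 voxels
    SPL_L = list(x = 2:5, y = 8:10, z = 3:4),  # 24 voxels
    SPL_R = list(x = 10:13, y = 8:10, z = 3:4) # 24 voxels
  )
  boxes <- boxes[seq_len(n)]
  names(boxes) <- series$region_labels
  for (b in boxes) {
    if (max(b$x) > grid[1] || max(b$y) > grid[2] || max(b$z) > grid[3]) {
      stop("ROI placement exceeds the volume grid")
    }
  }
  masks <- lapply(boxes, function(b) {
    m <- array(0L, dim = grid)
    m[b$x, b$y, b$z] <- 1L
    m
  })
  total <- Reduce(`+`, masks)
  if (any(total > 1)) stop("ROIs must be disjoint")
  vol <- with_seed(seed, {
    v <- array(rnorm(prod(grid) * Tn, 0, voxel_sd), dim = c(grid, Tn))
    if (voxel_sd == 0) v[] <- 0
    v
  })
  for (r in seq_len(n)) {
    m <- masks[[r]] == 1L
    for (t in seq_len(Tn)) {
      slab <- vol[, , , t]
      slab[m] <- slab[m] + series$values[t, r]
      vol[, , , t] <- slab
    }
  }
  list(volume = vol, masks = masks,
       roi_sizes = vapply(masks, sum, numeric(1)))
}
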