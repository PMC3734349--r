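#' Write an ROI time series as TSV with a JSON sidecar
#'
#' The TSV holds a `scan` index column and one column per region, with a
#' header row of region labels; the repetition time and region order are
#' recorded in a sidecar JSON next to the file (same name, `.json`
#' extension).
#'
#' @param series a [roi_timeseries()].
#' @param path output TSV path.
#' @return The TSV path, invisibly.
#' @export
write_roi_timeseries <- function(series, path) {
  stopifnot(inherits(series, "roi_timeseries"))
  df <- data.frame(scan = seq_len(nrow(series$values)), series$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(TR = series$TR, region_labels = as.list(series$region_labels)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.tsv$", ".json", path)

canonical_region_order <- function(labels) {
  canon <- dcm_regions()
  if (setequal(labels, canon)) match(canon, labels) else seq_along(labels)
}

#' Read an ROI time series (TSV or NIfTI + masks)
#'
#' For a `.tsv` path, reads the table written by [write_roi_timeseries()]
#' and its JSON sidecar (the sidecar must provide the TR unless `TR` is
#' given). For a NIfTI 4D volume, extracts the mask-mean time course of
#' each region from the supplied binary masks. When the labels match the
#' canonical network, regions are reordered to (`VC_L`, `VC_R`, `SPL_L`,
#' `SPL_R`).
#'
#' @param path TSV file or NIfTI 4D volume.
#' @param masks for the NIfTI path: named list of binary mask arrays or
#'   NIfTI mask file paths, one per region.
#' @param TR repetition time override (s); otherwise taken from the sidecar
#'   or the NIfTI header.
#' @param region_labels expected region labels; an error names any missing
#'   region column.
#'
#' @return A [roi_timeseries()].
#' @export
read_roi_timeseries <- function(path, masks = NULL, TR = NULL,
                                region_labels = NULL) {
  if (grepl("\\.tsv$", path)) {
    df <- read.delim(path, check.names = FALSE)
    if (!"scan" %in% names(df)) stop("TSV is missing the 'scan' column")
    sc <- sidecar_path(path)
    meta <- if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE)
    else NULL
    if (is.null(TR)) TR <- meta$TR
    if (is.null(TR)) stop("TR absent: no sidecar JSON and no TR argument")
    labels <- region_labels %||% meta$region_labels %||%
      setdiff(names(df), "scan")
    missing <- setdiff(labels, names(df))
    if (length(missing) > 0) {
      stop("missing region column(s): ", paste(missing, collapse = ", "))
    }
    vals <- as.matrix(df[, labels, drop = FALSE])
    if (!is.numeric(vals)) stop("non-numeric values in ROI columns")
  } else {
    if (is.null(masks)) stop("NIfTI input needs region masks")
    img <- RNifti::readNifti(path)
    if (is.null(TR)) TR <- RNifti::pixdim(img)[4]
    if (is.null(TR) || !is.finite(TR) || TR <= 0) {
      stop("TR absent from NIfTI header; pass TR explicitly")
    }
    arr <- as.array(img)
    Tn <- dim(arr)[4]
    vals <- vapply(masks, function(m) {
      if (is.character(m)) m <- as.array(RNifti::readNifti(m))
      sel <- m == 1
      vapply(seq_len(Tn), function(t) mean(arr[, , , t][sel]), numeric(1))
    }, numeric(Tn))
    labels <- names(masks) %||% paste0("R", seq_along(masks))
    colnames(vals) <- labels
  }
  ord <- canonical_region_order(labels)
  roi_timeseries(vals[, ord, drop = FALSE], TR, labels[ord])
}

#' Write NIfTI volume and masks from a synthetic volume set
#'
#' @param vols output of [simulate_volumes()].
#' @param dir output directory.
#' @param TR repetition time stored in the 4D header (s).
#' @param prefix file name prefix.
#' @return Named list of written paths (`volume` plus one per mask).
#' @export
write_volumes_nifti <- function(vols, dir, TR = 1, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vp <- file.path(dir, paste0(prefix, "_bold.nii.gz"))
  img <- RNifti::asNifti(vols$volume)
  RNifti::pixdim(img) <- c(1, 1, 1, TR)
  RNifti::writeNifti(img, vp)
  mp <- lapply(names(vols$masks), function(nm) {
    p <- file.path(dir, paste0(prefix, "_mask_", nm, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(vols$masks[[nm]] + 0), p)
    p
  })
  names(mp) <- names(vols$masks)
  c(list(volume = vp), mp)
}

#' Write a session log as JSON lines
#'
#' One feedback event per line; rereading reproduces the events exactly.
#'
#' @param log a `session_log` from [run_session()] (or list of
#'   `feedback_event`s).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_session_log <- function(log, path) {
  lines <- vapply(log, function(ev) {
    jsonlite::toJSON(unclass(ev), auto_unbox = TRUE, digits = NA,
                     null = "null", na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a session log written by [write_session_log()]
#'
#' @param path JSON-lines file.
#' @return A `session_log` (list of `feedback_event`s).
#' @export
read_session_log <- function(path) {
  lines <- readLines(path)
  events <- lapply(lines, function(l) {
    ev <- jsonlite::fromJSON(l)
    ev$n_iterations <- as.integer(unlist(ev$n_iterations))
    ev$converged <- as.logical(unlist(ev$converged))
    structure(ev, class = "feedback_event")
  })
  reward <- if (length(events) > 0)
    events[[length(events)]]$reward_total else 0
  structure(events, class = "session_log", reward_total = reward,
            n_trials = length(events))
}

config_defaults <- function() {
  list(
    window = list(length_scans = 90, step_scans = 20),
    inversion = list(max_iter = 44, tol = 0.05, dt_fraction = 8),
    cleaner = list(half_life = 50, spike_sd = 3, spike_window = 50,
                   spike_warmup = 10, ema_weight = 0.6),
    session = list(n_trials = 8, TR = 1, start_condition = "aL"),
    noise = list(white_sd = 0.5, ar = 0.3, drift = 0.01, spike_p = 0.005,
                 spike_amp = 8),
    seed = 1
  )
}

#' Load (or default) a session configuration
#'
#' Reads a YAML/JSON configuration, validates it against the documented
#' schema, rejects unknown keys, and fills in the defaults: 44-iteration
#' inversion cap, 90-scan window with step 20, the cleaner constants, and
#' the synthetic-noise defaults. `path = NULL` (or an empty file) yields
#' the full default configuration.
#'
#' @param path YAML or JSON file, or `NULL` for defaults.
#' @return A validated configuration list of class `session_config`.
#' @export
load_config <- function(path = NULL) {
  defaults <- config_defaults()
  user <- if (is.null(path)) list() else {
    x <- if (grepl("\\.json$", path)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else yaml::read_yaml(path)
    if (is.null(x)) list() else x
  }
  merged <- merge_config(defaults, user, path = character(0))
  validate_config(merged)
  structure(merged, class = "session_config")
}

merge_config <- function(defaults, user, path) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ",
         paste(c(path, unknown[1]), collapse = "."),
         if (length(unknown) > 1) paste0(" (and ", length(unknown) - 1,
                                         " more)") else "")
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]])) {
      if (!is.list(user[[k]])) {
        stop("configuration field ", paste(c(path, k), collapse = "."),
             " must be a mapping")
      }
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], c(path, k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  check_pos <- function(x, field, integer = FALSE) {
    if (!is.numeric(x) || length(x) != 1 || x <= 0 ||
        (integer && x != round(x))) {
      stop("invalid value for ", field, ": must be a positive ",
           if (integer) "integer" else "number")
    }
  }
  check_pos(cfg$window$length_scans, "window.length_scans", integer = TRUE)
  check_pos(cfg$window$step_scans, "window.step_scans", integer = TRUE)
  if (cfg$window$length_scans < 30) stop("window.length_scans must be >= 30")
  if (!is.numeric(cfg$inversion$max_iter) || cfg$inversion$max_iter < 0 ||
      cfg$inversion$max_iter != round(cfg$inversion$max_iter)) {
    stop("invalid value for inversion.max_iter: must be a non-negative integer")
  }
  check_pos(cfg$inversion$tol, "inversion.tol")
  check_pos(cfg$inversion$dt_fraction, "inversion.dt_fraction")
  check_pos(cfg$cleaner$half_life, "cleaner.half_life")
  check_pos(cfg$session$TR, "session.TR")
  check_pos(cfg$session$n_trials, "session.n_trials", integer = TRUE)
  invisible(TRUE)
}

#' Save a configuration as YAML
#'
#' @param cfg a configuration list from [load_config()].
#' @param path output YAML path.
#' @return The path, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
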