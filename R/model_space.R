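#' Candidate network architectures
#'
#' All candidate models share the same four regions in canonical order
#' (`VC_L`, `VC_R`, `SPL_L`, `SPL_R`) and the same intrinsic structure:
#' reciprocal VC-SPL coupling within each hemisphere and no interhemispheric
#' connections. Models differ in where the attention input enters (SPL, VC,
#' or both) and which VC-SPL connections it modulates (top-down = SPL to VC,
#' bottom-up = VC to SPL, both, or none). `hemisphere` states which
#' hemisphere carries the input and modulation; covert attention acts on the
#' hemisphere contralateral to the attended visual field, so the
#' attention-left model is right-lateralized.
#'
#' @param name model name.
#' @param input_target where the attention input enters: `"SPL"`, `"VC"`,
#'   or `"both"`.
#' @param modulation which connections attention modulates: `"both"`
#'   (top-down and bottom-up), `"td"`, `"bu"`, or `"none"`.
#' @param hemisphere lateralization of input and modulation, `"R"` or `"L"`.
#' @param extra_modulation optional list of `c(from, to)` region-label pairs
#'   of additional modulated edges; checked against the structure by
#'   [validate_model()].
#'
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name, input_target = c("SPL", "VC", "both"),
                       modulation = c("both", "td", "bu", "none"),
                       hemisphere = c("R", "L"), extra_modulation = NULL) {
  structure(
    list(name = name, input_target = match.arg(input_target),
         modulation = match.arg(modulation),
         hemisphere = match.arg(hemisphere),
         extra_modulation = extra_modulation),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model", x$name, "- input:", x$input_target,
      "| modulation:", x$modulation, "| hemisphere:", x$hemisphere, "\n")
  invisible(x)
}

dcm_regions <- function() c("VC_L", "VC_R", "SPL_L", "SPL_R")

#' The neurofeedback model pair
#'
#' The attention-left model `M_aL` places the direct attention input on the
#' right SPL and lets attention modulate the reciprocal right VC-SPL
#' coupling; `M_aR` is its mirror image on the left hemisphere. The pair
#' shares an identical intrinsic structure.
#'
#' @return Named list `list(aL = , aR = )` of [model_spec()] objects.
#' @export
attention_pair <- function() {
  list(aL = model_spec("M_aL", "SPL", "both", "R"),
       aR = model_spec("M_aR", "SPL", "both", "L"))
}

#' The twelve-model comparison family
#'
#' Three input families (attention into SPL, into VC, or into both) crossed
#' with four modulation patterns (top-down and bottom-up, top-down only,
#' bottom-up only, none). Model 1 -- SPL input with both modulations -- is
#' the architecture used for the neurofeedback signal; models 5-8 receive
#' direct input into VC, models 9-12 into both.
#'
#' @param hemisphere lateralization of all family members (default `"R"`,
#'   i.e. the attention-left variants).
#'
#' @return List of 12 [model_spec()] objects named `model_01` ... `model_12`.
#' @export
model_family <- function(hemisphere = c("R", "L")) {
  hemisphere <- match.arg(hemisphere)
  targets <- c("SPL", "VC", "both")
  mods <- c("both", "td", "bu", "none")
  out <- vector("list", 12)
  for (i in seq_len(3)) {
    for (j in seq_len(4)) {
      idx <- (i - 1) * 4 + j
      out[[idx]] <- model_spec(sprintf("model_%02d", idx), targets[i],
                               mods[j], hemisphere)
    }
  }
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Swap the hemispheres of a model specification
#'
#' An involution: applied to the attention-left model it yields the
#' attention-right model and vice versa.
#'
#' @param spec a [model_spec()].
#' @return The mirrored [model_spec()].
#' @export
swap_hemispheres <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  spec$hemisphere <- if (spec$hemisphere == "R") "L" else "R"
  flip <- function(lbl) {
    ifelse(grepl("_L$", lbl), sub("_L$", "_R", lbl), sub("_R$", "_L", lbl))
  }
  if (!is.null(spec$extra_modulation)) {
    spec$extra_modulation <- lapply(spec$extra_modulation, flip)
  }
  spec
}

#' Validate a model specification into a free-parameter skeleton
#'
#' Emits the logical masks of free A/B/C entries implied by the
#' specification and rejects modulation placed on structurally absent
#' (e.g. interhemispheric) edges.
#'
#' @param spec a [model_spec()].
#'
#' @return An object of class `dcm_skeleton` with fields `regions`,
#'   `input_labels`, `A_mask` (free off-diagonal couplings), `self`
#'   (regions with an estimated self-decay log-scale), `B_mask`, `C_mask`,
#'   and `theta_names` (canonical free-parameter ordering).
#' @export
validate_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  regions <- dcm_regions()
  n <- length(regions)
  idx <- function(r) match(r, regions)
  A_mask <- matrix(FALSE, n, n, dimnames = list(regions, regions))
  for (h in c("L", "R")) {
    vc <- paste0("VC_", h); spl <- paste0("SPL_", h)
    A_mask[idx(vc), idx(spl)] <- TRUE  # top-down SPL -> VC
    A_mask[idx(spl), idx(vc)] <- TRUE  # bottom-up VC -> SPL
  }
  h <- spec$hemisphere
  vc <- paste0("VC_", h); spl <- paste0("SPL_", h)
  B_mask <- array(FALSE, dim = c(n, n, 1),
                  dimnames = list(regions, regions, "attention"))
  if (spec$modulation %in% c("both", "td")) B_mask[idx(vc), idx(spl), 1] <- TRUE
  if (spec$modulation %in% c("both", "bu")) B_mask[idx(spl), idx(vc), 1] <- TRUE
  for (edge in spec$extra_modulation) {
    i <- idx(edge[2]); j <- idx(edge[1])
    if (anyNA(c(i, j))) stop("unknown region in extra_modulation")
    if (!A_mask[i, j]) {
      stop("cannot modulate structurally absent edge ", edge[1], " -> ",
           edge[2])
    }
    B_mask[i, j, 1] <- TRUE
  }
  C_mask <- matrix(FALSE, n, 1, dimnames = list(regions, "attention"))
  if (spec$input_target %in% c("SPL", "both")) C_mask[idx(spl), 1] <- TRUE
  if (spec$input_target %in% c("VC", "both")) C_mask[idx(vc), 1] <- TRUE

  theta_names <- c(
    paste0("self:", regions),
    paste0("A:", regions[col(A_mask)[A_mask]], "->", regions[row(A_mask)[A_mask]]),
    if (any(B_mask)) {
      paste0("B.attention:", regions[col(B_mask[, , 1])[B_mask[, , 1]]], "->",
             regions[row(B_mask[, , 1])[B_mask[, , 1]]])
    },
    if (any(C_mask)) paste0("C.attention:", regions[which(C_mask[, 1])])
  )
  structure(
    list(spec = spec, regions = regions, n_regions = n,
         input_labels = "attention", A_mask = A_mask, self = regions,
         B_mask = B_mask, C_mask = C_mask, theta_names = theta_names),
    class = "dcm_skeleton"
  )
}

#' Map a free-parameter vector onto connectivity matrices
#'
#' Self-connections are parameterized as \eqn{-0.5 \exp(a_{ii})} Hz so the
#' estimated intrinsic dynamics always decay; off-diagonal couplings enter
#' untransformed.
#'
#' @param skel a `dcm_skeleton` from [validate_model()].
#' @param theta numeric vector ordered as `skel$theta_names` (defaults to
#'   the prior mean, i.e. all zeros).
#'
#' @return A [connectivity_params()] object.
#' @export
skeleton_to_params <- function(skel, theta = NULL) {
  stopifnot(inherits(skel, "dcm_skeleton"))
  p <- length(skel$theta_names)
  if (is.null(theta)) theta <- numeric(p)
  if (length(theta) != p) {
    stop("theta has length ", length(theta), ", expected ", p)
  }
  names(theta) <- skel$theta_names
  n <- skel$n_regions
  A <- matrix(0, n, n)
  diag(A) <- -0.5 * exp(theta[seq_len(n)])
  A[skel$A_mask] <- theta[grep("^A:", skel$theta_names)]
  B <- array(0, dim = dim(skel$B_mask))
  B[skel$B_mask] <- theta[grep("^B\\.", skel$theta_names)]
  C <- matrix(0, n, 1)
  C[skel$C_mask] <- theta[grep("^C\\.", skel$theta_names)]
  connectivity_params(A, B, C, skel$regions, skel$input_labels)
}

#' Serialize / restore a model specification as YAML
#'
#' @param spec a [model_spec()].
#' @param path file path; for [read_model_spec()] a YAML file written by
#'   [write_model_spec()].
#' @return `read_model_spec` returns the restored [model_spec()].
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "model_spec"))
  yaml::write_yaml(spec[c("name", "input_target", "modulation", "hemisphere")],
                   path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  x <- yaml::read_yaml(path)
  model_spec(x$name, x$input_target, x$modulation, x$hemisphere)
}
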