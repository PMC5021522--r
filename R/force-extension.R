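# Force-extension analysis: molecular extension from the differential
# displacement of the target (piezo) and probe (bead) channels.

#' Force-extension curve of the bonded portion of a cycle
#'
#' Molecular extension is the differential displacement between the target
#' (piezo) and the probe bead: `extension = (target - target0) -
#' (probe - probe0)`, zeroed at the tensile-force onset. Returned over the
#' bonded interval (tensile onset to dissociation / rupture collapse).
#'
#' @inheritParams segment_trace
#' @return data frame with `extension_nm`, `force_pN`, `time_s`.
#' @export
force_extension_curve <- function(trace, ...) {
  if (!all(c("probe_nm", "target_nm") %in% names(trace)))
    stop("trace lacks probe/target position channels", call. = FALSE)
  seg <- segment_trace(trace, ...)
  if (seg$outcome == "no_bond")
    stop("no bond in this cycle: force-extension undefined", call. = FALSE)
  margin <- max(1L, round(0.006 * seg$fs))   # clear of the dissociation edge
  i0 <- seg$i_zero
  i1 <- if (seg$outcome == "lifetime") seg$i_diss - margin
        else seg$i_ramp_end - margin
  idx <- i0:i1
  # zero references averaged over a short pre-tensile window so that probe
  # tracking noise in a single sample does not offset the whole curve
  ref <- max(1L, i0 - 9L):i0
  data.frame(
    extension_nm = (trace$target_nm[idx] - mean(trace$target_nm[ref])) -
      (trace$probe_nm[idx] - mean(trace$probe_nm[ref])),
    force_pN = trace$force_pN[idx],
    time_s = trace$time_s[idx])
}

#' Unfolding length from a force-extension curve
#'
#' Two estimators of the length released by a single unfolding event visible
#' in a force-extension curve:
#' * `"jump"`: the extension gap between the pre- and post-unfolding
#'   branches, evaluated at the highest force the two branches share
#'   (branch extensions obtained by local interpolation);
#' * `"delta_Lc"`: the difference of WLC contour lengths fitted separately
#'   to the pre- and post-unfolding branches.
#'
#' The two give comparable results when the branches are sampled at forces
#' where the chain is substantially extended. A curve with no resolvable
#' jump returns 0 for both methods.
#'
#' @param curve data frame from [force_extension_curve()] (columns
#'   `extension_nm`, `force_pN`).
#' @param method `"jump"` or `"delta_Lc"`.
#' @param p persistence length (nm) for the WLC fits / branch model.
#' @param kBT thermal energy (pN nm).
#' @param min_jump smallest extension step (nm) accepted as an unfolding
#'   jump (default 5).
#' @return length (nm).
#' @export
ramped_unfolding_length <- function(curve, method = c("jump", "delta_Lc"),
                                    p = 0.5, kBT = 4.28, min_jump = 5) {
  method <- match.arg(method)
  x <- curve$extension_nm; f <- curve$force_pN
  n <- length(x)
  stopifnot(n >= 8)
  xs <- stats::runmed(x, k = min(5L, n - (1 - n %% 2)))  # despike before locating
  dx <- diff(xs)
  i <- which.max(dx)
  # a genuine jump must stand clear of both the floor and the curve's own
  # sample-to-sample progression
  step_floor <- stats::median(dx) + 5 * stats::mad(dx)
  if (dx[i] < max(min_jump, step_floor) || i < 2L || i > n - 2L) return(0)
  pre <- seq_len(i); post <- (i + 1L):n
  pre <- pre[f[pre] > 0.5]; post <- post[f[post] > 0.5]
  if (method == "delta_Lc" && (length(pre) < 4 || length(post) < 4))
    stop("too few points on a branch for WLC fitting", call. = FALSE)
  if (length(pre) < 2 || length(post) < 2)
    stop("too few points on a branch around the unfolding jump", call. = FALSE)
  if (method == "jump") {
    f_eval <- min(max(f[pre]), max(f[post]))
    branch_ext <- function(idx) {
      # median extension of the points nearest in force to the shared level
      near <- idx[order(abs(f[idx] - f_eval))]
      stats::median(x[utils::head(near, 7L)])
    }
    branch_ext(post) - branch_ext(pre)
  } else {
    fit1 <- fit_contour_length(x[pre], f[pre], p = p, kBT = kBT)
    fit2 <- fit_contour_length(x[post], f[post], p = p, kBT = kBT)
    fit2$Lc - fit1$Lc
  }
}
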