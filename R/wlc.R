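#' Worm-like-chain (Marko-Siggia) force at a given extension
#'
#' Entropic elasticity of a polymer chain in the Marko-Siggia interpolation:
#' \deqn{F(x) = (k_BT/p)\,[1/(4(1-x/L_c)^2) - 1/4 + x/L_c]}
#' with contour length \eqn{L_c} and persistence length \eqn{p}. This is the
#' standard model for force-extension of an unfolded polypeptide, used here to
#' relate unfolding force to the length of polypeptide released by a domain
#' unfolding event.
#'
#' @param x extension (nm); must satisfy `0 <= x < Lc`.
#' @param Lc contour length (nm).
#' @param p persistence length (nm). Default 0.5 nm, the usual value for an
#'   unstructured polypeptide.
#' @param kBT thermal energy (pN nm). Default 4.28 pN nm (310 K, i.e. 37 C).
#' @return force (pN), same length as `x`. Strictly increasing in `x`.
#' @examples
#' wlc_force(13, Lc = 26, p = 0.5)   # 10.70 pN
#' @export
wlc_force <- function(x, Lc, p = 0.5, kBT = 4.28) {
  stopifnot(is.numeric(x), length(Lc) == 1L, Lc > 0, p > 0, p < Lc, kBT > 0)
  if (any(x < 0) || any(x >= Lc))
    stop("extension must satisfy 0 <= x < Lc", call. = FALSE)
  s <- x / Lc
  (kBT / p) * (1 / (4 * (1 - s)^2) - 0.25 + s)
}

#' Worm-like-chain extension at a given force
#'
#' Numerical inverse of [wlc_force()]: the extension at which the Marko-Siggia
#' chain exerts force `f`. Solved by root bracketing; the composition
#' `wlc_force(wlc_extension(f))` recovers `f` to high relative accuracy.
#'
#' @param f force (pN), `>= 0`.
#' @inheritParams wlc_force
#' @return extension (nm) in `[0, Lc)`.
#' @export
wlc_extension <- function(f, Lc, p = 0.5, kBT = 4.28) {
  stopifnot(is.numeric(f), all(f >= 0))
  vapply(f, function(fi) {
    if (fi == 0) return(0)
    stats::uniroot(function(x) wlc_force(x, Lc, p, kBT) - fi,
                   lower = 0, upper = Lc * (1 - 1e-12),
                   tol = .Machine$double.eps^0.75)$root
  }, numeric(1))
}

#' Fit a WLC contour length to unfolding force vs length data
#'
#' Least-squares fit of the Marko-Siggia model to averaged (length, force)
#' points, as used to validate domain identity of unfolding-length
#' subpopulations: the released-polypeptide length grows with the force at
#' which unfolding occurred, following the WLC of the unfolded domain.
#'
#' The persistence length may be held fixed (the usual mode; the default
#' 0.5 nm polypeptide value) or co-estimated.
#'
#' @param lengths unfolding lengths (nm); the extension coordinate.
#' @param forces unfolding forces (pN); must be positive.
#' @param p persistence length (nm) when held fixed.
#' @param fit_p logical; if `TRUE`, estimate `p` jointly with `Lc`.
#' @param kBT thermal energy (pN nm).
#' @param Lc_start optional starting value for `Lc` (defaults to
#'   `1.05 * max(lengths)`).
#' @return an object of class `"wlc_fit"`: a list with elements `Lc`, `Lc_se`,
#'   `p`, `p_se` (NA when `p` fixed), `kBT`, `residuals`, `fitted`, and the
#'   underlying `nls` fit.
#' @seealso [wlc_force()], [sort_unfolding_mechanics()]
#' @export
fit_contour_length <- function(lengths, forces, p = 0.5, fit_p = FALSE,
                               kBT = 4.28, Lc_start = NULL) {
  stopifnot(length(lengths) == length(forces))
  if (length(lengths) < 4L) stop("need at least 4 points", call. = FALSE)
  if (any(forces <= 0)) stop("forces must be positive", call. = FALSE)
  if (any(lengths <= 0)) stop("lengths must be positive", call. = FALSE)
  if (is.null(Lc_start)) Lc_start <- 1.05 * max(lengths)
  d <- data.frame(x = lengths, f = forces)
  ms <- function(x, Lc, p) {
    s <- pmin(x / Lc, 1 - 1e-9)
    (kBT / p) * (1 / (4 * (1 - s)^2) - 0.25 + s)
  }
  fit <- if (fit_p) {
    minpack.lm::nlsLM(f ~ ms(x, Lc, p), data = d,
                      start = list(Lc = Lc_start, p = p),
                      lower = c(max(d$x) * (1 + 1e-6), 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    minpack.lm::nlsLM(f ~ ms(x, Lc, p), data = d,
                      start = list(Lc = Lc_start),
                      lower = max(d$x) * (1 + 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  if (!fit$convInfo$isConv && fit$convInfo$stopCode %in% c(0L, 9L))
    stop("WLC fit did not converge: ", fit$convInfo$stopMessage, call. = FALSE)
  cf <- summary(fit)$coefficients
  out <- list(
    Lc = unname(cf["Lc", "Estimate"]),
    Lc_se = unname(cf["Lc", "Std. Error"]),
    p = if (fit_p) unname(cf["p", "Estimate"]) else p,
    p_se = if (fit_p) unname(cf["p", "Std. Error"]) else NA_real_,
    kBT = kBT,
    fitted = stats::fitted(fit),
    residuals = stats::residuals(fit),
    fit = fit
  )
  class(out) <- "wlc_fit"
  out
}

#' @export
print.wlc_fit <- function(x, ...) {
  cat(sprintf("WLC fit: Lc = %.2f +/- %.2f nm; p = %.3f nm%s (kBT = %.2f pN nm)\n",
              x$Lc, x$Lc_se, x$p,
              if (is.na(x$p_se)) " (fixed)" else sprintf(" +/- %.3f", x$p_se),
              x$kBT))
  invisible(x)
}

#' Bin unfolding events into averaged force vs length points
#'
#' Sorts single-event (length, force) pairs into length bins and returns the
#' per-bin mean and s.e.m. of both coordinates -- the averaged point sets that
#' WLC curves are fit to. Bins holding fewer than `min_count` events are
#' dropped (s.e.m. of a single event is undefined and flagged).
#'
#' @param lengths,forces per-event unfolding lengths (nm) and forces (pN).
#' @param bins number of equal-occupancy bins, or a numeric vector of bin
#'   breaks (nm).
#' @param min_count minimum events per retained bin (default 2).
#' @return data frame with columns `length`, `length_sem`, `force`,
#'   `force_sem`, `n`; attribute `dropped` holds the number of discarded bins.
#' @export
sort_unfolding_mechanics <- function(lengths, forces, bins = 8, min_count = 2) {
  stopifnot(length(lengths) == length(forces), length(lengths) >= 1)
  breaks <- if (length(bins) == 1L) {
    stats::quantile(lengths, probs = seq(0, 1, length.out = bins + 1),
                    names = FALSE)
  } else sort(bins)
  breaks <- unique(breaks)
  if (length(breaks) < 2)
    breaks <- c(breaks[1] - 0.5, breaks[1] + 0.5)   # degenerate: one bin
  idx <- cut(lengths, breaks = breaks, include.lowest = TRUE)
  sem <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  agg <- lapply(split(seq_along(lengths), idx), function(i) {
    data.frame(length = mean(lengths[i]), length_sem = sem(lengths[i]),
               force = mean(forces[i]), force_sem = sem(forces[i]),
               n = length(i))
  })
  out <- do.call(rbind, agg[vapply(agg, nrow, 1L) > 0])
  keep <- !is.na(out$n) & out$n >= min_count
  dropped <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}
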