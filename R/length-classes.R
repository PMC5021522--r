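#' Kernel-density peaks of an unfolding-length ensemble
#'
#' Estimates the density of unfolding lengths with a Gaussian or Epanechnikov
#' kernel and data-based (Sheather-Jones plug-in) bandwidth, and returns the
#' local maxima. Multimodality of the density is what separates the
#' mechanosensitive-domain, leucine-rich-repeat-domain and combined unfolding
#' subpopulations.
#'
#' @param lengths unfolding lengths (nm), `n >= 10`.
#' @param kernel `"gaussian"` or `"epanechnikov"`.
#' @param bandwidth `"auto"` (Sheather-Jones) or a numeric bandwidth (nm).
#' @param n_grid density grid size (default 512).
#' @param min_prominence modes rising less than this fraction of the global
#'   mode above their separating valley are merged into their taller
#'   neighbour (default 0.05); guards against bandwidth-induced ripples.
#' @return list with `peaks` (locations, nm), `n_peaks`, `valleys` (locations
#'   of the interior minima separating retained peaks), `density` (the
#'   `stats::density` object).
#' @export
kde_peaks <- function(lengths, kernel = c("gaussian", "epanechnikov"),
                      bandwidth = "auto", n_grid = 512,
                      min_prominence = 0.05) {
  kernel <- match.arg(kernel)
  if (length(lengths) < 10L) stop("need at least 10 lengths", call. = FALSE)
  if (stats::sd(lengths) == 0) {
    warning("degenerate (all-equal) data: single trivial peak", call. = FALSE)
    return(list(peaks = lengths[1], n_peaks = 1L, valleys = numeric(0),
                density = NULL))
  }
  bw <- if (identical(bandwidth, "auto")) stats::bw.SJ(lengths) else bandwidth
  d <- stats::density(lengths, bw = bw, kernel = kernel, n = n_grid)
  y <- d$y
  im <- which(diff(sign(diff(y))) == -2) + 1L        # strict local maxima
  iv <- which(diff(sign(diff(y))) == 2) + 1L
  im <- im[y[im] > 0.01 * max(y)]
  thr <- min_prominence * max(y)
  # merge low-prominence modes: drop the peak whose rise above the valley
  # toward its taller neighbour is smallest, until all retained peaks are
  # prominent
  repeat {
    if (length(im) <= 1L) break
    # prominence relative to the higher separating valley
    prom <- vapply(seq_along(im), function(j) {
      vl <- if (j == 1L) 0 else min(y[im[j - 1L]:im[j]])
      vr <- if (j == length(im)) 0 else min(y[im[j]:im[j + 1L]])
      y[im[j]] - max(vl, vr)
    }, numeric(1))
    worst <- which.min(prom)
    if (prom[worst] >= thr) break
    im <- im[-worst]
  }
  iv_keep <- if (length(im) > 1L)
    vapply(seq_len(length(im) - 1L), function(j) {
      seg <- im[j]:im[j + 1L]
      seg[which.min(y[seg])]
    }, integer(1))
  else integer(0)
  list(peaks = d$x[im], n_peaks = length(im), valleys = d$x[iv_keep],
       density = d)
}

#' Freedman-Diaconis histogram bin width
#'
#' \eqn{2\,\mathrm{IQR}\, n^{-1/3}}. The result depends on the quartile
#' convention; the default is R's type-7 (linear interpolation) quantile,
#' configurable because discrete conventions (e.g. type 2) differ on small
#' samples.
#'
#' @param lengths numeric data, `n >= 2`.
#' @param qtype quantile algorithm type passed to [stats::quantile()]
#'   (default 7).
#' @return bin width in the units of `lengths`.
#' @export
fd_bin_width <- function(lengths, qtype = 7) {
  n <- length(lengths)
  if (n < 2L) stop("need at least 2 values", call. = FALSE)
  iqr <- diff(stats::quantile(lengths, c(0.25, 0.75), type = qtype, names = FALSE))
  if (iqr == 0)
    stop("zero interquartile range: bin width degenerate, consider kde_peaks()",
         call. = FALSE)
  2 * iqr * n^(-1 / 3)
}

#' Assign an unfolding event to a receptor domain
#'
#' Decision rule mapping an unfolding event to the domain(s) that unfolded.
#' Clamped-phase events are always MSD (clamped forces unfold only the
#' mechanosensitive domain). Ramped events are classified by length:
#' below `boundaries[1]` MSD, between the boundaries LRRD, above
#' `boundaries[2]` both domains in one unresolved step. Default boundaries
#' 28 and 56 nm; [calibrate_boundaries()] derives them from the KDE valleys
#' of a calibration ensemble.
#'
#' @param phase `"ramped"` or `"clamped"` (vectorised with `length`).
#' @param length unfolding length (nm), positive.
#' @param boundaries numeric length-2 vector `(b1, b2)` in nm.
#' @return character vector: `"MSD"`, `"LRRD"` or `"BOTH"`.
#' @export
assign_domain <- function(phase, length, boundaries = c(28, 56)) {
  stopifnot(length(boundaries) == 2L, boundaries[1] < boundaries[2])
  if (any(length <= 0)) stop("unfolding length must be positive", call. = FALSE)
  phase <- match.arg(phase, c("ramped", "clamped"), several.ok = TRUE)
  phase <- rep_len(phase, base::length(length))
  out <- ifelse(phase == "clamped", "MSD",
                ifelse(length < boundaries[1], "MSD",
                       ifelse(length <= boundaries[2], "LRRD", "BOTH")))
  out
}

#' Domain boundaries from the valleys of a calibration ensemble
#'
#' Runs [kde_peaks()] on a ramped unfolding-length ensemble and returns the
#' two interior valley locations separating three modes, falling back to the
#' fixed defaults when the density is not trimodal.
#'
#' @inheritParams kde_peaks
#' @param fallback boundaries used when three modes are not found.
#' @return numeric length-2 boundaries (nm).
#' @export
calibrate_boundaries <- function(lengths, fallback = c(28, 56), ...) {
  k <- kde_peaks(lengths, ...)
  if (k$n_peaks >= 3 && length(k$valleys) >= 2) {
    # the two valleys flanking the central (LRRD) mode
    mid <- sort(k$peaks)[2]
    lo <- max(k$valleys[k$valleys < mid])
    hi <- min(k$valleys[k$valleys > mid])
    if (is.finite(lo) && is.finite(hi)) return(c(lo, hi))
  }
  fallback
}

#' Per-condition summary of unfolding frequency and mechanics
#'
#' Aggregates labeled unfolding events over interrogated cycles: per domain
#' (and optional extra grouping such as clamp force), the unfolding frequency
#' (events per cycle), mean unfolding force and mean length, each with s.e.m.
#'
#' @param events data frame with at least `domain`, `length`, `force` (force
#'   may be `NA` for clamped events); zero-row input allowed.
#' @param n_cycles number of interrogated cycles (denominator of frequency).
#' @param by optional name of an extra grouping column in `events`.
#' @return data frame with `domain`, optional group, `n_events`, `frequency`,
#'   `frequency_se` (multinomial/binomial), `mean_force`, `force_sem`,
#'   `mean_length`, `length_sem`.
#' @export
condition_summary <- function(events, n_cycles, by = NULL) {
  stopifnot(n_cycles >= 1)
  domains <- c("MSD", "LRRD", "BOTH")
  groups <- if (is.null(by)) list(seq_len(nrow(events)))
            else split(seq_len(nrow(events)), events[[by]])
  res <- lapply(names(groups) %||% "all", function(g) {
    idx <- if (is.null(by)) groups[[1]] else groups[[g]]
    ev <- events[idx, , drop = FALSE]
    do.call(rbind, lapply(domains, function(d) {
      sel <- ev$domain == d
      n <- sum(sel)
      p <- n / n_cycles
      data.frame(group = g, domain = d, n_events = n,
                 frequency = p, frequency_se = sqrt(p * (1 - p) / n_cycles),
                 mean_force = if (n) mean(ev$force[sel], na.rm = TRUE) else NA_real_,
                 force_sem = sem(ev$force[sel]),
                 mean_length = if (n) mean(ev$length[sel]) else NA_real_,
                 length_sem = sem(ev$length[sel]))
    }))
  })
  out <- do.call(rbind, res)
  if (is.null(by)) out$group <- NULL
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
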