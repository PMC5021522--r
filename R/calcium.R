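# Calcium-trace normalization, typing, pre-onset lifetime statistics,
# correlation and ROC threshold analysis.

#' Normalize a calcium intensity trace and locate its onset and peak
#'
#' Divides the raw intensity by the mean of an initial baseline window
#' (making the baseline 1), computes the maximum normalized increase
#' `dI_max = max(I)/I0 - 1`, and locates the onset as the first time the
#' normalized intensity exceeds baseline + `onset_k` baseline noise s.d.
#' for at least `onset_frames` consecutive frames.
#'
#' @param time,intensity raw trace (s; arbitrary intensity units, positive
#'   baseline). At least 10 samples.
#' @param baseline_frames frames used for the baseline (default 10).
#' @param onset_k onset criterion in baseline noise s.d. (default 5).
#' @param onset_frames sustained frames required (default 3).
#' @return object of class `"calcium_trace"`: list with `time`, `intensity`
#'   (normalized), `dI_max`, `onset_time` (NA if never crossed),
#'   `peak_time`.
#' @export
normalize_and_peak <- function(time, intensity, baseline_frames = 10,
                               onset_k = 5, onset_frames = 3) {
  stopifnot(length(time) == length(intensity), length(time) >= 10)
  nb <- min(baseline_frames, length(intensity))
  base <- mean(intensity[seq_len(nb)])
  if (!is.finite(base) || base <= 0)
    stop("non-positive baseline", call. = FALSE)
  I <- intensity / base
  noise <- stats::sd(I[seq_len(nb)])
  thr <- 1 + max(onset_k * noise, 1e-6)
  above <- I > thr
  io <- first_run(above, onset_frames)
  ipk <- which.max(I)
  structure(list(time = time, intensity = I,
                 dI_max = max(I) - 1,
                 onset_time = if (is.na(io)) NA_real_ else time[io],
                 peak_time = time[ipk]),
            class = "calcium_trace")
}

#' Classify a calcium trace as null, alpha or beta type
#'
#' Null responses are basal traces with `dI_max < null_threshold` (0.05).
#' Among responders, alpha-type responses are spike-shaped -- fast rise
#' (onset to peak shorter than `rise_max`) and quick decay (post-peak
#' half-decay time shorter than `decay_half_max`) -- and beta-type responses
#' rise to an intermediate level with a gradual decay. When the shape
#' cannot be evaluated (no onset, or the trace never decays within the
#' record and the peak is at the end), the amplitude boundary
#' `amp_boundary` (0.5) decides.
#'
#' @param ct a `"calcium_trace"` from [normalize_and_peak()].
#' @param null_threshold `dI_max` below which the trace is null (0.05).
#' @param amp_boundary amplitude fallback separating alpha from beta (0.5).
#' @param rise_max maximum alpha rise time (s, default 10).
#' @param decay_half_max maximum alpha half-decay time (s, default 30).
#' @return `"null"`, `"alpha"` or `"beta"`.
#' @export
classify_calcium <- function(ct, null_threshold = 0.05, amp_boundary = 0.5,
                             rise_max = 10, decay_half_max = 30) {
  stopifnot(inherits(ct, "calcium_trace"))
  if (ct$dI_max < null_threshold) return("null")
  if (is.na(ct$onset_time))
    return(if (ct$dI_max >= amp_boundary) "alpha" else "beta")
  rise <- ct$peak_time - ct$onset_time
  post <- ct$time > ct$peak_time
  half_level <- 1 + ct$dI_max / 2
  ih <- which(post & ct$intensity < half_level)
  decay_half <- if (length(ih)) ct$time[ih[1]] - ct$peak_time else Inf
  if (is.infinite(decay_half) && ct$peak_time >= max(ct$time) - 1e-9)
    return(if (ct$dI_max >= amp_boundary) "alpha" else "beta")
  if (rise < rise_max && decay_half < decay_half_max) "alpha" else "beta"
}

#' Pre-onset bond lifetime statistics
#'
#' Statistics of the bond lifetimes completed before calcium onset: the
#' longest (`t_max`), the cumulative (`sum_t`) and the mean lifetime.
#' Sessions without an onset use the whole-session window.
#'
#' @param lifetimes bond lifetimes (s).
#' @param end_times completion times of those lifetimes on the session
#'   clock (s).
#' @param onset_time calcium onset (s) or `NA`.
#' @return list with `t_max`, `sum_t`, `mean_t`, `n_lifetimes` (all `NA`/0
#'   when no lifetime completed pre-onset, flagged by `empty = TRUE`).
#' @export
pre_ca_stats <- function(lifetimes, end_times, onset_time = NA) {
  stopifnot(length(lifetimes) == length(end_times))
  keep <- if (is.na(onset_time)) rep(TRUE, length(lifetimes))
          else end_times <= onset_time
  lt <- lifetimes[keep]
  if (!length(lt))
    return(list(t_max = NA_real_, sum_t = NA_real_, mean_t = NA_real_,
                n_lifetimes = 0L, empty = TRUE))
  list(t_max = max(lt), sum_t = sum(lt), mean_t = mean(lt),
       n_lifetimes = length(lt), empty = FALSE)
}

#' Pearson correlation with linear fit
#'
#' @param x,y paired numeric vectors, `n >= 3` (null-type platelets are
#'   excluded upstream).
#' @return list with `r`, `p`, `slope`, `intercept`, `n`.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), n = length(x))
}

#' ROC analysis of a scalar threshold separating two labeled classes
#'
#' Sweeps thresholds over the observed values of a statistic (e.g. the
#' pre-onset longest lifetime `t_max`), predicting the positive class
#' (alpha) when `value > threshold`. Reports sensitivity `TP/(TP+FN)` and
#' specificity `TN/(TN+FP)` at each threshold and selects the optimal
#' threshold by minimizing the total count of false positives plus false
#' negatives; ties resolve toward the smaller (more sensitive) threshold.
#'
#' @param values the statistic (one per cell/session).
#' @param labels logical (or `"alpha"`/`"beta"` character): `TRUE`/alpha is
#'   the positive class. Both classes must be present.
#' @return list with `t0`, `sensitivity`, `specificity` (at `t0`), `curve`
#'   (data frame `threshold`, `tpr`, `fpr`, `errors`), `auc`.
#' @export
roc_threshold <- function(values, labels) {
  if (is.character(labels) || is.factor(labels)) labels <- labels == "alpha"
  stopifnot(length(values) == length(labels), is.logical(labels))
  if (!any(labels) || all(labels))
    stop("degenerate ROC: both classes must be present", call. = FALSE)
  np <- sum(labels); nn <- sum(!labels)
  thr <- c(-Inf, sort(unique(values)))
  stats_at <- function(t0) {
    pred <- values > t0
    tp <- sum(pred & labels); fp <- sum(pred & !labels)
    c(tpr = tp / np, fpr = fp / nn, errors = fp + (np - tp))
  }
  m <- t(vapply(thr, stats_at, c(tpr = 0, fpr = 0, errors = 0)))
  curve <- data.frame(threshold = thr, tpr = m[, "tpr"], fpr = m[, "fpr"],
                      errors = m[, "errors"])
  best <- which(curve$errors == min(curve$errors))
  i0 <- best[1]   # smallest threshold among ties
  o <- order(curve$fpr, curve$tpr)
  auc <- sum(diff(curve$fpr[o]) *
               (utils::head(curve$tpr[o], -1) + utils::tail(curve$tpr[o], -1)) / 2)
  list(t0 = curve$threshold[i0], sensitivity = curve$tpr[i0],
       specificity = 1 - curve$fpr[i0], curve = curve, auc = auc)
}

#' Group calcium metrics by unfolding history
#'
#' Segregates per-platelet records into the four (LRRD+/-, MSD+/-) groups
#' and summarizes `dI_max` and `t_max` per group, with multinomial s.e. on
#' the occurrence fractions.
#'
#' @param records data frame with logical columns `lrrd`, `msd` and numeric
#'   `dI_max`, `t_max`.
#' @return data frame with one row per group: `lrrd`, `msd`, `n`,
#'   `fraction`, `fraction_se`, `mean_dI_max`, `dI_max_sem`, `mean_t_max`,
#'   `t_max_sem`.
#' @export
segregate_by_unfolding <- function(records) {
  stopifnot(all(c("lrrd", "msd", "dI_max", "t_max") %in% names(records)))
  combos <- expand.grid(lrrd = c(TRUE, FALSE), msd = c(TRUE, FALSE))
  counts <- mapply(function(l, m) sum(records$lrrd == l & records$msd == m),
                   combos$lrrd, combos$msd)
  ms <- multinomial_sem(counts)
  out <- cbind(combos, n = counts, fraction = ms$fraction,
               fraction_se = ms$se)
  stats_ <- t(mapply(function(l, m) {
    sel <- records$lrrd == l & records$msd == m
    c(mean_dI_max = if (any(sel)) mean(records$dI_max[sel]) else NA_real_,
      dI_max_sem = sem(records$dI_max[sel]),
      mean_t_max = if (any(sel)) mean(records$t_max[sel], na.rm = TRUE) else NA_real_,
      t_max_sem = sem(records$t_max[sel]))
  }, combos$lrrd, combos$msd))
  cbind(out, stats_)
}
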