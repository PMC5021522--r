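# Detection of cycle outcomes, lifetimes and unfolding signatures in
# force-time traces.

trace_attr <- function(trace, what, default = NULL) {
  v <- attr(trace, what)
  if (is.null(v)) default else v
}

smooth_force <- function(force, window = 21, order = 3) {
  n <- length(force)
  if (n < window + 2) return(force)
  signal::sgolayfilt(force, p = order, n = window)
}

# first index at which `cond` holds for at least `run` consecutive samples
first_run <- function(cond, run) {
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= run)
  if (!length(hit)) return(NA_integer_)
  ends[hit[1]] - r$lengths[hit[1]] + 1L
}

#' Segment a BFP trace into its cycle phases
#'
#' Detects, from the force channel alone, the retraction onset (end of the
#' compressive contact hold), the tensile zero crossing, the clamp
#' attainment (clamp mode), and bond dissociation or rupture. Dissociation
#' is called when the smoothed force stays below `drop_to` (2 pN) for at
#' least 5 ms; clamp attainment when it stays within `clamp_tol` of the
#' clamp level for at least 10 ms.
#'
#' @param trace a trace data frame (from [simulate_cycle()] or
#'   [read_session()]) carrying `sample_rate`, `clamp_force`, `ramp_rate`
#'   metadata attributes.
#' @param min_force minimum peak tensile force (pN) to call a bond
#'   (default 5).
#' @param clamp_tol tolerance (pN) on reaching the clamp level (default 3).
#' @param drop_to force level (pN) defining dissociation (default 2).
#' @param smoothing_window Savitzky-Golay window (samples, odd; default 21).
#' @return list with `outcome` (`"no_bond"`, `"rupture"`, `"lifetime"`),
#'   indices `i_retract`, `i_zero`, `i_attain`, `i_diss`, `i_ramp_end`,
#'   `peak_force`, `rupture_force`, and the smoothed force `sm`.
#' @export
segment_trace <- function(trace, min_force = 5, clamp_tol = 3, drop_to = 2,
                          smoothing_window = 21) {
  fs <- trace_attr(trace, "sample_rate")
  clamp <- trace_attr(trace, "clamp_force")
  mode <- trace_attr(trace, "mode", "clamp")
  if (is.null(fs)) stop("trace is missing sample_rate metadata", call. = FALSE)
  f <- trace$force_pN
  n <- length(f)
  sm <- smooth_force(f, smoothing_window)
  ms <- function(x) max(1L, round(x * fs))   # milliseconds -> samples

  cmin <- min(sm)
  if (cmin < -min_force) {
    plateau <- which(sm < cmin * 0.8)
    i_retract <- max(plateau)
    after <- which(sm[i_retract:n] >= 0)
    if (!length(after)) stop("unsegmentable trace: no tensile zero crossing",
                             call. = FALSE)
    i_zero <- i_retract + after[1] - 1L
    # refine: extrapolate the linear compressive unload to its zero crossing
    # (robust to soft tethers whose tensile force builds up slowly)
    unl <- i_retract:min(i_zero + 2L, n)
    unl <- unl[sm[unl] < -3 & sm[unl] > cmin * 0.8]
    if (length(unl) >= 5) {
      co <- stats::lm.fit(cbind(1, unl), f[unl])$coefficients
      iz <- round(-co[1] / co[2])
      if (is.finite(iz) && iz > i_retract && iz < i_zero + ms(0.02))
        i_zero <- as.integer(iz)
    }
  } else {
    # no compressive phase recorded; treat the whole record as post-contact
    i_retract <- 1L
    i_zero <- which(sm >= 0)[1]
    if (is.na(i_zero)) stop("unsegmentable trace", call. = FALSE)
  }

  # bond call on a lightly despiked force: heavy smoothing would smear
  # short-lived low-force peaks below the calling threshold
  fmed <- stats::runmed(f, k = min(5L, n - (1 - n %% 2)))
  peak <- max(fmed[i_zero:n])
  if (peak < min_force) {
    return(list(outcome = "no_bond", i_retract = i_retract, i_zero = i_zero,
                i_attain = NA_integer_, i_diss = NA_integer_,
                i_ramp_end = NA_integer_, peak_force = peak,
                rupture_force = NA_real_, sm = sm, fs = fs))
  }

  i_attain <- NA_integer_
  if (mode == "clamp" && !is.null(clamp)) {
    rel <- sm[i_zero:n] >= clamp - clamp_tol
    ia <- first_run(rel, ms(0.010))
    if (!is.na(ia)) i_attain <- i_zero + ia - 1L
  }

  if (!is.na(i_attain)) {
    rel <- sm[i_attain:n] < drop_to
    id <- first_run(rel, ms(0.005))
    i_diss <- if (is.na(id)) n else i_attain + id - 1L
    return(list(outcome = "lifetime", i_retract = i_retract, i_zero = i_zero,
                i_attain = i_attain, i_diss = i_diss, i_ramp_end = i_attain,
                peak_force = peak, rupture_force = NA_real_, sm = sm, fs = fs))
  }

  # rupture: peak then collapse; the rupture force comes from a short raw
  # line fit just before the collapse edge (smoothing rounds the peak off)
  i_peak <- i_zero - 1L + which.max(fmed[i_zero:n])
  rel <- sm[i_peak:n] < drop_to
  ic <- first_run(rel, ms(0.005))
  i_ramp_end <- if (is.na(ic)) n else i_peak + ic - 1L
  look <- max(i_zero + 1L, i_ramp_end - ms(0.025)):min(i_ramp_end + ms(0.005),
                                                       n - 1L)
  i_col <- look[which.min(f[look + 1L] - f[look])]
  pre <- max(i_zero, i_col - ms(0.008)):i_col
  rupture <- if (length(pre) >= 4) {
    co <- stats::lm.fit(cbind(1, trace$time_s[pre]), f[pre])$coefficients
    unname(co[1] + co[2] * trace$time_s[i_col])
  } else peak
  list(outcome = "rupture", i_retract = i_retract, i_zero = i_zero,
       i_attain = NA_integer_, i_diss = NA_integer_, i_ramp_end = i_ramp_end,
       peak_force = peak, rupture_force = rupture, sm = sm, fs = fs)
}

#' Classify the outcome of a BFP test cycle
#'
#' A cycle is `no_bond` when the peak tensile force never exceeds
#' `min_force`, a `lifetime` event when the clamp plateau is attained, and a
#' `rupture` when a bond breaks during the ramp.
#'
#' @inheritParams segment_trace
#' @return outcome string.
#' @export
classify_cycle <- function(trace, min_force = 5, ...) {
  segment_trace(trace, min_force = min_force, ...)$outcome
}

#' Measure the bond lifetime of a clamp cycle
#'
#' Lifetime = time from clamp attainment (force first sustained at the clamp
#' level) to dissociation (force sustained below 2 pN).
#'
#' @inheritParams segment_trace
#' @param clamp_force clamp level (pN); defaults to the trace metadata.
#' @return lifetime (s).
#' @export
measure_lifetime <- function(trace, clamp_force = NULL, ...) {
  if (!is.null(clamp_force)) attr(trace, "clamp_force") <- clamp_force
  seg <- segment_trace(trace, ...)
  if (seg$outcome != "lifetime")
    stop("not a lifetime cycle: the clamp level was never attained",
         call. = FALSE)
  (seg$i_diss - seg$i_attain) / seg$fs
}

lm_line <- function(t, y) {
  fit <- stats::lm.fit(cbind(1, t), y)
  unname(fit$coefficients)   # c(intercept, slope)
}

#' Detect ramped unfolding events (force kinks) in a trace
#'
#' A ramped unfolding is a sudden force stagnation or drop interrupting the
#' tensile ramp. The detector flags intervals where the Savitzky-Golay
#' slope of the force falls below `kink_threshold` times the reference
#' loading rate for at least `min_duration`. The reference rate is the
#' nominal ramp rate (`reference = "nominal"`, appropriate for a stiff
#' tether) or the median observed ramp slope (`"local"`, robust when tether
#' compliance makes the loading rate sub-nominal).
#'
#' Each event's onset force is taken from a line fit to the pre-kink force;
#' the unfolding length is measured as the jump in molecular extension
#' (target minus probe displacement) across the kink when position channels
#' are present, otherwise as (force drop)/(spring constant).
#'
#' @inheritParams segment_trace
#' @param kink_threshold slope fraction below which a kink is called
#'   (default 0.3).
#' @param min_duration minimum kink duration (s, default 0.003).
#' @param reference `"nominal"` or `"local"` loading-rate reference.
#' @return data frame with one row per event: `phase`, `time_s` (onset),
#'   `force` (pN at onset), `length` (nm), `t_u` (NA for ramped events).
#' @export
detect_ramped_unfolding <- function(trace, smoothing_window = 21,
                                    kink_threshold = 0.3,
                                    min_duration = 0.003,
                                    reference = c("nominal", "local"),
                                    min_force = 5, ...) {
  reference <- match.arg(reference)
  seg <- segment_trace(trace, min_force = min_force,
                       smoothing_window = smoothing_window, ...)
  empty <- data.frame(phase = character(0), time_s = numeric(0),
                      force = numeric(0), length = numeric(0),
                      t_u = numeric(0))
  if (seg$outcome == "no_bond") return(empty)
  fs <- seg$fs
  k <- trace_attr(trace, "spring_constant")
  rate_nom <- trace_attr(trace, "ramp_rate")
  f <- trace$force_pN
  n <- length(f)
  ms <- function(x) max(1L, round(x * fs))

  i0 <- seg$i_zero + ms(0.004)
  i1 <- seg$i_ramp_end - ms(0.002)
  if (i1 - i0 < ms(0.015)) return(empty)

  # windowed slope: mean force over the leading window minus the lagging
  # window, per unit time; responds fully to both sharp drops and
  # stagnations within one window transit
  w <- ms(0.005)
  cs <- cumsum(c(0, f))
  wmean <- function(a, b) (cs[pmin(b, n) + 1L] - cs[pmax(a, 1L)]) / (pmin(b, n) - pmax(a, 1L) + 1L)
  region <- i0:i1
  slope <- (wmean(region, region + w - 1L) - wmean(region - w, region - 1L)) /
    (w / fs)
  ref <- if (reference == "nominal" && !is.null(rate_nom)) rate_nom
         else stats::median(slope)
  low <- slope < kink_threshold * ref
  r <- rle(low)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= ms(min_duration))
  if (!length(runs)) return(empty)
  # merge runs separated by < 5 ms
  iv <- cbind(starts[runs], ends[runs])
  merged <- list(iv[1, ])
  if (nrow(iv) > 1) for (j in 2:nrow(iv)) {
    last <- merged[[length(merged)]]
    if (iv[j, 1] - last[2] < ms(0.005)) merged[[length(merged)]][2] <- iv[j, 2]
    else merged[[length(merged) + 1L]] <- iv[j, ]
  }

  has_pos <- all(c("probe_nm", "target_nm") %in% names(trace))
  sm <- seg$sm
  tt <- trace$time_s
  out <- lapply(merged, function(m) {
    rs <- region[1] + m[1] - 1L   # run start (absolute index)
    re <- region[1] + m[2] - 1L
    # fine localization: the steepest single-sample descent near the run
    look <- max(seg$i_zero + 1L, rs - ms(0.015)):min(re + ms(0.005), n - 1L)
    dd <- f[look + 1L] - f[look]
    onset <- look[which.min(dd)]
    if (min(dd) > -2.5) onset <- rs   # stagnation without a sharp edge
    # kink-onset force from a short line fit to the raw pre-kink force
    # (raw samples immediately before the drop are uncontaminated by
    # smoothing spill-over; a short window stays on the linear ramp)
    pre_a <- max(seg$i_retract, onset - ms(0.008))
    co <- lm_line(tt[pre_a:onset], f[pre_a:onset])
    f_on <- co[1] + co[2] * tt[onset]
    # post-kink level: re-tensioned samples only (above the slack floor)
    post_win <- (onset + ms(0.002)):min(onset + ms(0.040), n)
    post_sel <- post_win[f[post_win] > 3.5]
    len <- if (has_pos) {
      ext <- trace$target_nm - trace$probe_nm
      pre_w <- max(1L, onset - ms(0.020)):(onset - ms(0.002))
      if (length(post_sel) >= ms(0.005) && length(pre_w) >= ms(0.005))
        mean(ext[post_sel]) - mean(ext[pre_w])
      else NA_real_
    } else if (!is.null(k) && length(post_sel) >= ms(0.005)) {
      # force-drop route: gap between the pre-kink line and the resumed ramp
      cp <- lm_line(tt[post_sel], sm[post_sel])
      (f_on - (cp[1] + cp[2] * tt[onset])) / k
    } else NA_real_
    data.frame(phase = "ramped", time_s = tt[onset], force = f_on,
               length = len, t_u = NA_real_)
  })
  res <- do.call(rbind, out)
  res <- res[is.finite(res$length) & res$length > 3, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Detect clamped unfolding events (abrupt force drops during the hold)
#'
#' During the force-clamp hold, a domain unfolding appears as an abrupt
#' force drop that does not collapse to zero (which would be dissociation);
#' the clamp feedback then restores the set force. The unfolding length is
#' the force drop divided by the BFP spring constant, and the time-to-unfold
#' `t_u` is measured from clamp attainment to the drop.
#'
#' @inheritParams segment_trace
#' @param drop_threshold minimum force drop (pN) to call an event
#'   (default 3).
#' @return data frame as in [detect_ramped_unfolding()], with `t_u` filled.
#' @export
detect_clamped_unfolding <- function(trace, drop_threshold = 3, ...) {
  seg <- segment_trace(trace, ...)
  empty <- data.frame(phase = character(0), time_s = numeric(0),
                      force = numeric(0), length = numeric(0),
                      t_u = numeric(0))
  if (seg$outcome != "lifetime") return(empty)
  fs <- seg$fs
  k <- trace_attr(trace, "spring_constant")
  if (is.null(k)) stop("trace is missing spring_constant metadata", call. = FALSE)
  ms <- function(x) max(1L, round(x * fs))
  f <- trace$force_pN
  i0 <- seg$i_attain; i1 <- seg$i_diss - 1L
  if (i1 - i0 < ms(0.05)) return(empty)
  w <- ms(0.010)
  cs <- cumsum(c(0, f))
  win_mean <- function(a, b) (cs[b + 1L] - cs[a]) / (b - a + 1L)
  idx <- (i0 + w):(i1 - w)
  if (!length(idx)) return(empty)
  d <- vapply(idx, function(i) win_mean(i, min(i + w - 1L, i1)) -
                win_mean(i - w, i - 1L), numeric(1))
  low <- d < -drop_threshold
  r <- rle(low)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (!length(runs)) return(empty)
  out <- lapply(runs, function(j) {
    a <- idx[starts[j]]; b <- idx[ends[j]]
    look <- max(i0, a - w):min(i1 - 1L, b + w)
    onset <- look[which.min(diff(f[c(look, min(look[length(look)] + 1L, i1))]))]
    pre_a <- max(i0 + 2L, onset - ms(0.023)); pre_b <- onset - ms(0.003)
    post_a <- onset + ms(0.002); post_b <- min(i1, onset + ms(0.022))
    # need a settled pre-drop window inside the clamp hold
    if (pre_b - pre_a < 5L || post_b <= post_a) return(NULL)
    pre <- win_mean(pre_a, pre_b); post <- win_mean(post_a, post_b)
    if (post < 5) return(NULL)   # collapse toward zero: dissociation, not unfolding
    drop <- pre - post
    if (drop < drop_threshold) return(NULL)
    data.frame(phase = "clamped", time_s = trace$time_s[onset],
               force = pre, length = drop / k,
               t_u = (onset - i0) / fs)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Full analysis of one cycle trace
#'
#' Runs segmentation, lifetime measurement and both unfolding detectors,
#' returning the cycle-level result.
#'
#' @inheritParams segment_trace
#' @param ... passed to the detectors.
#' @return list with `outcome`, `t_b`, `rupture_force`, `events` (data
#'   frame).
#' @export
analyze_cycle <- function(trace, min_force = 5, ...) {
  seg <- segment_trace(trace, min_force = min_force)
  ev_r <- detect_ramped_unfolding(trace, min_force = min_force, ...)
  ev_c <- detect_clamped_unfolding(trace, min_force = min_force)
  list(outcome = seg$outcome,
       t_b = if (seg$outcome == "lifetime")
         (seg$i_diss - seg$i_attain) / seg$fs else NA_real_,
       rupture_force = seg$rupture_force,
       events = rbind(ev_r, ev_c))
}

#' Analyze all cycles of a session
#'
#' @param session a `"bfp_session"` with rendered traces.
#' @param ... passed to [analyze_cycle()].
#' @return list with `cycles` (per-cycle data frame: `cycle`, `outcome`,
#'   `t_b`, `rupture_force`, event counts) and `events` (per-event data
#'   frame with `cycle` id).
#' @export
analyze_session <- function(session, ...) {
  stopifnot(inherits(session, "bfp_session"))
  if (is.null(session$cycles[[1]]$trace))
    stop("session has no rendered traces (simulate with traces = TRUE)",
         call. = FALSE)
  res <- lapply(seq_along(session$cycles), function(i) {
    a <- analyze_cycle(session$cycles[[i]]$trace, ...)
    ev <- a$events
    if (nrow(ev)) ev <- cbind(cycle = i, ev)
    list(row = data.frame(cycle = i, outcome = a$outcome, t_b = a$t_b,
                          rupture_force = a$rupture_force,
                          n_ramped = sum(ev$phase == "ramped"),
                          n_clamped = sum(ev$phase == "clamped")),
         ev = ev)
  })
  cycles <- do.call(rbind, lapply(res, `[[`, "row"))
  events <- do.call(rbind, Filter(function(e) NROW(e) > 0,
                                  lapply(res, `[[`, "ev")))
  if (is.null(events))
    events <- data.frame(cycle = integer(0), phase = character(0),
                         time_s = numeric(0), force = numeric(0),
                         length = numeric(0), t_u = numeric(0))
  list(cycles = cycles, events = events)
}
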