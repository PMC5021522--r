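# Synthetic BFP cycle generation: event-level draws plus trace rendering.

rtnorm1 <- function(mean, sd, lo, hi) {
  for (i in 1:100) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

# Draw the stochastic content of one cycle (no trace). Returns the ground
# truth: outcome, lifetime, and unfolding events with their true times,
# forces and lengths.
draw_cycle_events <- function(params) {
  p <- params
  gt <- list(bond_formed = FALSE, outcome = "no_bond", t_b = NA_real_,
             rupture_force = NA_real_, lrrd_unfolded = FALSE,
             msd_unfolded = FALSE, events = list())
  if (stats::runif(1) >= p$adhesion_probability) return(gt)
  gt$bond_formed <- TRUE

  cat_names <- c("none", "msd", "lrrd", "both")
  category <- sample(cat_names, 1, prob = p$ramped_event_probs)

  peak_force <- if (p$mode == "clamp") {
    if (stats::runif(1) < p$rupture_probability)
      stats::runif(1, 8, p$clamp_force - 1) else p$clamp_force
  } else {
    rtnorm1(p$rupture_force_mean, p$rupture_force_sd, 8, 120)
  }
  reaches_clamp <- p$mode == "clamp" && peak_force >= p$clamp_force

  draw_len <- function(domain) {
    u <- p$unfold_lengths
    switch(domain,
      msd = rtnorm1(u$msd["mean"], u$msd["sd"], 10, 27.5),
      lrrd = rtnorm1(u$lrrd["mean"], u$lrrd["sd"], 28.5, 56),
      both = {
        b <- if (!is.null(u$both)) u$both else c(mean = 65, sd = 7)
        rtnorm1(b["mean"], b["sd"], 58, 85)
      })
  }

  events <- list()
  if (category != "none") {
    fmax <- peak_force - 1.5
    if (fmax > 5.5) {
      fstar <- rtnorm1(p$lrrd_force_mean, p$lrrd_force_sd, 5, fmax)
      events[[1]] <- list(phase = "ramped", domain = toupper(category),
                          length = draw_len(category), force = fstar,
                          t_u = NA_real_)
      if (category %in% c("lrrd", "both")) gt$lrrd_unfolded <- TRUE
      if (category %in% c("msd", "both")) gt$msd_unfolded <- TRUE
    }
  }

  if (!reaches_clamp) {
    gt$outcome <- "rupture"
    gt$rupture_force <- peak_force
    gt$events <- events
    return(gt)
  }

  lt <- if (gt$lrrd_unfolded) p$lifetime_model$lrrd_plus else p$lifetime_model$lrrd_minus
  k <- if (stats::runif(1) < lt$w1) lt$k1 else lt$k2
  t_b <- stats::rexp(1, k)
  gt$outcome <- "lifetime"
  gt$t_b <- t_b

  if (!gt$msd_unfolded && p$msd_rate > 0) {
    t_u <- if (is.infinite(p$msd_rate)) 0 else stats::rexp(1, p$msd_rate)
    if (t_u < t_b) {
      events[[length(events) + 1L]] <-
        list(phase = "clamped", domain = "MSD", length = draw_len("msd"),
             force = p$clamp_force, t_u = t_u)
      gt$msd_unfolded <- TRUE
    }
  }
  gt$events <- events
  gt
}

# solve spring + WLC series for force at total displacement D (vector), given
# contour length Lc; used by the compliant-tether renderer
solve_series_force <- function(D, k, Lc, p, kBT, f_init = NULL) {
  vapply(seq_along(D), function(i) {
    d <- D[i]
    if (d <= 0) return(0)
    upper <- k * d   # force if tether were rigid
    stats::uniroot(function(f) f / k + wlc_extension(f, Lc, p, kBT) - d,
                   lower = 0, upper = upper + 1e-9, tol = 1e-6)$root
  }, numeric(1))
}

#' Simulate one BFP test cycle
#'
#' Generates a complete synthetic force-clamp or force-ramp cycle: the
#' ground-truth event draw (bond formation, ramped/clamped unfolding events,
#' dual-exponential bond lifetime) plus, optionally, the rendered force-time
#' trace with probe and target position channels and Gaussian force noise.
#'
#' The trace follows the canonical cycle stages: approach, impingement at the
#' compressive contact force, contact hold, retraction with compressive
#' unloading, then -- if a bond formed -- a tensile ramp at the nominal rate.
#' Ramped unfolding renders as an abrupt force drop of magnitude
#' `spring_constant * length` (floored at zero force, i.e. a stagnation while
#' the retraction takes up the released slack) with the ramp resuming at the
#' nominal rate; in clamp mode, reaching the clamp level starts a hold whose
#' duration is the drawn bond lifetime, during which a clamped MSD unfolding
#' renders as a force drop of `spring_constant * length` restored by the
#' clamp feedback with time constant `feedback_tau`. Dissociation collapses
#' the force to zero.
#'
#' @param params a [sim_params()] object.
#' @param seed optional integer seed (cycle substream).
#' @param trace logical; render the sampled trace (default `TRUE`). With
#'   `FALSE` only the ground truth is returned (fast path for large
#'   ensembles).
#' @return list of class `"bfp_cycle"` with elements `truth` (ground truth,
#'   see Details), `trace` (data frame `time_s`, `force_pN`, `probe_nm`,
#'   `target_nm`, or `NULL`), and `params`. The trace carries acquisition
#'   metadata as attributes (`spring_constant`, `sample_rate`, `ramp_rate`,
#'   `clamp_force`, `mode`).
#' @export
simulate_cycle <- function(params, seed = NULL, trace = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  truth <- draw_cycle_events(params)
  tr <- if (trace) render_cycle_trace(truth, params) else NULL
  structure(list(truth = truth, trace = tr, params = params),
            class = "bfp_cycle")
}

# Render the sampled force/position channels for a drawn cycle.
render_cycle_trace <- function(truth, params) {
  p <- params
  k <- p$spring_constant; fs <- p$sample_rate; dt <- 1 / fs
  rate <- p$ramp_rate; v <- p$retraction_speed
  wlc_mode <- !identical(p$tether, "rigid")

  t_approach <- 0.10; t_impinge <- 0.05; t_pause <- 0.20
  d_imp <- p$impingement_force / k

  seg_force <- list(); seg_target <- list()
  add <- function(f, tg) {
    seg_force[[length(seg_force) + 1L]] <<- f
    seg_target[[length(seg_target) + 1L]] <<- tg
  }

  # approach: target closes 100 nm; no contact force
  n1 <- round(t_approach * fs)
  add(rep(0, n1), seq(100, 0, length.out = n1))
  # impinge: compress to -F_imp
  n2 <- round(t_impinge * fs)
  add(seq(0, -p$impingement_force, length.out = n2),
      seq(0, -d_imp, length.out = n2))
  # contact hold
  n3 <- round(p$contact_duration * fs)
  add(rep(-p$impingement_force, n3), rep(-d_imp, n3))

  # retraction: compressive unload at the nominal rate
  n4 <- ceiling(p$impingement_force / rate * fs)
  add(seq(-p$impingement_force, 0, length.out = n4),
      -d_imp + v * dt * seq_len(n4))
  target_zero <- -d_imp + v * dt * n4   # target at tensile onset

  ramp_events <- Filter(function(e) e$phase == "ramped", truth$events)
  clamp_events <- Filter(function(e) e$phase == "clamped", truth$events)

  if (!truth$bond_formed) {
    n5 <- round(0.3 * fs)
    add(rep(0, n5), target_zero + v * dt * pmin(seq_len(n5), round(0.1 * fs)))
  } else {
    peak <- if (truth$outcome == "rupture") truth$rupture_force else p$clamp_force
    # tensile ramp with event drops; drop floored at zero (slack), ramp resumes
    drops <- 0
    ev_t <- c()   # event times relative to tensile onset
    for (e in ramp_events) {
      ev_t <- c(ev_t, (e$force + drops) / rate)
      drops <- drops + k * e$length
    }
    t_end_ramp <- (peak + drops) / rate
    nr <- ceiling(t_end_ramp * fs)
    tt <- dt * seq_len(nr)
    base <- rate * tt
    fr <- base
    if (length(ev_t)) {
      # force = nominal ramp minus the drops of all events already passed
      cumdrop <- numeric(length(tt))
      for (j in seq_along(ev_t))
        cumdrop[tt >= ev_t[j]] <- cumdrop[tt >= ev_t[j]] + k * ramp_events[[j]]$length
      fr <- pmax(base - cumdrop, 0)
    }
    if (wlc_mode) {
      # compliant tether: solve the spring+WLC series force along the ramp,
      # releasing contour length at each unfolding event; the ramp lasts
      # until the required total displacement for the peak force is reached
      pw <- p$tether$p; kBT <- p$tether$kBT
      Lc <- p$tether$Lc0
      fr <- numeric(0)
      t_cursor <- 0
      for (e in ramp_events) {
        D_ev <- e$force / k + wlc_extension(e$force, Lc, pw, kBT)
        tseg <- seq(t_cursor + dt, D_ev / v, by = dt)
        if (length(tseg))
          fr <- c(fr, solve_series_force(v * tseg, k, Lc, pw, kBT))
        t_cursor <- if (length(tseg)) tseg[length(tseg)] else t_cursor
        Lc <- Lc + e$length
      }
      D_end <- peak / k + wlc_extension(peak, Lc, pw, kBT)
      tseg <- seq(t_cursor + dt, D_end / v, by = dt)
      if (length(tseg))
        fr <- c(fr, solve_series_force(v * tseg, k, Lc, pw, kBT))
      nr <- length(fr)
      tt <- dt * seq_len(nr)
    }
    add(fr, target_zero + v * dt * seq_len(nr))
    target_ramp_end <- target_zero + v * dt * nr

    if (truth$outcome == "rupture") {
      n5 <- round(t_pause * fs)
      add(rep(0, n5),
          target_ramp_end + v * dt * pmin(seq_len(n5), round(0.05 * fs)))
    } else {
      # clamp hold for the drawn lifetime
      nc <- max(2L, ceiling(truth$t_b * fs))
      tc <- dt * seq_len(nc)
      fc <- rep(p$clamp_force, nc)
      tg <- rep(target_ramp_end, nc)
      if (length(clamp_events)) {
        e <- clamp_events[[1]]
        after <- tc >= e$t_u
        rec <- exp(-(tc[after] - e$t_u) / p$feedback_tau)
        fc[after] <- p$clamp_force - k * e$length * rec
        tg[after] <- target_ramp_end + e$length * (1 - rec)
      }
      add(fc, tg)
      n5 <- round(t_pause * fs)
      add(rep(0, n5), tg[nc] + v * dt * pmin(seq_len(n5), round(0.05 * fs)))
    }
  }

  idle <- p$idle_duration %||% 0
  if (idle > 0) {
    ni <- round(idle * fs)
    last_tg <- seg_target[[length(seg_target)]]
    add(rep(0, ni), rep(last_tg[length(last_tg)], ni))
  }
  force <- unlist(seg_force, use.names = FALSE)
  target <- unlist(seg_target, use.names = FALSE)
  n <- length(force)
  noisy <- force + stats::rnorm(n, 0, p$noise_sd)
  tr <- data.frame(time_s = dt * (seq_len(n) - 1L),
                   force_pN = noisy,
                   probe_nm = noisy / k,
                   target_nm = target)
  attr(tr, "spring_constant") <- k
  attr(tr, "sample_rate") <- fs
  attr(tr, "ramp_rate") <- rate
  attr(tr, "clamp_force") <- p$clamp_force
  attr(tr, "mode") <- p$mode
  tr
}
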