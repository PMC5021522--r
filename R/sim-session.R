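# Session-level simulation: repeated cycles on one platelet plus its
# calcium response.

#' Simulate a BFP session (repeated cycles on one platelet)
#'
#' Draws `n_cycles` consecutive test cycles with per-cycle substream seeds
#' derived from `seed`, lays them on a common session clock (a 50-cycle
#' clamp session spans roughly 200 s with the default 2 s contact), and
#' generates the platelet's calcium intensity trace according to the
#' [calcium_coupling()] rule.
#'
#' @param n_cycles number of cycles, `>= 1` (default 50).
#' @param params a [sim_params()] object.
#' @param coupling a [calcium_coupling()] object.
#' @param seed master seed for the session.
#' @param traces logical; render full force-time traces per cycle (default
#'   `FALSE`: event-level fast path).
#' @return object of class `"bfp_session"`: list with `cycles` (list of
#'   [simulate_cycle()] results, each with an added `start_time`), `cycle_table`
#'   (per-cycle data frame: outcome, lifetime, unfolding flags, absolute
#'   times), `calcium` (list `time`, `intensity`, `truth`), `params`,
#'   `coupling`, `seed`.
#' @export
simulate_session <- function(n_cycles = 50, params = sim_params(),
                             coupling = calcium_coupling(), seed = 1,
                             traces = FALSE) {
  stopifnot(n_cycles >= 1, inherits(params, "sim_params"),
            inherits(coupling, "calcium_coupling"))
  cycles <- vector("list", n_cycles)
  t0 <- 0
  rows <- vector("list", n_cycles)
  for (i in seq_len(n_cycles)) {
    cy <- simulate_cycle(params, seed = child_seed(seed, i), trace = traces)
    cy$start_time <- t0
    dur <- cycle_duration(cy$truth, params)
    tru <- cy$truth
    # absolute event times on the session clock
    t_att <- if (tru$outcome == "lifetime") attain_time(tru, params) else NA_real_
    msd_clamp_t <- NA_real_
    for (e in tru$events) {
      if (e$phase == "clamped")
        msd_clamp_t <- t0 + t_att + e$t_u
    }
    rows[[i]] <- data.frame(
      cycle = i, start_time = t0, outcome = tru$outcome,
      t_b = tru$t_b,
      t_end = if (tru$outcome == "lifetime") t0 + t_att + tru$t_b else NA_real_,
      lrrd_unfolded = tru$lrrd_unfolded, msd_unfolded = tru$msd_unfolded,
      msd_clamped = any(vapply(tru$events, function(e) e$phase == "clamped",
                               logical(1))),
      msd_clamp_time = msd_clamp_t)
    cycles[[i]] <- cy
    t0 <- t0 + dur
  }
  tab <- do.call(rbind, rows)
  session_dur <- t0
  ca <- generate_calcium(tab, session_dur, coupling,
                         seed = child_seed(seed, n_cycles + 1L))
  structure(list(cycles = cycles, cycle_table = tab, calcium = ca,
                 params = params, coupling = coupling, seed = seed,
                 duration = session_dur),
            class = "bfp_session")
}

# time from tensile onset to clamp attainment (ramped drops delay it)
attain_time <- function(truth, params) {
  drops <- params$spring_constant *
    sum(vapply(Filter(function(e) e$phase == "ramped", truth$events),
               function(e) e$length, 1))
  (params$clamp_force + drops) / params$ramp_rate
}

# wall-clock duration of one cycle (matches the renderer's segment layout)
cycle_duration <- function(truth, params) {
  p <- params
  idle <- p$idle_duration %||% 0
  pre <- 0.10 + 0.05 + p$contact_duration + p$impingement_force / p$ramp_rate
  if (!truth$bond_formed) return(pre + 0.3 + idle)
  drops <- p$spring_constant *
    sum(vapply(Filter(function(e) e$phase == "ramped", truth$events),
               function(e) e$length, 1))
  if (truth$outcome == "rupture")
    return(pre + (truth$rupture_force + drops) / p$ramp_rate + 0.2 + idle)
  pre + (p$clamp_force + drops) / p$ramp_rate + max(truth$t_b, 2 / p$sample_rate) +
    0.2 + idle
}

# Apply the coupling rule and synthesize the intensity trace.
generate_calcium <- function(cycle_table, session_dur, coupling, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cc <- coupling
  type <- "null"; onset <- NA_real_; amp <- 0
  lifetimes <- cycle_table[cycle_table$outcome == "lifetime", , drop = FALSE]
  if (cc$enabled && nrow(lifetimes)) {
    trig <- which(cycle_table$msd_clamped)
    trig_ok <- NA_integer_
    for (i in trig) {
      upto <- cycle_table[seq_len(i), ]
      tmax <- suppressWarnings(max(upto$t_b[upto$outcome == "lifetime"],
                                   na.rm = TRUE))
      if (is.finite(tmax) && tmax > cc$t_threshold) { trig_ok <- i; break }
    }
    if (!is.na(trig_ok)) {
      type <- "alpha"
      onset <- cycle_table$t_end[trig_ok] + cc$latency
      amp <- stats::runif(1, cc$alpha_amp[1], cc$alpha_amp[2])
    } else {
      type <- "beta"
      onset <- min(lifetimes$t_end, na.rm = TRUE) + cc$latency
      amp <- stats::runif(1, cc$beta_amp[1], cc$beta_amp[2])
    }
  }
  dt <- 1 / cc$ca_sample_rate
  tgrid <- seq(0, max(session_dur, onset + 30, na.rm = TRUE), by = dt)
  base <- rep(1, length(tgrid))
  if (type != "null") {
    rise <- if (type == "alpha") cc$alpha_rise else cc$beta_rise
    half <- if (type == "alpha") cc$alpha_decay_half else cc$beta_decay_half
    plateau <- if (type == "alpha") 0.15 else 0.3
    rel <- tgrid - onset
    shape <- ifelse(rel < 0, 0,
                    ifelse(rel < rise, rel / rise,
                           plateau + (1 - plateau) *
                             2^(-(rel - rise) / half)))
    base <- base + amp * shape
  }
  intensity <- base * (1 + stats::rnorm(length(tgrid), 0, cc$ca_noise_sd))
  list(time = tgrid, intensity = intensity,
       truth = list(calcium_type = type, onset_time = onset, amplitude = amp))
}
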