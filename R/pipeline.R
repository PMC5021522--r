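# End-to-end orchestration: simulate -> detect -> classify -> kinetics ->
# cooperativity -> calcium, with a YAML-configurable, seed-reproducible run.

#' Default pipeline configuration
#'
#' @param seed master seed.
#' @param n_platelets number of simulated platelet sessions.
#' @param n_cycles cycles per session.
#' @param output_dir directory for artifacts (`NULL`: return-only run).
#' @return nested configuration list (YAML-serializable).
#' @export
default_config <- function(seed = 1, n_platelets = 6, n_cycles = 30,
                           output_dir = NULL) {
  list(
    seed = seed,
    n_platelets = n_platelets,
    n_cycles = n_cycles,
    output_dir = output_dir,
    sim = list(mode = "clamp", clamp_force = 25, contact_duration = 2,
               adhesion_probability = 0.18, noise_sd = 1, sample_rate = 1000),
    detect = list(min_force = 5, kink_threshold = 0.3, drop_threshold = 3),
    classify = list(boundaries = c(28, 56)),
    coupling = list(enabled = TRUE, t_threshold = 2)
  )
}

#' Run the full analysis pipeline on simulated sessions
#'
#' Simulates `n_platelets` BFP sessions with traces, detects outcomes and
#' unfolding events from the traces, classifies event domains, fits the
#' clamped unfolding rate and compares the observed clamped MSD unfolding
#' frequency per lifetime event against the closed-form joint-model
#' prediction, tests LRRD/MSD cooperativity, and classifies the calcium
#' responses with pre-onset lifetime statistics.
#'
#' The run is a pure function of the configuration (including its seed).
#' When `output_dir` is set, per-stage artifacts are written:
#' `events.csv`, `cycles.csv`, `summary.json`.
#'
#' @param config configuration list from [default_config()], or the path to
#'   a YAML file holding one.
#' @return report list (invisible when written to disk): `n_cycles_total`,
#'   `adhesion`, `outcome_counts`, `events`, `domain_summary`, `kinetics`
#'   (`ku_hat`, `pu_predicted`, `pu_observed`), `cooperativity` (`table`,
#'   `chi2`, `p`, `dP_over_P`), `calcium` (per-platelet types and
#'   statistics), `config`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  known <- c("seed", "n_platelets", "n_cycles", "output_dir", "sim",
             "detect", "classify", "coupling")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  sp <- do.call(sim_params, cfg$sim %||% list())
  cc <- do.call(calcium_coupling, cfg$coupling %||% list())
  det <- cfg$detect %||% list()
  bounds <- unlist((cfg$classify %||% list())$boundaries %||% c(28, 56))

  sessions <- lapply(seq_len(cfg$n_platelets), function(i)
    simulate_session(cfg$n_cycles, sp, cc,
                     seed = child_seed(cfg$seed, 1000 + i), traces = TRUE))

  all_events <- list(); all_cycles <- list(); platelet_rows <- list()
  for (i in seq_along(sessions)) {
    ses <- sessions[[i]]
    an <- analyze_session(ses, min_force = det$min_force %||% 5)
    ev <- an$events
    if (nrow(ev)) {
      ev$domain <- assign_domain(ev$phase, ev$length, boundaries = bounds)
      ev$platelet <- i
      all_events[[i]] <- ev
    }
    cyc <- an$cycles; cyc$platelet <- i
    all_cycles[[i]] <- cyc

    ca <- normalize_and_peak(ses$calcium$time, ses$calcium$intensity)
    ctype <- classify_calcium(ca)
    lt <- cyc[cyc$outcome == "lifetime", , drop = FALSE]
    end_times <- ses$cycle_table$t_end[lt$cycle]
    pcs <- pre_ca_stats(lt$t_b, end_times, ca$onset_time)
    lr <- if (nrow(ev))
      any(ev$domain %in% c("LRRD", "BOTH")) else FALSE
    md <- if (nrow(ev)) any(ev$domain == "MSD" | ev$domain == "BOTH") else FALSE
    platelet_rows[[i]] <- data.frame(
      platelet = i, calcium_type = ctype, dI_max = ca$dI_max,
      onset_time = ca$onset_time, t_max = pcs$t_max, sum_t = pcs$sum_t,
      mean_t = pcs$mean_t, n_lifetimes = pcs$n_lifetimes,
      lrrd = lr, msd = md)
  }
  events <- do.call(rbind, Filter(Negate(is.null), all_events))
  cycles <- do.call(rbind, all_cycles)
  platelets <- do.call(rbind, platelet_rows)

  adh <- adhesion_frequency(cycles$outcome)
  outcome_counts <- table(cycles$outcome)

  # kinetics: clamped unfolding rate and joint-model check
  kin <- NULL
  t_u <- if (!is.null(events)) events$t_u[events$phase == "clamped"] else numeric(0)
  t_u <- t_u[is.finite(t_u)]
  n_life <- sum(cycles$outcome == "lifetime")
  if (length(t_u) >= 5 && n_life > 0) {
    ef <- fit_exponential(t_u, "reciprocal_mean")
    kp <- sp$lifetime_model
    pu_pred <- mean(c(predict_unfold_probability(sp$msd_rate, kp$lrrd_minus),
                      predict_unfold_probability(sp$msd_rate, kp$lrrd_plus)))
    kin <- list(ku_hat = ef$rate, ku_ci = ef$ci, n_tu = ef$n,
                pu_observed = length(t_u) / n_life,
                pu_predicted_range = c(
                  predict_unfold_probability(sp$msd_rate, kp$lrrd_minus),
                  predict_unfold_probability(sp$msd_rate, kp$lrrd_plus)),
                pu_predicted_mid = pu_pred)
  }

  # cooperativity over lifetime cycles
  coop <- NULL
  lt_cycles <- cycles[cycles$outcome == "lifetime", , drop = FALSE]
  if (nrow(lt_cycles) >= 10 && !is.null(events)) {
    key <- paste(lt_cycles$platelet, lt_cycles$cycle)
    evl <- events[paste(events$platelet, events$cycle) %in% key, , drop = FALSE]
    lab <- function(dom) {
      hit <- unique(paste(evl$platelet, evl$cycle)[evl$domain %in% dom])
      key %in% hit
    }
    lrrd <- lab(c("LRRD", "BOTH")); msd <- lab(c("MSD", "BOTH"))
    tab <- build_table(lrrd, msd)
    coop <- list(table = unclass(tab))
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      ch <- chi_square_independence(tab)
      m <- unclass(tab); n <- sum(m)
      coop$chi2 <- ch$chi2; coop$p <- ch$p
      coop$dP_over_P <- delta_p_over_p(m[1, 1] / n, sum(m[, 1]) / n,
                                       sum(m[1, ]) / n)
    }
  }

  # calcium summary
  ca_counts <- table(factor(platelets$calcium_type,
                            levels = c("null", "alpha", "beta")))
  ca_sum <- list(type_counts = as.list(ca_counts),
                 type_fractions = multinomial_sem(as.integer(ca_counts)))
  ab <- platelets[platelets$calcium_type != "null", , drop = FALSE]
  if (nrow(ab) >= 3 && length(unique(ab$calcium_type)) == 2 &&
      all(is.finite(ab$t_max))) {
    ca_sum$roc <- roc_threshold(ab$t_max, ab$calcium_type == "alpha")[
      c("t0", "sensitivity", "specificity", "auc")]
  }

  report <- list(
    n_cycles_total = nrow(cycles),
    adhesion = adh,
    outcome_counts = as.list(outcome_counts),
    domain_summary = if (!is.null(events))
      condition_summary(events, n_cycles = nrow(cycles)) else NULL,
    kinetics = kin,
    cooperativity = coop,
    calcium = c(ca_sum, list(platelets = platelets)),
    config = cfg
  )

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(events))
      utils::write.csv(events, file.path(cfg$output_dir, "events.csv"),
                       row.names = FALSE)
    utils::write.csv(cycles, file.path(cfg$output_dir, "cycles.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      report[setdiff(names(report), "config")],
      file.path(cfg$output_dir, "summary.json"),
      auto_unbox = TRUE, digits = 10, na = "null", force = TRUE)
    return(invisible(report))
  }
  report
}
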