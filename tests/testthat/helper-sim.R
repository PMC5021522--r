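# shared fixture builders for the test suite

# clamp-mode parameters tuned for detector validation: every cycle bonds,
# no ramp ruptures, short contact/idle so traces stay small
detector_params <- function(...) {
  defaults <- list(adhesion_probability = 1, rupture_probability = 0,
                   contact_duration = 0.3, idle_duration = 0.1,
                   ramped_event_probs = c(none = 0.2, msd = 0.3, lrrd = 0.3,
                                          both = 0.2))
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_params, args)
}

# match detected events against ground truth for one simulated cycle;
# returns per-event tp/fn counts and measurement errors
match_events <- function(cycle, detected) {
  tru_r <- Filter(function(e) e$phase == "ramped", cycle$truth$events)
  tru_c <- Filter(function(e) e$phase == "clamped", cycle$truth$events)
  det_r <- detected[detected$phase == "ramped", , drop = FALSE]
  det_c <- detected[detected$phase == "clamped", , drop = FALSE]
  tp <- 0L; fn <- 0L; len_err <- numeric(0)
  for (e in tru_r) {
    m <- which(abs(det_r$force - e$force) < 6)
    if (length(m)) {
      tp <- tp + 1L
      len_err <- c(len_err, det_r$length[m[1]] - e$length)
      det_r <- det_r[-m[1], , drop = FALSE]
    } else fn <- fn + 1L
  }
  for (e in tru_c) {
    m <- which(abs(det_c$t_u - e$t_u) < 0.05)
    if (length(m)) {
      tp <- tp + 1L
      len_err <- c(len_err, det_c$length[m[1]] - e$length)
      det_c <- det_c[-m[1], , drop = FALSE]
    } else fn <- fn + 1L
  }
  list(tp = tp, fn = fn, fp = nrow(det_r) + nrow(det_c), len_err = len_err)
}

# trimodal unfolding-length ensemble mimicking the ramped-length histogram
trimodal_lengths <- function(n = 300, seed = 1) {
  set.seed(seed)
  n1 <- round(n * 0.4); n2 <- round(n * 0.33); n3 <- n - n1 - n2
  len <- c(rnorm(n1, 20, 3), rnorm(n2, 36, 5), rnorm(n3, 65, 6))
  len[len > 1]
}

# synthetic force-extension curve with one unfolding jump: pre-branch WLC of
# contour Lc, post-branch Lc + dL, sampled over realistic force windows
jump_curve <- function(Lc = 279.3, dL = 39.3, p = 10, noise = 1,
                       f_pre = c(2, 15), f_post = c(12, 28), n_branch = 30) {
  f1 <- seq(f_pre[1], f_pre[2], length.out = n_branch)
  f2 <- seq(f_post[1], f_post[2], length.out = n_branch)
  data.frame(
    extension_nm = c(wlc_extension(f1, Lc, p = p) + rnorm(n_branch, 0, noise),
                     wlc_extension(f2, Lc + dL, p = p) + rnorm(n_branch, 0, noise)),
    force_pN = c(f1, f2))
}
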