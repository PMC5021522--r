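test_that("cycle outcomes are classified against ground truth", {
  p <- sim_params(adhesion_probability = 0.5, rupture_probability = 0.4,
                  contact_duration = 0.3, idle_duration = 0.1)
  for (s in 1:30) {
    cy <- simulate_cycle(p, seed = 700 + s)
    expect_equal(classify_cycle(cy$trace), cy$truth$outcome,
                 label = paste("seed", s))
  }
})

test_that("rupture force is recovered from a simulated ramp-mode rupture", {
  p <- sim_params(mode = "ramp", adhesion_probability = 1,
                  contact_duration = 0.3, idle_duration = 0.1,
                  ramped_event_probs = c(none = 1, msd = 0, lrrd = 0, both = 0))
  for (s in 1:10) {
    cy <- simulate_cycle(p, seed = 40 + s)
    seg <- segment_trace(cy$trace)
    expect_equal(seg$outcome, "rupture")
    expect_lt(abs(seg$rupture_force - cy$truth$rupture_force), 3)
  }
})

test_that("lifetimes are measured to sampling resolution", {
  p <- detector_params(msd_rate = 0,
                       ramped_event_probs = c(none = 1, msd = 0, lrrd = 0,
                                              both = 0))
  errs <- vapply(1:25, function(s) {
    cy <- simulate_cycle(p, seed = 900 + s)
    # lifetimes below the sustained-attainment resolution read as ruptures
    if (cy$truth$outcome != "lifetime" || cy$truth$t_b < 0.05) return(NA_real_)
    measure_lifetime(cy$trace) - cy$truth$t_b
  }, numeric(1))
  errs <- errs[!is.na(errs)]
  expect_gt(length(errs), 10)
  expect_lt(max(abs(errs)), 0.03)
  # ensemble mean within 3 s.e. of the generating model mean
  kp <- gpiba_kinetic_params()$lrrd_minus
  tb <- vapply(1:25, function(s) {
    cy <- simulate_cycle(p, seed = 900 + s, trace = FALSE)
    cy$truth$t_b
  }, numeric(1))
  tb <- tb[is.finite(tb)]
  mu <- kp$w1 / kp$k1 + (1 - kp$w1) / kp$k2
  sd_th <- sqrt(kp$w1 * 2 / kp$k1^2 + (1 - kp$w1) * 2 / kp$k2^2 - mu^2)
  expect_lt(abs(mean(tb) - mu), 3 * sd_th / sqrt(length(tb)))
  # not-a-lifetime error on a rupture trace
  pr <- sim_params(mode = "ramp", adhesion_probability = 1,
                   contact_duration = 0.3, idle_duration = 0.1)
  cy <- simulate_cycle(pr, seed = 77)
  expect_error(measure_lifetime(cy$trace), "never attained")
})

test_that("a pure linear ramp yields no kink events and few false positives", {
  p <- detector_params(msd_rate = 0,
                       ramped_event_probs = c(none = 1, msd = 0, lrrd = 0,
                                              both = 0))
  n_fp <- 0L
  for (s in 1:40) {
    cy <- simulate_cycle(p, seed = 1200 + s)
    n_fp <- n_fp + nrow(detect_ramped_unfolding(cy$trace))
  }
  expect_lte(n_fp, 1L)   # < 1% per-cycle false-positive budget, with margin
})

test_that("simulated kinks are detected in the expected force range", {
  p <- detector_params(msd_rate = 0,
                       ramped_event_probs = c(none = 0, msd = 0, lrrd = 1,
                                              both = 0))
  n_in_range <- 0L; n_det <- 0L
  for (s in 1:20) {
    cy <- simulate_cycle(p, seed = 1500 + s)
    ev <- detect_ramped_unfolding(cy$trace)
    if (nrow(ev) == 1) {
      n_det <- n_det + 1L
      if (ev$force > 4 && ev$force < 24) n_in_range <- n_in_range + 1L
    }
  }
  expect_gte(n_det, 18L)
  expect_equal(n_in_range, n_det)
})

test_that("clamped force drops convert to length by the spring constant", {
  # arithmetic identity: a 6 pN drop at 0.3 pN/nm reads as 20 nm
  p <- detector_params(msd_rate = 5,
                       unfold_lengths = list(msd = c(mean = 20, sd = 0.01),
                                             lrrd = c(mean = 36, sd = 6)),
                       ramped_event_probs = c(none = 1, msd = 0, lrrd = 0,
                                              both = 0))
  hits <- 0L
  for (s in 1:20) {
    cy <- simulate_cycle(p, seed = 1600 + s)
    ev <- detect_clamped_unfolding(cy$trace)
    tru <- Filter(function(e) e$phase == "clamped", cy$truth$events)
    if (length(tru) == 1 && nrow(ev) == 1) {
      hits <- hits + 1L
      expect_lt(abs(ev$length - 20), 2.5)
      expect_lt(abs(ev$t_u - tru[[1]]$t_u), 0.01)
      expect_lt(ev$t_u, measure_lifetime(cy$trace))
    }
  }
  expect_gte(hits, 8L)
})

test_that("a clean collapse to zero is dissociation, not unfolding", {
  p <- detector_params(msd_rate = 0,
                       ramped_event_probs = c(none = 1, msd = 0, lrrd = 0,
                                              both = 0))
  for (s in 1:15) {
    cy <- simulate_cycle(p, seed = 1700 + s)
    if (cy$truth$outcome != "lifetime") next
    expect_equal(nrow(detect_clamped_unfolding(cy$trace)), 0L)
  }
})

test_that("reported clamped events always have t_u below the lifetime", {
  p <- detector_params()
  for (s in 1:30) {
    cy <- simulate_cycle(p, seed = 1800 + s)
    a <- analyze_cycle(cy$trace)
    cl <- a$events[a$events$phase == "clamped", , drop = FALSE]
    if (nrow(cl)) {
      expect_equal(a$outcome, "lifetime")
      expect_true(all(cl$t_u < a$t_b))
    }
  }
})
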