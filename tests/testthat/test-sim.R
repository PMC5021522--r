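test_that("parameter validation enforces the physical invariants", {
  expect_error(sim_params(spring_constant = -1))
  expect_error(sim_params(adhesion_probability = 1.2))
  expect_error(sim_params(lifetime_model = list(
    lrrd_minus = list(w1 = 0.5, k1 = -1, k2 = 0.2),
    lrrd_plus = list(w1 = 0.5, k1 = 1, k2 = 0.2))), "positive")
  p <- sim_params(ramp_rate = 1000, spring_constant = 0.3)
  # retraction speed is ramp rate over spring constant (~3.3 um/s)
  expect_equal(p$retraction_speed * p$spring_constant, p$ramp_rate)
})

test_that("no-adhesion limit produces only no-bond cycles with flat force", {
  p <- sim_params(adhesion_probability = 0, contact_duration = 0.2,
                  idle_duration = 0.1)
  for (s in 1:5) {
    cy <- simulate_cycle(p, seed = s)
    expect_false(cy$truth$bond_formed)
    tr <- cy$trace
    post <- tr$force_pN[tr$time_s > 0.4]   # after compressive unload
    expect_lt(max(post), 5)                 # noise only
  }
})

test_that("infinite unfolding-rate limit yields immediate clamped events", {
  p <- sim_params(adhesion_probability = 1, rupture_probability = 0,
                  msd_rate = Inf,
                  ramped_event_probs = c(none = 1, msd = 0, lrrd = 0, both = 0))
  for (s in 1:10) {
    cy <- simulate_cycle(p, seed = s, trace = FALSE)
    ev <- Filter(function(e) e$phase == "clamped", cy$truth$events)
    expect_length(ev, 1L)
    expect_equal(ev[[1]]$t_u, 0)
  }
})

test_that("force equals spring constant times probe deflection throughout", {
  cy <- simulate_cycle(detector_params(), seed = 5)
  tr <- cy$trace
  expect_equal(tr$force_pN, tr$probe_nm * attr(tr, "spring_constant"))
  expect_true(all(diff(tr$time_s) > 0))
})

test_that("ground-truth event times respect the bonded interval", {
  p <- detector_params()
  for (s in 1:50) {
    tru <- simulate_cycle(p, seed = 600 + s, trace = FALSE)$truth
    for (e in tru$events) {
      if (e$phase == "clamped") {
        expect_gte(e$t_u, 0)
        expect_lt(e$t_u, tru$t_b)
      } else {
        expect_gt(e$force, 0)
        if (tru$outcome == "rupture") expect_lt(e$force, tru$rupture_force)
      }
    }
  }
})

test_that("simulated lifetimes follow the generating dual-exponential law", {
  kp <- gpiba_kinetic_params()$lrrd_minus
  p <- sim_params(adhesion_probability = 1, rupture_probability = 0,
                  msd_rate = 0,
                  ramped_event_probs = c(none = 1, msd = 0, lrrd = 0, both = 0))
  set.seed(9)
  tb <- replicate(4000, bfpmech:::draw_cycle_events(p)$t_b)
  cdf <- function(q) kp$w1 * pexp(q, kp$k1) + (1 - kp$w1) * pexp(q, kp$k2)
  ks <- suppressWarnings(stats::ks.test(tb, cdf))
  expect_gt(ks$p.value, 0.01)
  # mean simulated time-to-unfold matches 1/ku within 3 s.e.
  set.seed(10)
  tu <- rexp(10000, 0.870)
  expect_lt(abs(mean(tu) - 1 / 0.870), 3 * sd(tu) / sqrt(10000))
})

test_that("bond fraction converges to the adhesion probability", {
  p <- sim_params(adhesion_probability = 0.18)
  set.seed(13)
  bonds <- replicate(2000, bfpmech:::draw_cycle_events(p)$bond_formed)
  expect_lt(abs(mean(bonds) - 0.18), 3 * sqrt(0.18 * 0.82 / 2000))
})

test_that("sessions are deterministic given the seed and span ~200 s", {
  s1 <- simulate_session(50, sim_params(), calcium_coupling(), seed = 7)
  s2 <- simulate_session(50, sim_params(), calcium_coupling(), seed = 7)
  expect_identical(s1$cycle_table, s2$cycle_table)
  expect_identical(s1$calcium, s2$calcium)
  expect_gt(s1$duration, 150)
  expect_lt(s1$duration, 320)
  s3 <- simulate_session(50, sim_params(), calcium_coupling(), seed = 8)
  expect_false(identical(s1$cycle_table$t_b, s3$cycle_table$t_b))
})

test_that("calcium coupling rules drive the session calcium type", {
  # coupling disabled -> null trace with a basal intensity
  off <- simulate_session(30, sim_params(), calcium_coupling(enabled = FALSE),
                          seed = 3)
  expect_equal(off$calcium$truth$calcium_type, "null")
  ct <- normalize_and_peak(off$calcium$time, off$calcium$intensity)
  expect_lt(ct$dI_max, 0.05)

  # a session whose only lifetime is long and carries a clamped MSD
  # unfolding triggers a spike-then-decay (alpha) response
  found <- FALSE
  for (s in 1:60) {
    ses <- simulate_session(50, sim_params(), calcium_coupling(), seed = 500 + s)
    tab <- ses$cycle_table
    if (any(tab$msd_clamped & tab$t_b > 5, na.rm = TRUE)) {
      expect_equal(ses$calcium$truth$calcium_type, "alpha")
      ct <- normalize_and_peak(ses$calcium$time, ses$calcium$intensity)
      expect_gt(ct$dI_max, 0.4)
      expect_equal(classify_calcium(ct), "alpha")
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("session round-trips losslessly through CSV + JSON", {
  ses <- simulate_session(5, detector_params(), calcium_coupling(), seed = 3,
                          traces = TRUE)
  dir <- withr::local_tempdir()
  write_session(ses, dir)
  back <- read_session(dir)
  expect_equal(back$cycle_table$t_b, ses$cycle_table$t_b)
  expect_equal(back$cycle_table$outcome, ses$cycle_table$outcome)
  expect_equal(back$calcium$intensity, ses$calcium$intensity)
  for (i in seq_along(ses$cycles)) {
    expect_equal(back$cycles[[i]]$trace$force_pN, ses$cycles[[i]]$trace$force_pN)
    expect_equal(back$cycles[[i]]$truth$events, ses$cycles[[i]]$truth$events)
  }
  expect_s3_class(back$params, "sim_params")

  # streamed checksum equals the in-memory force sum
  ck <- session_checksum(file.path(dir, "traces.csv"), chunk_lines = 1000)
  expect_equal(ck$force_sum,
               sum(vapply(ses$cycles, function(c) sum(c$trace$force_pN), 1)),
               tolerance = 1e-8)

  # malformed file: missing force column is named in the error
  tr <- utils::read.csv(file.path(dir, "traces.csv"))
  utils::write.csv(tr[setdiff(names(tr), "force_pN")],
                   file.path(dir, "traces.csv"), row.names = FALSE)
  expect_error(read_session(dir), "force_pN")
})
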