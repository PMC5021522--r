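test_that("normalization, peak and onset detection behave on basic shapes", {
  t <- 0:99
  # constant trace: no increase, no onset
  ct <- normalize_and_peak(t, rep(3.2, 100))
  expect_equal(ct$dI_max, 0)
  expect_true(is.na(ct$onset_time))
  # doubling trace
  ct2 <- normalize_and_peak(t, c(rep(1, 50), rep(2, 50)))
  expect_equal(ct2$dI_max, 1.0, tolerance = 1e-9)
  expect_equal(ct2$onset_time, 50)
  expect_error(normalize_and_peak(t, rep(0, 100)), "baseline")
  # scale invariance of normalization (and so of classification)
  set.seed(2)
  raw <- c(rep(1, 30), 1 + 0.8 * exp(-(0:69) / 15)) * (1 + rnorm(100, 0, 0.01))
  a <- normalize_and_peak(t, raw)
  b <- normalize_and_peak(t, raw * 137)
  expect_equal(a$intensity, b$intensity)
  expect_equal(classify_calcium(a), classify_calcium(b))
})

test_that("calcium traces classify into null, alpha and beta types", {
  t <- seq(0, 200)
  mk <- function(I) normalize_and_peak(t, I)
  set.seed(4)
  noise <- function() 1 + rnorm(201, 0, 0.005)
  # basal trace with a tiny fluctuation
  expect_equal(classify_calcium(mk(1.0 * noise() + 0.02 * sin(t / 30))), "null")
  # latency, spike to +0.8, fast decay
  alpha <- ifelse(t < 60, 1, ifelse(t < 63, 1 + 0.8 * (t - 60) / 3,
                                    1 + 0.12 + 0.68 * 2^(-(t - 63) / 12)))
  expect_equal(classify_calcium(mk(alpha * noise())), "alpha")
  # gradual rise to +0.3, slow decay
  beta <- ifelse(t < 40, 1, ifelse(t < 70, 1 + 0.3 * (t - 40) / 30,
                                   1 + 0.3 * 2^(-(t - 70) / 80)))
  expect_equal(classify_calcium(mk(beta * noise())), "beta")
})

test_that("simulated alpha onsets are recovered within one frame", {
  found <- 0L
  for (s in 1:40) {
    ses <- simulate_session(50, sim_params(), calcium_coupling(), seed = 2200 + s)
    if (ses$calcium$truth$calcium_type != "alpha") next
    ct <- normalize_and_peak(ses$calcium$time, ses$calcium$intensity)
    expect_lt(abs(ct$onset_time - ses$calcium$truth$onset_time), 2.01)
    found <- found + 1L
    if (found >= 8L) break
  }
  expect_gte(found, 5L)
})

test_that("pre-onset lifetime statistics", {
  # single pre-onset lifetime
  one <- pre_ca_stats(3, end_times = 10, onset_time = 20)
  expect_equal(c(one$t_max, one$sum_t, one$mean_t), c(3, 3, 3))
  # several lifetimes, all pre-onset
  st <- pre_ca_stats(c(0.3, 0.5, 4.0), c(10, 30, 50), onset_time = 60)
  expect_equal(st$t_max, 4.0)
  expect_equal(st$sum_t, 4.8)
  expect_equal(st$mean_t, 1.6)
  # post-onset lifetimes excluded
  st2 <- pre_ca_stats(c(0.3, 0.5, 4.0), c(10, 30, 50), onset_time = 40)
  expect_equal(st2$t_max, 0.5)
  # no onset: whole session counts
  st3 <- pre_ca_stats(c(1, 2), c(5, 10), onset_time = NA)
  expect_equal(st3$n_lifetimes, 2L)
  # onset before any completion: flagged empty
  expect_true(pre_ca_stats(c(1, 2), c(5, 10), onset_time = 1)$empty)
})

test_that("cumulative pre-onset lifetime is dominated by the longest", {
  ratios <- c()
  for (s in 1:30) {
    ses <- simulate_session(50, sim_params(), calcium_coupling(), seed = 2600 + s)
    lt <- ses$cycle_table[ses$cycle_table$outcome == "lifetime", ]
    if (nrow(lt) < 2) next
    pc <- pre_ca_stats(lt$t_b, lt$t_end, ses$calcium$truth$onset_time)
    if (pc$empty) next
    ratios <- c(ratios, pc$t_max / pc$sum_t)
  }
  expect_gt(median(ratios), 0.5)
})

test_that("correlation utility matches base R and detects coupling", {
  x <- 1:10
  expect_equal(correlate(x, 2 * x)$r, 1)
  expect_error(correlate(rep(1, 5), 1:5), "zero variance")
  set.seed(6)
  tmax <- runif(60, 0, 8)
  dI <- 0.1 + 0.1 * tmax + rnorm(60, 0, 0.1)
  co <- correlate(tmax, dI)
  expect_gt(co$r, 0.5)
  expect_lt(co$p, 1e-4)
  # permutation destroys the correlation
  expect_lt(abs(correlate(tmax, sample(dI))$r), 0.35)
})

test_that("ROC analysis finds the error-minimizing threshold", {
  # separable classes: perfect sensitivity and specificity
  r <- roc_threshold(c(1, 2, 3, 10, 11, 12), c(rep(FALSE, 3), rep(TRUE, 3)))
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$auc, 1)
  expect_true(r$t0 >= 3 && r$t0 < 10)
  expect_error(roc_threshold(1:4, rep(TRUE, 4)), "degenerate")

  # constructed set reproducing the published operating point: 12 of 17
  # alpha above 2 s and 17 of 21 beta at or below 2 s
  set.seed(8)
  alpha_t <- c(runif(12, 2.2, 9), runif(5, 0.2, 1.9))
  beta_t <- c(runif(17, 0.1, 1.9), runif(4, 2.2, 6))
  vals <- c(alpha_t, beta_t)
  labs <- rep(c("alpha", "beta"), c(17, 21))
  r2 <- roc_threshold(vals, labs)
  expect_equal(r2$sensitivity, 12 / 17, tolerance = 1e-9)   # 0.7059
  expect_equal(r2$specificity, 17 / 21, tolerance = 1e-9)   # 0.8095
  expect_true(r2$t0 > 1.8 && r2$t0 < 2.2)

  # reversing labels maps AUC to 1 - AUC; curve is monotone
  r3 <- roc_threshold(vals, labs == "beta")
  expect_equal(r3$auc, 1 - r2$auc, tolerance = 1e-9)
  o <- order(r2$curve$fpr)
  expect_true(all(diff(r2$curve$tpr[o]) <= 1e-12 | diff(r2$curve$tpr[o]) >= 0))

  # random labels: best achievable accuracy stays near the class prior
  set.seed(9)
  v <- runif(200); l <- sample(c(TRUE, FALSE), 200, replace = TRUE)
  rr <- roc_threshold(v, l)
  acc <- 1 - min(rr$curve$errors) / 200
  expect_lt(acc, max(mean(l), 1 - mean(l)) + 0.1)
})

test_that("ROC cross-checks against the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(10)
  vals <- c(rnorm(40, 3, 1.5), rnorm(50, 1, 1))
  labs <- rep(c(TRUE, FALSE), c(40, 50))
  mine <- roc_threshold(vals, labs)
  ref <- pROC::roc(response = labs, predictor = vals, quiet = TRUE,
                   direction = "<")
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-9)
})

test_that("grouping by unfolding history summarizes the coupling", {
  rec <- data.frame(
    lrrd = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
    msd = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    dI_max = c(1.2, 0.9, 0.6, 0.05, 0.3, 0.1),
    t_max = c(5, 4, 2, 0.5, 1, 0.3))
  g <- segregate_by_unfolding(rec)
  expect_equal(sum(g$fraction), 1)
  expect_equal(sum(g$n), 6)
  both <- g[g$lrrd & g$msd, ]
  expect_equal(both$mean_dI_max, 1.05)
  expect_true(both$mean_dI_max == max(g$mean_dI_max, na.rm = TRUE))
})
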