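test_that("exponential rate estimators agree and handle edge cases", {
  # degenerate: all dwell times equal -> reciprocal mean rate
  same <- rep(2, 10)
  expect_equal(fit_exponential(same, "reciprocal_mean")$rate, 0.5)
  set.seed(5)
  t <- rexp(5000, rate = 0.870)
  f1 <- fit_exponential(t, "reciprocal_mean")
  f2 <- fit_exponential(t, "survival_slope")
  expect_lt(abs(f1$rate - 0.870) / 0.870, 0.05)
  # cross-method agreement within the joint confidence region
  expect_lt(abs(f1$rate - f2$rate),
            (f1$ci[2] - f1$ci[1]) / 2 + (f2$ci[2] - f2$ci[1]) / 2)
  expect_true(f1$ci[1] < f1$rate && f1$rate < f1$ci[2])
  expect_error(fit_exponential(c(1, 2, -1, 3, 4)), "positive")
  expect_error(fit_exponential(1:3), "at least 5")
})

test_that("dual-exponential MLE recovers generating parameters", {
  set.seed(31)
  n <- 2000; w1 <- 0.7; k1 <- 2; k2 <- 0.2
  comp <- runif(n) < w1
  t <- ifelse(comp, rexp(n, k1), rexp(n, k2))
  fit <- fit_dual_exponential(t, seed = 1)
  # parameter recovery (sampling s.e. of each is a few percent at n=2000)
  expect_lt(abs(fit$w1 - w1), 0.06)
  expect_lt(abs(fit$k1 - k1) / k1, 0.15)
  expect_lt(abs(fit$k2 - k2) / k2, 0.15)
  expect_true(fit$k1 >= fit$k2)
  # moment identity: fitted mean matches the sample mean within its s.e.
  expect_lt(abs(dualexp_mean(fit) - mean(t)), 3 * sd(t) / sqrt(n))
  expect_gt(fit$lrt, 10)   # clearly better than single exponential
})

test_that("dual-exponential fit flags single-exponential data as degenerate", {
  set.seed(8)
  t <- rexp(500, 1.5)
  expect_warning(fit <- fit_dual_exponential(t, seed = 2), "degenerate")
  expect_true(fit$single)
})

test_that("Bell model evaluation and log-linear fit are mutually consistent", {
  expect_equal(bell_rate(c(0, 10, 50), k0 = 0.3, x_dagger = 0),
               rep(0.3, 3))
  f <- c(10, 25, 40, 60)
  r <- bell_rate(f, k0 = 0.26, x_dagger = 0.242)
  fit <- suppressWarnings(fit_bell(f, r))   # noiseless: lm warns on perfect fit
  expect_equal(fit$k0, 0.26, tolerance = 1e-10)
  expect_equal(fit$x_dagger, 0.242, tolerance = 1e-10)
  expect_error(fit_bell(c(10, 10), c(1, 1.1)), "single force")
})

test_that("joint-probability closed form equals the double integral", {
  kp <- gpiba_kinetic_params()
  expect_equal(predict_unfold_probability(kp$ku, kp$lrrd_minus), 0.215,
               tolerance = 1e-12)
  expect_equal(predict_unfold_probability(kp$ku, kp$lrrd_plus), 0.462,
               tolerance = 1e-12)
  # limits and symmetry
  lt <- list(w1 = 0.5, k1 = 1, k2 = 1)
  expect_equal(predict_unfold_probability(1, lt), 0.5)
  expect_equal(predict_unfold_probability(0, lt), 0)
  expect_gt(predict_unfold_probability(1e9, lt), 0.999)

  # randomized parameter draws: quadrature over t_u < t_b matches closed form
  set.seed(17)
  for (i in 1:100) {
    ku <- runif(1, 0.05, 5)
    k1 <- runif(1, 0.5, 8); k2 <- runif(1, 0.02, 0.5)
    lt <- list(w1 = runif(1), k1 = k1, k2 = k2)
    num <- stats::integrate(function(tb) {
      vapply(tb, function(b)
        joint_density(0, b, ku, lt) / ku *      # p(t_b) alone
          (1 - exp(-ku * b)), numeric(1))       # inner integral of p_u
    }, 0, Inf, rel.tol = 1e-9)$value
    expect_equal(num, predict_unfold_probability(ku, lt), tolerance = 1e-4)
  }
})

test_that("joint density normalizes and has the right boundary value", {
  kp <- gpiba_kinetic_params()
  lt <- kp$lrrd_minus
  num <- stats::integrate(function(tu) {
    vapply(tu, function(u) stats::integrate(function(tb)
      joint_density(u, tb, kp$ku, lt), 0, Inf, rel.tol = 1e-8)$value,
      numeric(1))
  }, 0, Inf, rel.tol = 1e-6)$value
  expect_equal(num, 1, tolerance = 1e-4)
  expect_equal(joint_density(0, 0, kp$ku, lt),
               kp$ku * (lt$w1 * lt$k1 + (1 - lt$w1) * lt$k2))
})

test_that("at-least-one and expected-count formulas behave", {
  expect_equal(prob_at_least_one(0, 10), 0)
  expect_equal(prob_at_least_one(0.3, 0), 0)
  expect_equal(prob_at_least_one(0.5, 2), 0.75)
  # monotone in both arguments
  p <- seq(0, 1, 0.1)
  expect_true(all(diff(prob_at_least_one(p, 3)) >= 0))
  expect_true(all(diff(prob_at_least_one(0.3, 0:10)) >= 0))

  ec <- expected_unfold_count(10, 0.2, n_se = 1, p_se = 0.02)
  expect_equal(ec$expected, 2)
  expect_equal(ec$se, sqrt((0.2 * 1)^2 + (10 * 0.02)^2))   # 0.2828
  expect_equal(expected_unfold_count(5, 0)$se, 0)
})

test_that("dual-exponential fit is a fixed point on its own output", {
  set.seed(77)
  kp <- gpiba_kinetic_params()$lrrd_plus
  n <- 3000
  comp <- runif(n) < kp$w1
  t <- ifelse(comp, rexp(n, kp$k1), rexp(n, kp$k2))
  fit <- fit_dual_exponential(t, seed = 3)
  expect_lt(abs(fit$w1 - kp$w1), 0.08)
  expect_lt(abs(fit$k1 - kp$k1) / kp$k1, 0.2)
  expect_lt(abs(fit$k2 - kp$k2) / kp$k2, 0.2)
})
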