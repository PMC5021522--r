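#' Fit a single-exponential rate to dwell times
#'
#' Estimates the rate of an exponentially distributed dwell time (e.g. the
#' clamped time-to-unfold of the mechanosensitive domain) either as the
#' reciprocal sample mean (the maximum-likelihood estimator) or from the slope
#' of the log survival frequency vs time, the semi-log straight-line fit used
#' for visual rate estimation.
#'
#' @param times positive dwell times (s), `n >= 5`.
#' @param method `"reciprocal_mean"` (MLE; exact gamma confidence interval) or
#'   `"survival_slope"` (negative slope of `ln S(t)` regression; CI from the
#'   regression slope).
#' @param conf confidence level for the interval (default 0.95).
#' @return an object of class `"exp_fit"`: list with `rate` (1/s), `ci`
#'   (2-vector), `n`, `method`.
#' @export
fit_exponential <- function(times, method = c("reciprocal_mean", "survival_slope"),
                            conf = 0.95) {
  method <- match.arg(method)
  if (length(times) < 5L) stop("need at least 5 dwell times", call. = FALSE)
  if (any(!is.finite(times)) || any(times <= 0))
    stop("dwell times must be positive and finite", call. = FALSE)
  n <- length(times)
  a <- (1 - conf) / 2
  if (method == "reciprocal_mean") {
    rate <- 1 / mean(times)
    # 2*n*rate_hat/rate ~ chi^2_{2n}: exact interval for the exponential rate
    ci <- stats::qgamma(c(a, 1 - a), shape = n, rate = n / rate)
  } else {
    ts <- sort(times)
    surv <- 1 - (seq_len(n) - 1) / n          # S(t-) at each observed time
    keep <- surv > 0
    fit <- stats::lm(log(surv[keep]) ~ 0 + ts[keep])
    rate <- -unname(stats::coef(fit)[1])
    se <- summary(fit)$coefficients[1, 2]
    ci <- rate + c(-1, 1) * stats::qnorm(1 - a) * se
  }
  structure(list(rate = rate, ci = ci, n = n, method = method),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("exponential rate = %.4g 1/s  [%.4g, %.4g]  (n = %d, %s)\n",
              x$rate, x$ci[1], x$ci[2], x$n, x$method))
  invisible(x)
}

dualexp_nll <- function(par, t) {
  w1 <- stats::plogis(par[1]); k1 <- exp(par[2]); k2 <- exp(par[3])
  d <- w1 * k1 * exp(-k1 * t) + (1 - w1) * k2 * exp(-k2 * t)
  -sum(log(pmax(d, 1e-300)))
}

#' Maximum-likelihood fit of a dual-exponential dwell-time distribution
#'
#' Fits \eqn{p(t) = w_1 k_1 e^{-k_1 t} + (1-w_1) k_2 e^{-k_2 t}} to bond
#' lifetimes by direct MLE with random restarts. Receptor-ligand bond
#' lifetimes under clamped force commonly dissociate along a fast and a slow
#' pathway; `w1` is the fast-pathway fraction. The identifiability convention
#' `k1 >= k2` is enforced by relabeling after optimisation.
#'
#' If the two rates collapse (relative difference below `collapse_tol`) the
#' fit degenerates to a single exponential; the result is then flagged with
#' `single = TRUE` (and a warning) with `w1 = 1` and both rates equal.
#'
#' @param lifetimes positive dwell times (s), `n >= 20`.
#' @param n_restarts random restarts for the optimiser (default 10).
#' @param collapse_tol relative rate difference below which the model is
#'   declared degenerate (default 0.05).
#' @param seed optional integer seed for the restart draws (local RNG).
#' @return object of class `"dualexp_fit"`: list with `w1`, `k1`, `k2`
#'   (`k1 >= k2`), `logLik`, `single` flag, `lrt` (likelihood-ratio statistic
#'   vs the single-exponential nested model), `n`.
#' @export
fit_dual_exponential <- function(lifetimes, n_restarts = 10,
                                 collapse_tol = 0.05, seed = NULL) {
  t <- lifetimes
  if (length(t) < 20L) stop("need at least 20 lifetimes", call. = FALSE)
  if (any(!is.finite(t)) || any(t <= 0))
    stop("lifetimes must be positive and finite", call. = FALSE)
  n <- length(t)
  k0 <- 1 / mean(t)
  starts <- list(c(0, log(k0 * 4), log(k0 / 4)))
  rng <- if (is.null(seed)) NULL else local_seed(seed)
  for (i in seq_len(max(0, n_restarts - 1))) {
    starts[[i + 1L]] <- c(stats::rnorm(1, 0, 1.5),
                          log(k0) + stats::rnorm(1, 1.2, 0.8),
                          log(k0) + stats::rnorm(1, -1.2, 0.8))
  }
  if (!is.null(rng)) rng()
  best <- NULL
  for (s in starts) {
    o <- try(stats::optim(s, dualexp_nll, t = t, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12)),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("dual-exponential fit failed to converge", call. = FALSE)
  w1 <- stats::plogis(best$par[1]); k1 <- exp(best$par[2]); k2 <- exp(best$par[3])
  if (k2 > k1) { tmp <- k1; k1 <- k2; k2 <- tmp; w1 <- 1 - w1 }
  ll2 <- -best$value
  ll1 <- sum(stats::dexp(t, rate = k0, log = TRUE))  # MLE single-exponential
  # degenerate when the rates collapse, a component vanishes, or the mixture
  # adds no real likelihood over the nested single exponential
  single <- (k1 - k2) / k1 < collapse_tol || w1 > 1 - 1e-3 || w1 < 1e-3 ||
    2 * (ll2 - ll1) < 4
  if (single) {
    warning("dual-exponential fit is degenerate; collapsing to single exponential",
            call. = FALSE)
    w1 <- 1; k1 <- k2 <- k0
  }
  structure(list(w1 = w1, k1 = k1, k2 = k2, logLik = ll2, single = single,
                 lrt = 2 * (ll2 - ll1), n = n),
            class = "dualexp_fit")
}

#' @export
print.dualexp_fit <- function(x, ...) {
  cat(sprintf("dual-exponential fit (n = %d): w1 = %.3f, k1 = %.3g 1/s, k2 = %.3g 1/s%s\n",
              x$n, x$w1, x$k1, x$k2,
              if (x$single) "  [degenerate: single exponential]" else ""))
  cat(sprintf("  logLik = %.2f, LRT vs single exponential = %.2f\n", x$logLik, x$lrt))
  invisible(x)
}

#' Mean dwell time implied by a dual-exponential fit
#' @param fit a `"dualexp_fit"` object (or list with `w1`, `k1`, `k2`).
#' @return mean (s): `w1/k1 + (1-w1)/k2`.
#' @export
dualexp_mean <- function(fit) fit$w1 / fit$k1 + (1 - fit$w1) / fit$k2

#' Bell-model force dependence of a transition rate
#'
#' `bell_rate()` evaluates \eqn{k(f) = k^0 \exp(f x^\ddagger / k_BT)}: the
#' single-barrier (Bell) exponential acceleration of a rate by force, with
#' zero-force rate `k0` and barrier width `x_dagger`. `fit_bell()` estimates
#' the pair by log-linear regression of measured rates on force.
#'
#' @param force force (pN), vectorised.
#' @param k0 zero-force rate (1/s).
#' @param x_dagger distance to the transition state (nm).
#' @param kBT thermal energy (pN nm), default 4.28 (37 C).
#' @return `bell_rate`: rate(s) (1/s). `fit_bell`: object of class
#'   `"bell_fit"` with `k0`, `x_dagger`, standard errors, and `kBT`.
#' @export
bell_rate <- function(force, k0, x_dagger, kBT = 4.28) {
  stopifnot(k0 > 0, x_dagger >= 0, kBT > 0)
  k0 * exp(force * x_dagger / kBT)
}

#' @rdname bell_rate
#' @param rates measured rates (1/s) at `force`; all positive.
#' @export
fit_bell <- function(force, rates, kBT = 4.28) {
  stopifnot(length(force) == length(rates))
  if (length(unique(force)) < 2L)
    stop("Bell fit is underdetermined with a single force level", call. = FALSE)
  if (any(rates <= 0)) stop("rates must be positive", call. = FALSE)
  fit <- stats::lm(log(rates) ~ force)
  cf <- summary(fit)$coefficients
  structure(list(
    k0 = exp(cf[1, 1]),
    k0_se = exp(cf[1, 1]) * cf[1, 2],      # delta method
    x_dagger = cf[2, 1] * kBT,
    x_dagger_se = cf[2, 2] * kBT,
    kBT = kBT, fit = fit
  ), class = "bell_fit")
}

#' @export
print.bell_fit <- function(x, ...) {
  cat(sprintf("Bell fit: k0 = %.3g +/- %.2g 1/s, x-dagger = %.3g +/- %.2g nm (kBT = %.2f)\n",
              x$k0, x$k0_se, x$x_dagger, x$x_dagger_se, x$kBT))
  invisible(x)
}

#' Probability of observing clamped unfolding before bond dissociation
#'
#' Closed form of the joint-probability model: with the time-to-unfold
#' exponential at rate `ku` and the bond lifetime dual-exponential
#' `(w1, k1, k2)`, and the two processes independent, the probability that
#' unfolding precedes dissociation (`t_u < t_b`) is
#' \deqn{P_u = w_1 \frac{k_u}{k_u + k_1} + (1 - w_1)\frac{k_u}{k_u + k_2}.}
#' This equals the volume of [joint_density()] over the wedge
#' `0 < t_u < t_b < Inf`.
#'
#' @param ku unfolding rate (1/s).
#' @param lifetime a `"dualexp_fit"` object or list with `w1`, `k1`, `k2`.
#' @return probability in `[0, 1]`.
#' @export
predict_unfold_probability <- function(ku, lifetime) {
  stopifnot(ku >= 0, lifetime$w1 >= 0, lifetime$w1 <= 1,
            lifetime$k1 > 0, lifetime$k2 > 0)
  lifetime$w1 * ku / (ku + lifetime$k1) +
    (1 - lifetime$w1) * ku / (ku + lifetime$k2)
}

#' Joint density of time-to-unfold and bond lifetime
#'
#' Independence-product density
#' \eqn{p(t_u, t_b) = k_u e^{-k_u t_u} \, p(t_b)} with `p(t_b)` the
#' dual-exponential lifetime density. Integrates to 1 over the positive
#' quadrant; its volume over `t_u < t_b` is [predict_unfold_probability()].
#'
#' @param t_u,t_b times (s), `>= 0`; recycled to common length.
#' @inheritParams predict_unfold_probability
#' @return density values (1/s^2).
#' @export
joint_density <- function(t_u, t_b, ku, lifetime) {
  stopifnot(all(t_u >= 0), all(t_b >= 0), ku > 0)
  pu <- ku * exp(-ku * t_u)
  pb <- lifetime$w1 * lifetime$k1 * exp(-lifetime$k1 * t_b) +
    (1 - lifetime$w1) * lifetime$k2 * exp(-lifetime$k2 * t_b)
  pu * pb
}

#' Probability of at least one event in n trials
#'
#' `1 - (1 - p)^n`: e.g. the chance that a platelet experiences at least one
#' clamped domain unfolding over a session of `n` bond-lifetime events, each
#' unfolding independently with probability `p`.
#'
#' @param p_event per-event probability in `[0, 1]`.
#' @param n_events number of events, `>= 0`.
#' @return probability.
#' @export
prob_at_least_one <- function(p_event, n_events) {
  stopifnot(all(p_event >= 0), all(p_event <= 1), all(n_events >= 0))
  1 - (1 - p_event)^n_events
}

#' Expected number of unfolding events with propagated uncertainty
#'
#' Product `n * p` with Gaussian error propagation:
#' \eqn{\sigma = \sqrt{(p\,\sigma_n)^2 + (n\,\sigma_p)^2}}.
#'
#' @param n_lifetime_events count (may carry uncertainty `n_se`).
#' @param p_event per-event unfolding probability (uncertainty `p_se`).
#' @param n_se,p_se standard errors (default 0).
#' @return list with `expected` and `se`.
#' @export
expected_unfold_count <- function(n_lifetime_events, p_event, n_se = 0, p_se = 0) {
  stopifnot(n_lifetime_events >= 0, p_event >= 0, p_event <= 1)
  list(expected = n_lifetime_events * p_event,
       se = sqrt((p_event * n_se)^2 + (n_lifetime_events * p_se)^2))
}
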