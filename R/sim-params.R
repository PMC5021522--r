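#' Simulation parameters for synthetic BFP test cycles
#'
#' Builds a validated parameter set for the synthetic-data generator. The
#' defaults emulate the force-clamp interrogation of platelet GPIb-alpha by
#' wild-type VWF-A1: BFP spring constant 0.3 pN/nm, nominal loading rate
#' 1000 pN/s (retraction speed = ramp rate / spring constant, about
#' 3.3 um/s), 2 s contact at 20 pN impingement, infrequent adhesion (<20%),
#' dual-exponential bond lifetimes conditioned on prior LRRD unfolding,
#' exponential clamped MSD unfolding at 0.870 1/s (25 pN), and ramped LRRD
#' unfolding as a Gaussian threshold-force crossing in the 5-20 pN range.
#'
#' @param mode `"clamp"` or `"ramp"` cycle waveform.
#' @param spring_constant BFP spring constant (pN/nm).
#' @param ramp_rate nominal loading rate (pN/s).
#' @param clamp_force clamp hold level (pN), clamp mode only.
#' @param contact_duration contact (compressive hold) time (s).
#' @param impingement_force compressive contact force (pN, positive number).
#' @param adhesion_probability per-cycle bond probability in `[0, 1]`.
#' @param lifetime_model list with `lrrd_minus` and `lrrd_plus`, each
#'   `(w1, k1, k2)` dual-exponential lifetime parameters (1/s). Defaults to
#'   [gpiba_kinetic_params()].
#' @param msd_rate clamped MSD unfolding rate k_u (1/s).
#' @param lrrd_force_mean,lrrd_force_sd Gaussian threshold-force distribution
#'   for ramped LRRD unfolding (pN).
#' @param ramped_event_probs probabilities (summing to 1) that a bonded cycle
#'   carries no ramped unfolding, a ramped MSD, a ramped LRRD, or a merged
#'   BOTH event: named vector `(none, msd, lrrd, both)`.
#' @param unfold_lengths list with `msd` and `lrrd`, each `c(mean, sd)` of the
#'   released-length distribution (nm); draws are truncated away from the
#'   domain-assignment boundaries.
#' @param rupture_probability clamp mode: probability that a bonded cycle
#'   ruptures during the ramp before the clamp level is reached.
#' @param rupture_force_mean,rupture_force_sd ramp-mode rupture force
#'   distribution (pN).
#' @param idle_duration inter-cycle idle time (s); with the 2 s contact the
#'   default gives a 50-cycle session of roughly 200 s.
#' @param noise_sd Gaussian force noise (pN).
#' @param sample_rate acquisition rate (Hz).
#' @param feedback_tau clamp feedback recovery time constant (s) after a
#'   clamped unfolding force drop.
#' @param tether `"rigid"` (default; stiff-tether idealization, bonded ramp
#'   slope equals the nominal rate) or a list
#'   `list(model = "wlc", Lc0, p, kBT)` coupling the spring to a worm-like
#'   chain of contour length `Lc0`.
#' @return object of class `"sim_params"` (a validated list).
#' @export
sim_params <- function(mode = c("clamp", "ramp"),
                       spring_constant = 0.3,
                       ramp_rate = 1000,
                       clamp_force = 25,
                       contact_duration = 2,
                       impingement_force = 20,
                       adhesion_probability = 0.18,
                       lifetime_model = NULL,
                       msd_rate = 0.870,
                       lrrd_force_mean = 12,
                       lrrd_force_sd = 4,
                       ramped_event_probs = c(none = 0.70, msd = 0.08,
                                              lrrd = 0.14, both = 0.08),
                       unfold_lengths = list(msd = c(mean = 20, sd = 3),
                                             lrrd = c(mean = 36, sd = 6)),
                       rupture_probability = 0.25,
                       rupture_force_mean = 40,
                       rupture_force_sd = 12,
                       idle_duration = 1.4,
                       noise_sd = 1,
                       sample_rate = 1000,
                       feedback_tau = 0.5,
                       tether = "rigid") {
  mode <- match.arg(mode)
  if (is.null(lifetime_model)) {
    kp <- gpiba_kinetic_params()
    lifetime_model <- list(lrrd_minus = kp$lrrd_minus, lrrd_plus = kp$lrrd_plus)
  }
  stopifnot(spring_constant > 0, ramp_rate > 0, clamp_force > 0,
            contact_duration >= 0, impingement_force >= 0,
            adhesion_probability >= 0, adhesion_probability <= 1,
            msd_rate >= 0, lrrd_force_sd >= 0, noise_sd >= 0,
            sample_rate > 0, feedback_tau > 0,
            rupture_probability >= 0, rupture_probability <= 1)
  for (grp in lifetime_model) {
    stopifnot(grp$w1 >= 0, grp$w1 <= 1)
    if (grp$k1 <= 0 || grp$k2 <= 0)
      stop("lifetime off-rates must be positive", call. = FALSE)
  }
  stopifnot(abs(sum(ramped_event_probs) - 1) < 1e-9, all(ramped_event_probs >= 0))
  if (!identical(tether, "rigid")) {
    stopifnot(is.list(tether), tether$model == "wlc",
              tether$Lc0 > 0, tether$p > 0)
    if (is.null(tether$kBT)) tether$kBT <- 4.28
  }
  p <- list(mode = mode, spring_constant = spring_constant,
            ramp_rate = ramp_rate,
            retraction_speed = ramp_rate / spring_constant,   # nm/s
            clamp_force = clamp_force, contact_duration = contact_duration,
            impingement_force = impingement_force,
            adhesion_probability = adhesion_probability,
            lifetime_model = lifetime_model, msd_rate = msd_rate,
            lrrd_force_mean = lrrd_force_mean, lrrd_force_sd = lrrd_force_sd,
            ramped_event_probs = ramped_event_probs,
            unfold_lengths = unfold_lengths,
            rupture_probability = rupture_probability,
            rupture_force_mean = rupture_force_mean,
            rupture_force_sd = rupture_force_sd,
            idle_duration = idle_duration, noise_sd = noise_sd, sample_rate = sample_rate,
            feedback_tau = feedback_tau, tether = tether)
  class(p) <- "sim_params"
  p
}

#' Coupling rule linking bond mechanics to the calcium response
#'
#' Defines how a simulated platelet's calcium type is conditioned on its
#' unfolding and lifetime history: an alpha-type (spike) response is triggered
#' by the first clamped MSD unfolding event provided the longest bond
#' lifetime up to and including that cycle exceeds `t_threshold`; sessions
#' with lifetime events but no such trigger flux a low-amplitude beta-type
#' response; sessions without lifetime events stay null.
#'
#' @param enabled logical; disabled coupling yields null traces only.
#' @param t_threshold lifetime threshold (s) gating the alpha response
#'   (default 2 s).
#' @param latency delay (s) from the triggering bond's dissociation to
#'   calcium onset.
#' @param alpha_amp,beta_amp ranges (min, max) of the peak normalized
#'   intensity increase for alpha and beta responses.
#' @param alpha_rise,alpha_decay_half alpha shape: linear rise time and decay
#'   half-life (s).
#' @param beta_rise,beta_decay_half beta shape parameters (s).
#' @param ca_sample_rate calcium sampling rate (Hz).
#' @param ca_noise_sd multiplicative intensity noise s.d.
#' @return object of class `"calcium_coupling"`.
#' @export
calcium_coupling <- function(enabled = TRUE, t_threshold = 2, latency = 1,
                             alpha_amp = c(0.5, 1.5), beta_amp = c(0.08, 0.4),
                             alpha_rise = 2, alpha_decay_half = 15,
                             beta_rise = 15, beta_decay_half = 60,
                             ca_sample_rate = 1, ca_noise_sd = 0.01) {
  stopifnot(t_threshold >= 0, latency >= 0, ca_sample_rate > 0)
  structure(list(enabled = enabled, t_threshold = t_threshold,
                 latency = latency, alpha_amp = alpha_amp, beta_amp = beta_amp,
                 alpha_rise = alpha_rise, alpha_decay_half = alpha_decay_half,
                 beta_rise = beta_rise, beta_decay_half = beta_decay_half,
                 ca_sample_rate = ca_sample_rate, ca_noise_sd = ca_noise_sd),
            class = "calcium_coupling")
}
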