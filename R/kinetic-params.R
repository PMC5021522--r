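#' Solve the fast-pathway fraction that yields a target unfolding probability
#'
#' Closed-form inversion of the joint-probability model
#' (see [predict_unfold_probability()]): given the unfolding rate `ku` and the
#' two off-rates `k1 >= k2`, returns the weight `w1` for which
#' \eqn{P_u = w_1 k_u/(k_u+k_1) + (1-w_1) k_u/(k_u+k_2)} equals `pu`.
#'
#' @param pu target unfolding probability, must lie between the two
#'   single-pathway probabilities.
#' @param ku unfolding rate (1/s).
#' @param k1,k2 fast and slow off-rates (1/s).
#' @return `w1` in `[0, 1]`.
#' @export
solve_weight_for_pu <- function(pu, ku, k1, k2) {
  a1 <- ku / (ku + k1); a2 <- ku / (ku + k2)
  w1 <- (a2 - pu) / (a2 - a1)
  if (w1 < 0 || w1 > 1)
    stop("target probability unreachable with these rates", call. = FALSE)
  w1
}

#' Reference kinetic parameters for GPIb-alpha under clamped force (synthetic)
#'
#' A small table of dwell-time kinetic parameters for the wild-type VWF-A1 vs
#' platelet GPIb-alpha interaction at 25 pN clamped force, split by whether
#' the leucine-rich-repeat domain (LRRD) unfolded during the preceding ramp.
#'
#' The mechanosensitive-domain (MSD) unfolding rate is the published
#' 25 pN value, `ku = 0.870` 1/s. The dual-exponential lifetime parameters
#' are a *synthetic reconstruction*: the full per-condition fit table is part
#' of the original figure source data and is not reproduced here, so the
#' off-rate scales are set to plausible fast/slow values for this bond
#' (fast pathway of order seconds^-1, slow pathway of order 0.2 s^-1, with
#' LRRD unfolding prolonging lifetime) and the weights are then solved with
#' [solve_weight_for_pu()] so that the model reproduces the published clamped
#' MSD unfolding probabilities at 25 pN: 21.5% without and 46.2% with prior
#' LRRD unfolding.
#'
#' @return list with elements `ku` (1/s), `lrrd_minus` and `lrrd_plus`, each a
#'   list `(w1, k1, k2)`, and `bell` (the published Bell pair for MSD
#'   unfolding via A1: `k0` 1/s, `x_dagger` nm, `kBT` pN nm).
#' @examples
#' par <- gpiba_kinetic_params()
#' predict_unfold_probability(par$ku, par$lrrd_minus)  # 0.215
#' @export
gpiba_kinetic_params <- function() {
  ku <- 0.870
  lm_k1 <- 5.0; lm_k2 <- 0.25     # LRRD-: mostly fast dissociation
  lp_k1 <- 2.0; lp_k2 <- 0.20     # LRRD+: slower, larger slow fraction
  list(
    ku = ku,
    lrrd_minus = list(w1 = solve_weight_for_pu(0.215, ku, lm_k1, lm_k2),
                      k1 = lm_k1, k2 = lm_k2),
    lrrd_plus  = list(w1 = solve_weight_for_pu(0.462, ku, lp_k1, lp_k2),
                      k1 = lp_k1, k2 = lp_k2),
    bell = list(k0 = 0.26, x_dagger = 0.242, kBT = 4.28)
  )
}
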