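#' Build a 2x2 contingency table of LRRD and MSD unfolding occurrence
#'
#' Cross-tabulates per-cycle unfolding labels into the 2x2 table used for the
#' cooperativity test: rows are LRRD+ / LRRD-, columns MSD+ / MSD-.
#'
#' @param lrrd,msd logical vectors (one element per cycle): whether the LRRD /
#'   MSD unfolded in that cycle. `NA` is not allowed.
#' @return object of class `"coop_table"`: 2x2 integer matrix with dimnames,
#'   plus `marginals` attribute (row, column and grand totals).
#' @examples
#' # worked 25 pN example: counts 14, 11, 25, 95
#' tab <- build_table(lrrd = rep(c(TRUE, FALSE), c(25, 120)),
#'                    msd  = rep(c(TRUE, FALSE, TRUE, FALSE), c(14, 11, 25, 95)))
#' chi_square_independence(tab)
#' @export
build_table <- function(lrrd, msd) {
  if (length(lrrd) != length(msd)) stop("label vectors differ in length", call. = FALSE)
  if (anyNA(lrrd) || anyNA(msd)) stop("unlabeled cycle (NA label)", call. = FALSE)
  if (!is.logical(lrrd) || !is.logical(msd))
    stop("labels must be logical", call. = FALSE)
  m <- matrix(c(sum(lrrd & msd), sum(lrrd & !msd),
                sum(!lrrd & msd), sum(!lrrd & !msd)),
              nrow = 2, byrow = TRUE,
              dimnames = list(LRRD = c("+", "-"), MSD = c("+", "-")))
  structure(m, class = c("coop_table", class(m)),
            marginals = list(row = rowSums(m), col = colSums(m), n = sum(m)))
}

#' Construct a cooperativity table directly from counts
#' @param n11,n12,n21,n22 counts: (LRRD+,MSD+), (LRRD+,MSD-), (LRRD-,MSD+),
#'   (LRRD-,MSD-).
#' @return a `"coop_table"` as in [build_table()].
#' @export
coop_table <- function(n11, n12, n21, n22) {
  counts <- c(n11, n12, n21, n22)
  if (any(counts < 0) || sum(counts) < 1) stop("invalid counts", call. = FALSE)
  build_table(lrrd = rep(c(TRUE, FALSE), c(n11 + n12, n21 + n22)),
              msd = rep(c(TRUE, FALSE, TRUE, FALSE), c(n11, n12, n21, n22)))
}

#' Pearson chi-square test of independence on a 2x2 table
#'
#' Tests the null hypothesis that LRRD and MSD unfolding occur independently:
#' \eqn{\chi^2 = \sum (O - E)^2 / E} with expected counts from the marginal
#' products, 1 degree of freedom, no continuity correction (the convention
#' under which the published worked value 13.01 is obtained).
#'
#' @param table a 2x2 matrix of counts (e.g. from [build_table()]).
#' @return list with `chi2`, `df` (= 1), `p`, `expected`.
#' @export
chi_square_independence <- function(table) {
  m <- unclass(table)
  stopifnot(is.matrix(m), all(dim(m) == 2L))
  if (sum(m) == 0) stop("empty table", call. = FALSE)
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(E == 0)) stop("zero marginal: expected counts undefined", call. = FALSE)
  chi2 <- sum((m - E)^2 / E)
  list(chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       expected = E)
}

#' Relative excess of joint unfolding probability over independence
#'
#' Cooperativity index \eqn{\Delta P/P = P(\mathrm{both}) /
#' [P(\mathrm{MSD}) P(\mathrm{LRRD})] - 1}: zero under exact independence,
#' positive when the two domains unfold together more often than chance.
#'
#' @param p_both joint probability of both domains unfolding.
#' @param p_msd,p_lrrd marginal unfolding probabilities; must be positive
#'   (conditions where a marginal is zero carry no defined cooperativity and
#'   return `NA` with a warning).
#' @return the ratio, or `NA` when undefined.
#' @export
delta_p_over_p <- function(p_both, p_msd, p_lrrd) {
  stopifnot(p_both >= 0, p_both <= 1)
  if (p_msd <= 0 || p_lrrd <= 0) {
    warning("marginal probability is zero: cooperativity undefined", call. = FALSE)
    return(NA_real_)
  }
  p_both / (p_msd * p_lrrd) - 1
}

#' Multinomial standard errors of category fractions
#'
#' For observed counts \eqn{(n_1, ..., n_K)} with total `n`, estimates each
#' category probability by its fraction and the associated s.e.m. as
#' \eqn{\sqrt{(n_i/n)(1 - n_i/n)/n}}.
#'
#' @param counts non-negative integer counts.
#' @return data frame with `count`, `fraction`, `se`.
#' @export
multinomial_sem <- function(counts) {
  stopifnot(all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("total count must be positive", call. = FALSE)
  p <- counts / n
  data.frame(count = counts, fraction = p, se = sqrt(p * (1 - p) / n))
}

#' Adhesion frequency over repeated test cycles
#'
#' Fraction of cycles that produced a bond, with binomial s.e.m. Adhesion is
#' kept infrequent in single-bond experiments so that most binding events are
#' mediated by one bond.
#'
#' @param bonded logical per-cycle bond indicator (or a vector of outcome
#'   strings, where anything other than `"no_bond"` counts as bonded).
#' @return list with `frequency`, `se`, `n`.
#' @export
adhesion_frequency <- function(bonded) {
  if (is.character(bonded) || is.factor(bonded)) bonded <- bonded != "no_bond"
  stopifnot(is.logical(bonded), length(bonded) >= 1)
  n <- length(bonded); p <- mean(bonded)
  list(frequency = p, se = sqrt(p * (1 - p) / n), n = n)
}

#' Probability that an adhesion event involves exactly one bond
#'
#' Under a Poisson model for the number of bonds per contact, an observed
#' adhesion frequency `Pa` implies a Poisson mean \eqn{\lambda = -\ln(1-P_a)},
#' and the probability that an adhesion is mediated by exactly one bond is
#' \deqn{P(N = 1 \mid N \ge 1) = \lambda e^{-\lambda} / (1 - e^{-\lambda}).}
#' At `Pa = 0.20` this exceeds 89%, the usual justification that infrequent
#' adhesion ensures predominantly single-bond events.
#'
#' @param adhesion_freq adhesion frequency in `(0, 1)`.
#' @return conditional single-bond probability.
#' @export
single_bond_probability <- function(adhesion_freq) {
  if (any(adhesion_freq <= 0) || any(adhesion_freq >= 1))
    stop("adhesion frequency must lie strictly between 0 and 1", call. = FALSE)
  lambda <- -log(1 - adhesion_freq)
  lambda * exp(-lambda) / (1 - exp(-lambda))
}
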