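# Misclassification-induced attenuation of SNP coefficients and its
# correction via the mediation decomposition of SNP effects.

#' Misclassification rates of the imputed labels
#'
#' Converts the prediction model's accuracy on imputed subjects into the
#' cohort-level misclassification probabilities \eqn{\gamma_0} (true control
#' labeled case) and \eqn{\gamma_1} (true case labeled control):
#' the imputed-stratum rates are \eqn{1 - \pi_0} (one minus specificity) and
#' \eqn{1 - \pi_1} (one minus sensitivity), and the cohort-level rates scale
#' them by the imputed fraction of each true class, since clinically labeled
#' subjects are never misclassified.  With `n_m` imputed subjects of whom a
#' fraction `rho` are truly affected, alongside `n_a` labeled cases and `n_c`
#' labeled controls:
#' \deqn{\gamma_1 = (1-\pi_1)\,\frac{\rho\, n_m}{n_a + \rho\, n_m}, \qquad
#'       \gamma_0 = (1-\pi_0)\,\frac{(1-\rho)\, n_m}{n_c + (1-\rho)\, n_m}.}
#' When `n_m` is omitted the whole cohort is treated as imputed (both
#' fractions 1).
#'
#' @param sens sensitivity \eqn{\pi_1} of the prediction model on imputed
#'   subjects.
#' @param spec specificity \eqn{\pi_0}.
#' @param rho assumed true case fraction among imputed subjects.
#' @param n_m,n_a,n_c cohort composition (optional, see above).
#' @return an object of class `"misclass_rates"`: list with `gamma0`,
#'   `gamma1`.
#' @examples
#' misclass_rates(sens = 0.8, spec = 0.9)          # all subjects imputed
#' misclass_rates(0.8, 0.9, rho = 0.15, n_m = 1570, n_a = 1241, n_c = 2382)
#' @export
misclass_rates <- function(sens, spec, rho = 1, n_m = NULL,
                           n_a = 0, n_c = 0) {
  for (v in c(sens, spec, rho))
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("'sens', 'spec' and 'rho' must lie in [0, 1]")
  if (is.null(n_m)) {
    f1 <- f0 <- 1
  } else {
    f1 <- rho * n_m / (n_a + rho * n_m)
    f0 <- (1 - rho) * n_m / (n_c + (1 - rho) * n_m)
  }
  out <- list(gamma0 = (1 - spec) * f0, gamma1 = (1 - sens) * f1)
  if (out$gamma0 + out$gamma1 >= 1)
    stop("inadmissible rates: gamma0 + gamma1 must be < 1")
  structure(out, class = "misclass_rates")
}

#' @export
print.misclass_rates <- function(x, ...) {
  cat(sprintf("misclassification rates: gamma0 = %.4f (control->case), ",
              x$gamma0))
  cat(sprintf("gamma1 = %.4f (case->control)\n", x$gamma1))
  invisible(x)
}

#' Attenuation factor of a logistic coefficient under outcome misclassification
#'
#' When a binary outcome is misclassified with rates \eqn{(\gamma_0,
#' \gamma_1)}, a small logistic regression coefficient is attenuated
#' approximately by the multiplicative factor
#' \deqn{\hat B = \frac{1 - \gamma_1 - \gamma_0}
#'       {(1 + \gamma_1 - \gamma_0)(1 - \gamma_1 + \gamma_0)},}
#' which equals 1 under perfect classification, is symmetric in its
#' denominator (\eqn{(1+\delta)(1-\delta)} with \eqn{\delta = \gamma_1 -
#' \gamma_0}), and reduces to \eqn{1 - 2\gamma} for symmetric rates
#' \eqn{\gamma_0 = \gamma_1 = \gamma}.  It is exactly the small-coefficient
#' attenuation of a balanced logistic model with flipped labels, which is how
#' the package's tests validate it by Monte Carlo.
#'
#' @param rates a `"misclass_rates"` object, or \eqn{\gamma_0} directly.
#' @param gamma1 \eqn{\gamma_1} when `rates` is given as a number.
#' @return the scalar factor \eqn{\hat B \in (0, 1]}.
#' @examples
#' bias_factor(misclass_rates(0.8, 0.9))
#' bias_factor(0.1, 0.2)
#' @export
bias_factor <- function(rates, gamma1 = NULL) {
  if (inherits(rates, "misclass_rates")) {
    g0 <- rates$gamma0; g1 <- rates$gamma1
  } else {
    g0 <- rates; g1 <- gamma1
  }
  if (any(g0 < 0 | g0 >= 1) || any(g1 < 0 | g1 >= 1))
    stop("gamma0 and gamma1 must lie in [0, 1)")
  if (any(g0 + g1 >= 1))
    stop("gamma0 + gamma1 >= 1: attenuation factor undefined")
  (1 - g1 - g0) / ((1 + g1 - g0) * (1 - g1 + g0))
}

#' Proportion of the SNP effect acting directly on disease
#'
#' In the mediation decomposition the total SNP effect splits into a direct
#' path and an indirect path through the endophenotypes.  The direct
#' proportion is estimated as the ratio of the SNP heritability adjusted for
#' the mediating traits to the unadjusted SNP heritability:
#' \eqn{d^* = h^2_{\mathrm{adj}} / h^2_{\mathrm{unadj}}}.  Heritabilities are
#' user inputs here (e.g. from a GREML analysis).
#'
#' @param h2_unadjusted SNP heritability without trait adjustment, in (0, 1\].
#' @param h2_adjusted SNP heritability after adjusting for the mediating
#'   traits; must not exceed `h2_unadjusted`.
#' @return \eqn{d^* \in [0, 1]}.
#' @examples
#' estimate_direct_proportion(0.67, 0.36)
#' @export
estimate_direct_proportion <- function(h2_unadjusted, h2_adjusted) {
  if (h2_unadjusted <= 0 || h2_unadjusted > 1)
    stop("'h2_unadjusted' must lie in (0, 1]")
  if (h2_adjusted < 0) stop("'h2_adjusted' must be non-negative")
  if (h2_adjusted > h2_unadjusted)
    stop("adjusted heritability exceeds unadjusted: mediation proportion undefined")
  h2_adjusted / h2_unadjusted
}

#' Bias-adjust a SNP coefficient for label misclassification
#'
#' Only the fraction \eqn{d^*} of the SNP effect that acts directly on disease
#' is attenuated by imputation errors (the prediction model, built from the
#' mediators, captures the indirect path), so the observed coefficient relates
#' to the true one by \eqn{\beta^* \approx (\hat B d^* + 1 - d^*)\beta} and
#' the adjusted estimate is
#' \deqn{\hat\beta_{\mathrm{adj}} = \frac{\beta^*}{\hat B d^* + 1 - d^*}.}
#' The adjustment applies to reported effect sizes and odds ratios only —
#' hypothesis-test p-values are never modified.
#'
#' @param beta_star observed (biased) coefficient(s).
#' @param b_factor attenuation factor from [bias_factor()].
#' @param d_star direct-effect proportion from
#'   [estimate_direct_proportion()].
#' @return adjusted coefficient(s), same length as `beta_star`.  Use
#'   `exp(adjust_coefficient(...))` for adjusted odds ratios.
#' @examples
#' adjust_coefficient(0.08, b_factor = 0.8, d_star = 1)  # 0.1
#' @export
adjust_coefficient <- function(beta_star, b_factor, d_star) {
  if (d_star < 0 || d_star > 1) stop("'d_star' must lie in [0, 1]")
  den <- b_factor * d_star + 1 - d_star
  if (den <= 0) stop("non-positive adjustment denominator")
  beta_star / den
}
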