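#' True causal effects by standardization
#'
#' The outcome model is linear in A, so the conditional causal effects of a
#' one-unit increase in A are gamma_A given U = 0 and gamma_A + gamma_UA
#' given U = 1; the unconditional (marginal) effect, by standardization over
#' U ~ Bernoulli(pi_U), is delta_A = gamma_A + pi_U * gamma_UA.
#'
#' @param gamma_A conditional effect of A on Y given U = 0.
#' @param gamma_UA interaction effect.
#' @param pi_U P(U = 1), in `[0, 1]`.
#' @return a `causal_targets` list: `delta_A`, `conditional_U0`,
#'   `conditional_U1`.
#' @examples
#' true_effects(1, 0.5, 0.5)  # delta_A = 1.25, conditionals 1 and 1.5
#' @export
true_effects <- function(gamma_A, gamma_UA, pi_U) {
  stopifnot(pi_U >= 0, pi_U <= 1)
  structure(list(delta_A = gamma_A + pi_U * gamma_UA,
                 conditional_U0 = gamma_A,
                 conditional_U1 = gamma_A + gamma_UA),
            class = "causal_targets")
}

#' @export
print.causal_targets <- function(x, ...) {
  cat(sprintf("marginal delta_A = %g; conditional effects %g (U=0), %g (U=1)\n",
              x$delta_A, x$conditional_U0, x$conditional_U1))
  invisible(x)
}

#' Regression-dilution attenuation of the missing-indicator coefficient
#'
#' In the extreme deterministic case R_A = 1 - U with no interaction
#' (gamma_UA = 0), the missing indicator equals U, so the indicator
#' coefficient in the MI(R+A) model targets gamma_U. Because the imputed
#' exposure is a noisy version of A among the missing (U = 1) rows,
#' regression dilution attenuates the indicator coefficient: approximately
#'
#'   E[gamma_R_hat] = gamma_U * sigma_Y^2 / (gamma_A^2 sigma_A^2 + sigma_Y^2).
#'
#' The exposure coefficient itself remains unbiased for gamma_A in this
#' setting. This is a property of the completed-data estimand targeted by
#' multiple imputation, not a defect of the imputation.
#'
#' @param gamma_U true effect of U on Y.
#' @param gamma_A true effect of A on Y.
#' @param sigma_A SD of A given U (> 0).
#' @param sigma_Y residual SD of Y (> 0).
#' @return the approximate expected missing-indicator coefficient.
#' @examples
#' dilution_attenuation(1, 1, 1, 1)  # 0.5
#' @export
dilution_attenuation <- function(gamma_U, gamma_A, sigma_A, sigma_Y) {
  stopifnot(sigma_A > 0, sigma_Y >= 0)
  gamma_U * sigma_Y^2 / (gamma_A^2 * sigma_A^2 + sigma_Y^2)
}
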