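#' Solve the exposure-model intercept so that E[A] = 0
#'
#' With A | U ~ N(alpha_0 + alpha_U U, sigma_A^2) and U ~ Bernoulli(pi_U),
#' E[A] = alpha_0 + alpha_U pi_U, so alpha_0 = -alpha_U pi_U.
#'
#' @param alpha_U effect of U on A.
#' @param pi_U P(U = 1), in (0, 1).
#' @return the intercept alpha_0.
#' @export
solve_alpha0 <- function(alpha_U, pi_U) {
  stopifnot(pi_U > 0, pi_U < 1)
  -alpha_U * pi_U
}

#' Solve the outcome-model intercept so that E[Y] = 0
#'
#' E[Y] = gamma_0 + gamma_U pi_U + gamma_A E[A] + gamma_UA E[UA] with
#' E[A] = alpha_0 + alpha_U pi_U and E[UA] = pi_U (alpha_0 + alpha_U).
#'
#' @param gamma_U,gamma_A,gamma_UA outcome-model effects.
#' @param pi_U P(U = 1).
#' @param alpha_0,alpha_U exposure-model intercept and U effect
#'   (alpha_0 normally already solved via [solve_alpha0()]).
#' @return the intercept gamma_0.
#' @export
solve_gamma0 <- function(gamma_U, gamma_A, gamma_UA, pi_U, alpha_0, alpha_U) {
  stopifnot(pi_U > 0, pi_U < 1)
  EA <- alpha_0 + alpha_U * pi_U
  EUA <- pi_U * (alpha_0 + alpha_U)
  -(gamma_U * pi_U + gamma_A * EA + gamma_UA * EUA)
}

.gh_cache <- new.env(parent = emptyenv())
.gh_nodes <- function(n = 64L) {
  key <- as.character(n)
  if (is.null(.gh_cache[[key]])) .gh_cache[[key]] <- pracma::gaussHermite(n)
  .gh_cache[[key]]
}

# Marginal P(R_A = 0) under the logistic law, integrating over
# U ~ Bernoulli(pi_U) and A | U ~ N(alpha_0 + alpha_U u, sigma_A^2).
# Each U stratum is a one-dimensional Gaussian integral of expit, evaluated
# by Gauss-Hermite quadrature.
marginal_p_missing <- function(beta_0, beta_U, beta_A, beta_UA,
                               pi_U, alpha_0, alpha_U, sigma_A,
                               gh_nodes = 64L) {
  gh <- .gh_nodes(gh_nodes)
  stratum <- function(const, slope, mu) {
    a <- mu + sqrt(2) * sigma_A * gh$x
    sum(gh$w * expit(const + slope * a)) / sqrt(pi)
  }
  (1 - pi_U) * stratum(beta_0, beta_A, alpha_0) +
    pi_U * stratum(beta_0 + beta_U, beta_A + beta_UA, alpha_0 + alpha_U)
}

#' Solve the missingness-model intercept for a target marginal missingness
#'
#' Finds beta_0 such that the marginal probability of a missing exposure,
#' P(R_A = 0) = E[expit(beta_0 + beta_U U + beta_A A + beta_UA U A)],
#' equals `target_p_missing`. The expectation is a two-component mixture of
#' one-dimensional Gaussian integrals evaluated by 64-node Gauss-Hermite
#' quadrature; beta_0 is found by bracketed root-finding on [-40, 40] and the
#' achieved probability is checked to within 1e-6.
#'
#' @param target_p_missing desired marginal P(R_A = 0), in (0, 1).
#' @param beta_U,beta_A,beta_UA logistic slopes.
#' @param pi_U,alpha_0,alpha_U,sigma_A exposure-model parameters.
#' @param gh_nodes number of quadrature nodes.
#' @return the solved intercept beta_0.
#' @export
solve_beta0 <- function(target_p_missing, beta_U = 0, beta_A = 0, beta_UA = 0,
                        pi_U = 0.5, alpha_0 = 0, alpha_U = 0, sigma_A = 1,
                        gh_nodes = 64L) {
  stopifnot(target_p_missing > 0, target_p_missing < 1,
            pi_U > 0, pi_U < 1, sigma_A > 0,
            is.finite(beta_U), is.finite(beta_A), is.finite(beta_UA))
  f <- function(b0) {
    marginal_p_missing(b0, beta_U, beta_A, beta_UA,
                       pi_U, alpha_0, alpha_U, sigma_A, gh_nodes) -
      target_p_missing
  }
  lo <- f(-40); hi <- f(40)
  if (lo > 0 || hi < 0) {
    stop("cannot bracket beta_0 on [-40, 40]; check slope parameters")
  }
  b0 <- uniroot(f, c(-40, 40), tol = 1e-10)$root
  achieved <- f(b0) + target_p_missing
  if (abs(achieved - target_p_missing) > 1e-6) {
    stop("beta_0 root did not achieve target missingness to 1e-6")
  }
  b0
}

#' Classify a parameter zero-pattern into a DAG scenario label
#'
#' The six scenarios are indexed by which edges are present:
#' U -> R_A (beta_U or beta_UA nonzero, or deterministic R_A = 1 - U),
#' A -> R_A (beta_A or beta_UA nonzero) and U -> A (alpha_U nonzero).
#' Scenario (i) has no edges into R_A and no U -> A edge (MCAR);
#' (ii)/(iii) have U -> R_A only, without/with U -> A; (iv) has A -> R_A
#' only; (v) both edges into R_A without confounding; (vi) is the fully
#' connected case. Patterns the six panels do not display separately
#' (confounding with MCAR missingness, or A-driven missingness with
#' confounding but no U -> R_A edge) are mapped to the nearest label with
#' the same confounding structure, (iii) and (vi) respectively.
#'
#' @param alpha_U,beta_U,beta_A,beta_UA structural parameters (betas may be
#'   `NA` under the deterministic law).
#' @param deterministic logical, `TRUE` for R_A = 1 - U.
#' @param u_observed logical; appends the "-U" suffix.
#' @return a label such as `"i"`, `"iv"`, `"ii-U"`.
#' @export
classify_scenario <- function(alpha_U, beta_U = 0, beta_A = 0, beta_UA = 0,
                              deterministic = FALSE, u_observed = FALSE) {
  nz <- function(x) !is.na(x) && x != 0
  u_to_r <- deterministic || nz(beta_U) || nz(beta_UA)
  a_to_r <- (!deterministic) && (nz(beta_A) || nz(beta_UA))
  u_to_a <- nz(alpha_U)
  base <- if (!u_to_r && !a_to_r) {
    if (u_to_a) "iii" else "i"
  } else if (u_to_r && !a_to_r) {
    if (u_to_a) "iii" else "ii"
  } else if (!u_to_r && a_to_r) {
    if (u_to_a) "vi" else "iv"
  } else {
    if (u_to_a) "vi" else "v"
  }
  if (u_observed) paste0(base, "-U") else base
}

#' Construct a fully solved scenario configuration
#'
#' Bundles all structural parameters for one simulation cell, solves the
#' three intercepts (alpha_0 for E[A] = 0, gamma_0 for E[Y] = 0, beta_0 for
#' the target marginal missingness) and attaches the DAG scenario label.
#'
#' @param pi_U P(U = 1), in (0, 1).
#' @param alpha_U effect of U on A.
#' @param sigma_A SD of A given U (> 0).
#' @param missingness `"logistic"` for the expit law or `"deterministic"`
#'   (alias `"deterministic_1_minus_U"`) for R_A = 1 - U.
#' @param beta_U,beta_A,beta_UA logistic missingness slopes; must be left at
#'   their defaults under the deterministic law (they are redundant there and
#'   stored as `NA`).
#' @param target_p_missing desired marginal P(R_A = 0). Under the
#'   deterministic law this is necessarily `pi_U` and must not be set to
#'   anything else.
#' @param gamma_U,gamma_A,gamma_UA outcome-model effects.
#' @param sigma_Y residual SD of Y (> 0).
#' @param u_observed logical: is U available to the analysis models?
#' @param n observations per replicate.
#' @param cell_id optional stable integer id within a grid.
#' @return an object of class `scenario_config`.
#' @examples
#' cfg <- scenario_config(alpha_U = 1, gamma_U = 1)
#' cfg$alpha_0  # -0.5 so that E[A] = 0
#' @export
scenario_config <- function(pi_U = 0.5, alpha_U = 0, sigma_A = 1,
                            missingness = c("logistic", "deterministic",
                                            "deterministic_1_minus_U"),
                            beta_U = 0, beta_A = 0, beta_UA = 0,
                            target_p_missing = NULL,
                            gamma_U = 0, gamma_A = 1, gamma_UA = 0,
                            sigma_Y = 1, u_observed = FALSE, n = 10000L,
                            cell_id = 0L) {
  missingness <- match.arg(missingness)
  if (missingness == "deterministic_1_minus_U") missingness <- "deterministic"
  stopifnot(length(n) == 1, length(pi_U) == 1,
            pi_U > 0, pi_U < 1, sigma_A > 0, sigma_Y > 0, n >= 2)
  deterministic <- missingness == "deterministic"
  if (deterministic) {
    if (any(c(beta_U, beta_A, beta_UA) != 0, na.rm = TRUE)) {
      stop("beta_U, beta_A, beta_UA are redundant under R_A = 1 - U and must not be set")
    }
    if (!is.null(target_p_missing) && abs(target_p_missing - pi_U) > 1e-12) {
      stop("under R_A = 1 - U the marginal missingness equals pi_U; do not set target_p_missing")
    }
    target_p_missing <- pi_U
    beta_U <- beta_A <- beta_UA <- NA_real_
    beta_0 <- NA_real_
  } else {
    if (is.null(target_p_missing)) target_p_missing <- 0.5
    stopifnot(target_p_missing > 0, target_p_missing < 1)
  }
  alpha_0 <- solve_alpha0(alpha_U, pi_U)
  gamma_0 <- solve_gamma0(gamma_U, gamma_A, gamma_UA, pi_U, alpha_0, alpha_U)
  if (!deterministic) {
    beta_0 <- solve_beta0(target_p_missing, beta_U, beta_A, beta_UA,
                          pi_U, alpha_0, alpha_U, sigma_A)
  }
  cfg <- structure(list(
    pi_U = pi_U, alpha_0 = alpha_0, alpha_U = alpha_U, sigma_A = sigma_A,
    missingness = missingness,
    beta_0 = beta_0, beta_U = beta_U, beta_A = beta_A, beta_UA = beta_UA,
    target_p_missing = target_p_missing,
    gamma_0 = gamma_0, gamma_U = gamma_U, gamma_A = gamma_A,
    gamma_UA = gamma_UA, sigma_Y = sigma_Y,
    u_observed = isTRUE(u_observed), n = as.integer(n),
    cell_id = as.integer(cell_id),
    scenario_label = classify_scenario(alpha_U, beta_U, beta_A, beta_UA,
                                       deterministic, isTRUE(u_observed))
  ), class = "scenario_config")
  validate_scenario_config(cfg)
  cfg
}

#' Validate a scenario configuration
#'
#' Checks parameter ranges, the deterministic-law exclusions, consistency of
#' the solved intercepts with their moment constraints, and agreement of the
#' stored scenario label with the parameter zero-pattern.
#'
#' @param cfg a `scenario_config`.
#' @return `cfg`, invisibly; errors on violation.
#' @export
validate_scenario_config <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  with(cfg, {
    stopifnot(pi_U > 0, pi_U < 1, sigma_A > 0, sigma_Y > 0, n >= 2)
    stopifnot(missingness %in% c("logistic", "deterministic"))
  })
  det <- cfg$missingness == "deterministic"
  if (det) {
    if (!all(is.na(c(cfg$beta_0, cfg$beta_U, cfg$beta_A, cfg$beta_UA)))) {
      stop("deterministic missingness must carry NA beta parameters")
    }
    if (abs(cfg$target_p_missing - cfg$pi_U) > 1e-12) {
      stop("deterministic missingness implies P(R_A = 0) = pi_U")
    }
  } else {
    stopifnot(all(is.finite(c(cfg$beta_0, cfg$beta_U, cfg$beta_A, cfg$beta_UA))))
    achieved <- marginal_p_missing(cfg$beta_0, cfg$beta_U, cfg$beta_A,
                                   cfg$beta_UA, cfg$pi_U, cfg$alpha_0,
                                   cfg$alpha_U, cfg$sigma_A)
    if (abs(achieved - cfg$target_p_missing) > 1e-6) {
      stop("beta_0 inconsistent with target_p_missing")
    }
  }
  if (abs(cfg$alpha_0 - solve_alpha0(cfg$alpha_U, cfg$pi_U)) > 1e-12) {
    stop("alpha_0 violates E[A] = 0")
  }
  g0 <- solve_gamma0(cfg$gamma_U, cfg$gamma_A, cfg$gamma_UA, cfg$pi_U,
                     cfg$alpha_0, cfg$alpha_U)
  if (abs(cfg$gamma_0 - g0) > 1e-12) stop("gamma_0 violates E[Y] = 0")
  expected <- classify_scenario(cfg$alpha_U, cfg$beta_U, cfg$beta_A,
                                cfg$beta_UA, det, cfg$u_observed)
  if (!identical(cfg$scenario_label, expected)) {
    stop("scenario_label '", cfg$scenario_label,
         "' inconsistent with parameter pattern (expected '", expected, "')")
  }
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario", x$scenario_label,
      sprintf("[%s missingness, P(R_A=0) = %.3g, n = %d]\n",
              x$missingness, x$target_p_missing, x$n))
  cat(sprintf("  U:   pi_U = %.3g\n", x$pi_U))
  cat(sprintf("  A:   N(%.4g + %.3g U, %.3g^2)\n",
              x$alpha_0, x$alpha_U, x$sigma_A))
  if (x$missingness == "logistic") {
    cat(sprintf("  R_A: P(miss) = expit(%.4g + %.3g U + %.3g A + %.3g UA)\n",
                x$beta_0, x$beta_U, x$beta_A, x$beta_UA))
  } else {
    cat("  R_A: 1 - U (deterministic)\n")
  }
  cat(sprintf("  Y:   N(%.4g + %.3g U + %.3g A + %.3g UA, %.3g^2)\n",
              x$gamma_0, x$gamma_U, x$gamma_A, x$gamma_UA, x$sigma_Y))
  invisible(x)
}
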