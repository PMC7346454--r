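#' Specify the exposure imputation model
#'
#' With U hidden the linear imputation model regresses A on Y alone;
#' with U observed it regresses A on Y, U and their interaction (the
#' interaction is always included in the U-observed model).
#'
#' @param u_observed logical.
#' @param m number of imputations (default 5).
#' @return an `imputation_spec` list with the predictor set and `m`.
#' @export
imputation_spec <- function(u_observed = FALSE, m = 5L) {
  stopifnot(m >= 1)
  predictors <- if (u_observed) c("Y", "U", "U:Y") else "Y"
  structure(list(predictors = predictors, u_observed = isTRUE(u_observed),
                 m = as.integer(m)),
            class = "imputation_spec")
}

.imputation_design <- function(data, spec, rows) {
  X <- cbind("(Intercept)" = rep(1, length(rows)), Y = data$Y[rows])
  if (spec$u_observed) {
    X <- cbind(X, U = data$U[rows], "U:Y" = data$U[rows] * data$Y[rows])
  }
  X
}

#' Fit the imputation model on the observed-exposure rows
#'
#' Least-squares fit of A on the spec's predictors restricted to rows with
#' R_A = 1. Structurally aliased columns (e.g. U terms when U is constant
#' among observed rows, as under R_A = 1 - U) are dropped and recorded.
#'
#' @param data a `sim_dataset`.
#' @param spec an [imputation_spec()] (or logical, taken as `u_observed`).
#' @return a `fit_result` carrying coefficients, residual variance, the
#'   inverse design cross-product and residual df; `ok = FALSE` with a reason
#'   when there are too few observed rows.
#' @export
fit_imputation_model <- function(data, spec = imputation_spec()) {
  if (is.logical(spec)) spec <- imputation_spec(spec)
  obs <- which(data$R_A == 1L)
  k <- length(spec$predictors)
  if (length(obs) < k + 2) {
    return(failed_fit("imputation", "too few observed exposure values",
                      length(obs)))
  }
  X <- .imputation_design(data, spec, obs)
  fit <- fit_ols(X, data$A_star[obs], label = "imputation")
  if (fit$ok) fit$spec <- spec
  fit
}

#' Draw proper multiple imputations of the missing exposure
#'
#' Canonical Bayesian construction of proper imputation under the standard
#' noninformative prior: for each of the m imputations, draw the residual
#' variance from its scaled inverse-chi-square posterior on the fit's
#' residual df, draw the coefficients from a normal centred at the
#' least-squares estimates with covariance scaled by the drawn variance, and
#' draw each missing A from the normal predictive distribution. Observed
#' exposure values are never altered.
#'
#' @param data a `sim_dataset`.
#' @param fit result of [fit_imputation_model()]; a failed fit propagates.
#' @param m number of imputations (default: the spec stored in `fit`).
#' @param seed integer seed.
#' @return a list of `m` completed datasets (class `completed_dataset`),
#'   each the input with an `A_imp` column and an `imputation` attribute;
#'   or a single failed `fit_result` if the imputation fit failed.
#' @export
draw_proper_imputations <- function(data, fit, m = NULL, seed = 1L) {
  stopifnot(inherits(fit, "fit_result"))
  if (!fit$ok) return(fit)
  if (is.null(m)) m <- fit$spec$m
  stopifnot(m >= 1)
  set.seed(as.integer(seed))
  mis <- which(data$R_A == 0L)
  A_imp_base <- ifelse(data$R_A == 1L, data$A_star, NA_real_)
  complete_one <- function(A_imp, j) {
    out <- data
    out$A_imp <- A_imp
    attr(out, "imputation") <- j
    class(out) <- c("completed_dataset", class(data))
    out
  }
  if (length(mis) == 0L) {
    return(lapply(seq_len(m), function(j) complete_one(A_imp_base, j)))
  }
  Xmis <- .imputation_design(data, fit$spec, mis)[, names(fit$coef),
                                                  drop = FALSE]
  Rchol <- chol(fit$XtX_inv)
  p <- length(fit$coef)
  lapply(seq_len(m), function(j) {
    sigma2_j <- fit$sigma2 * fit$df / rchisq(1, fit$df)
    phi_j <- fit$coef + sqrt(sigma2_j) * drop(t(Rchol) %*% rnorm(p))
    mu <- drop(Xmis %*% phi_j)
    A_imp <- A_imp_base
    A_imp[mis] <- rnorm(length(mis), mu, sqrt(sigma2_j))
    complete_one(A_imp, j)
  })
}
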