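# Outcome-model designs. Canonical column names align the exposure
# coefficient ("A"), the missing-indicator main effect ("M", where
# M = 1 - R_A) and the indicator-exposure interaction ("A:M") across models,
# so grid summaries can compare like with like. Later columns are the ones
# dropped under aliasing, so the exposure coefficient survives whenever the
# design has any rank.
.outcome_design <- function(A, M, U, model, u_observed) {
  n <- length(A)
  X <- cbind("(Intercept)" = rep(1, n), A = A)
  if (model == "MI_RplusA" || model == "MI_RtimesA") X <- cbind(X, M = M)
  if (model == "MI_RtimesA") X <- cbind(X, "A:M" = A * M)
  if (u_observed) X <- cbind(X, U = U, "U:A" = U * A)
  X
}

.min_rows_ok <- function(n_rows, X) n_rows >= ncol(X) + 1

#' Complete-case analysis
#'
#' Ordinary least squares of Y on the observed exposure among rows with
#' R_A = 1: Y ~ A* when U is hidden, Y ~ A* + U + U:A* when U is observed.
#'
#' @param data a `sim_dataset`.
#' @param u_observed logical: include the U terms?
#' @return a `fit_result` labelled `"CC"`.
#' @export
fit_complete_case <- function(data, u_observed = FALSE) {
  obs <- which(data$R_A == 1L)
  if (length(obs) == 0L) return(failed_fit("CC", "no complete rows", 0L))
  X <- .outcome_design(data$A_star[obs], data$M[obs], data$U[obs],
                       "MI_A", u_observed)
  if (!.min_rows_ok(length(obs), X)) {
    return(failed_fit("CC", "too few complete rows", length(obs)))
  }
  fit_ols(X, data$Y[obs], label = "CC")
}

#' Fit an outcome model on one completed (imputed) dataset
#'
#' The three analysis models, with A taken as the imputed exposure `A_imp`
#' and M = 1 - R_A the missing indicator:
#' \describe{
#'   \item{`MI_A`}{Y ~ A_imp (standard multiple imputation).}
#'   \item{`MI_RplusA`}{Y ~ A_imp + M (missing-indicator main effect).}
#'   \item{`MI_RtimesA`}{Y ~ A_imp + M + A_imp:M (indicator and its
#'     interaction with the imputed exposure).}
#' }
#' When `u_observed`, the terms U and U:A_imp are added to each model. A
#' constant indicator column (no missing rows) or an indicator collinear
#' with U (deterministic missingness with U observed) is dropped and
#' recorded, not an error.
#'
#' @param completed a `completed_dataset` (must carry `A_imp` with no `NA`s).
#' @param model one of `"MI_A"`, `"MI_RplusA"`, `"MI_RtimesA"`.
#' @param u_observed logical.
#' @return a `fit_result` labelled by the model.
#' @export
fit_outcome_model <- function(completed,
                              model = c("MI_A", "MI_RplusA", "MI_RtimesA"),
                              u_observed = FALSE) {
  model <- match.arg(model)
  stopifnot("A_imp" %in% names(completed), !anyNA(completed$A_imp))
  X <- .outcome_design(completed$A_imp, completed$M, completed$U,
                       model, u_observed)
  if (!.min_rows_ok(nrow(completed), X)) {
    return(failed_fit(model, "too few rows", nrow(completed)))
  }
  fit_ols(X, completed$Y, label = model)
}

#' Completed-data benchmark fit
#'
#' OLS on the full, unmasked exposure A: the ground-truth analysis that would
#' be run in the absence of missing data. Estimates the completed-data
#' estimand, which differs from the causal estimand under unmeasured
#' confounding.
#'
#' @param data a `sim_dataset`.
#' @param u_observed logical.
#' @return a `fit_result` labelled `"CD"`.
#' @export
fit_completed_data <- function(data, u_observed = FALSE) {
  X <- .outcome_design(data$A, data$M, data$U, "MI_A", u_observed)
  if (!.min_rows_ok(nrow(data), X)) {
    return(failed_fit("CD", "too few rows", nrow(data)))
  }
  fit_ols(X, data$Y, label = "CD")
}

#' Pool multiply-imputed fits by Rubin's rules
#'
#' Point estimate = mean over imputations; within-imputation variance
#' W = mean squared SE; between-imputation variance B = variance of the
#' estimates; total variance T = W + (1 + 1/m) B. Degrees of freedom follow
#' the Barnard-Rubin small-sample formula on the complete-data residual df;
#' 95% intervals are t-based on that df. With a single fit (m = 1), B is
#' undefined: the pooled variance is W, the df is the residual df, and the
#' row is flagged.
#'
#' @param fits list of successful `fit_result`s with identical coefficient
#'   sets (after alias reconciliation); inconsistent sets are a hard error.
#' @param conf_level confidence level for the pooled intervals.
#' @return a `pooled_result` data.frame with one row per coefficient:
#'   `coefficient`, `estimate`, `W`, `B`, `T`, `se`, `df`, `lo`, `hi`, `m`,
#'   `flagged`.
#' @export
pool_rubin <- function(fits, conf_level = 0.95) {
  stopifnot(is.list(fits), length(fits) >= 1)
  ok <- vapply(fits, function(f) isTRUE(f$ok), logical(1))
  if (!any(ok)) stop("no successful fits to pool")
  fits <- fits[ok]
  m <- length(fits)
  nm <- names(fits[[1]]$coef)
  same <- vapply(fits, function(f) identical(names(f$coef), nm), logical(1))
  if (!all(same)) stop("fits have inconsistent coefficient sets; cannot pool")
  est <- do.call(rbind, lapply(fits, function(f) f$coef))
  ses <- do.call(rbind, lapply(fits, function(f) f$se))
  nu_com <- mean(vapply(fits, function(f) f$df, numeric(1)))
  Q <- colMeans(est)
  W <- colMeans(ses^2)
  if (m == 1L) {
    B <- rep(NA_real_, length(nm))
    Tv <- W
    df <- rep(nu_com, length(nm))
    flagged <- rep(TRUE, length(nm))
  } else {
    B <- apply(est, 2, var)
    Tv <- W + (1 + 1 / m) * B
    lambda <- ifelse(Tv > 0, (1 + 1 / m) * B / Tv, 0)
    df_obs <- (nu_com + 1) / (nu_com + 3) * nu_com * (1 - lambda)
    df_old <- ifelse(lambda > 0, (m - 1) / lambda^2, Inf)
    df <- 1 / (1 / df_old + 1 / df_obs)
    flagged <- rep(FALSE, length(nm))
  }
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  out <- data.frame(coefficient = nm, estimate = unname(Q), W = unname(W),
                    B = unname(B), T = unname(Tv), se = sqrt(unname(Tv)),
                    df = unname(df),
                    lo = unname(Q - tcrit * sqrt(Tv)),
                    hi = unname(Q + tcrit * sqrt(Tv)),
                    m = m, flagged = flagged)
  class(out) <- c("pooled_result", "data.frame")
  out
}
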