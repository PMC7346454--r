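# Shared least-squares machinery for the imputation and outcome models.
# Pivoted QR so that structurally aliased columns (e.g. a constant missing
# indicator when nothing is missing, or U terms when U is constant among
# complete rows) are dropped and recorded instead of failing the replicate.

fit_ols <- function(X, y, label = "ols") {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  qrx <- qr(X)
  rank <- qrx$rank
  keep <- qrx$pivot[seq_len(rank)]
  dropped <- colnames(X)[qrx$pivot[-seq_len(rank)]]
  n <- nrow(X)
  if (n - rank < 1) {
    return(failed_fit(label, "too few rows for the design", n))
  }
  Xk <- X[, keep, drop = FALSE]
  qrk <- qr(Xk)
  coef <- qr.coef(qrk, y)
  res <- y - drop(Xk %*% coef)
  df <- n - rank
  sigma2 <- sum(res^2) / df
  XtX_inv <- chol2inv(qr.R(qrk))
  dimnames(XtX_inv) <- list(colnames(Xk), colnames(Xk))
  se <- sqrt(pmax(diag(XtX_inv) * sigma2, 0))
  structure(list(ok = TRUE, label = label,
                 coef = setNames(as.numeric(coef), colnames(Xk)),
                 se = setNames(as.numeric(se), colnames(Xk)),
                 sigma2 = sigma2, df = df, n = n,
                 XtX_inv = XtX_inv, dropped = dropped),
            class = "fit_result")
}

failed_fit <- function(label, reason, n = NA_integer_) {
  structure(list(ok = FALSE, label = label, reason = reason, n = n),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (!x$ok) {
    cat("Failed fit [", x$label, "]: ", x$reason, "\n", sep = "")
    return(invisible(x))
  }
  cat("Fit [", x$label, "], n = ", x$n, ", residual df = ", x$df, "\n",
      sep = "")
  print(data.frame(estimate = x$coef, se = x$se))
  if (length(x$dropped)) {
    cat("aliased columns dropped:", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Confidence intervals for a single (non-pooled) fit
#'
#' t-based intervals on the fit's residual degrees of freedom.
#'
#' @param fit a successful `fit_result`.
#' @param conf_level confidence level.
#' @return data.frame with one row per coefficient: `coefficient`,
#'   `estimate`, `se`, `df`, `lo`, `hi`.
#' @export
fit_ci <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "fit_result"), isTRUE(fit$ok))
  tcrit <- qt(1 - (1 - conf_level) / 2, fit$df)
  data.frame(coefficient = names(fit$coef), estimate = unname(fit$coef),
             se = unname(fit$se), df = fit$df,
             lo = unname(fit$coef - tcrit * fit$se),
             hi = unname(fit$coef + tcrit * fit$se))
}
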