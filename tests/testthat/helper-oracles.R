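# Independent oracles and small fixture builders shared across the suite.

# Normal-equations least-squares solver, independent of the package's
# pivoted-QR fitting path.
ols_oracle <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - drop(X %*% beta)
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  list(coef = drop(beta), se = sqrt(diag(solve(XtX)) * sigma2), df = df)
}

# Hand-rolled Rubin pooling for a single coefficient.
rubin_oracle <- function(est, se) {
  m <- length(est)
  W <- mean(se^2)
  B <- var(est)
  list(estimate = mean(est), W = W, B = B, T = W + (1 + 1 / m) * B)
}

# Minimal successful fit_result for pooling tests.
make_fit <- function(coef, se, df = 100, label = "toy") {
  structure(list(ok = TRUE, label = label, coef = coef, se = se,
                 sigma2 = NA_real_, df = df, n = df + length(coef),
                 XtX_inv = NULL, dropped = character()),
            class = "fit_result")
}

# MCAR scenario (i) configuration at a chosen sample size: no U effects
# anywhere in the missingness or exposure models, 50% missing.
scenario_i_config <- function(n = 10000L) {
  scenario_config(alpha_U = 0, beta_U = 0, beta_A = 0, beta_UA = 0,
                  target_p_missing = 0.5, gamma_U = 1, gamma_A = 1,
                  gamma_UA = 0, sigma_Y = 1, n = n)
}

# Build a sim_dataset by hand from explicit columns (scalars recycle).
manual_dataset <- function(U, A, R_A, Y) {
  n <- length(A)
  d <- data.frame(U = rep(U, length.out = n), A = A,
                  R_A = rep(R_A, length.out = n),
                  Y = rep(Y, length.out = n))
  d$A_star <- ifelse(d$R_A == 1L, d$A, NA_real_)
  d$M <- 1L - d$R_A
  d <- d[, c("U", "A", "R_A", "A_star", "Y", "M")]
  class(d) <- c("sim_dataset", "data.frame")
  d
}

extract_A <- function(cell, method, variant = NULL) {
  e <- cell$estimates
  sub <- e[e$method == method & e$coefficient == "A" & !e$failed, ]
  if (!is.null(variant)) sub <- sub[sub$variant == variant, ]
  sub$estimate
}

# Shared heavy runs for the acceptance suite, computed once per test run.
.acc_cache <- new.env(parent = emptyenv())
acc_run <- function(key, fn) {
  if (is.null(.acc_cache[[key]])) .acc_cache[[key]] <- fn()
  .acc_cache[[key]]
}
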