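test_that("a noiseless masked toy is recovered exactly by complete case", {
  d <- toy_noiseless_linear(n = 30, slope = 3, p_missing = 0.5, seed = 2)
  fit <- fit_complete_case(d, u_observed = FALSE)
  expect_true(fit$ok)
  expect_equal(unname(fit$coef[["A"]]), 3, tolerance = 1e-10)
  expect_lt(fit$se[["A"]], 1e-8)
})

test_that("hand-dataset coefficients equal the normal-equations solution", {
  d <- toy_hand_ols()
  expect_identical(nrow(d), 6L)
  designs <- list(
    MI_A = cbind(1, d$A_imp),
    MI_RplusA = cbind(1, d$A_imp, d$M),
    MI_RtimesA = cbind(1, d$A_imp, d$M, d$A_imp * d$M))
  for (mod in names(designs)) {
    fit <- fit_outcome_model(d, mod, u_observed = FALSE)
    oracle <- ols_oracle(designs[[mod]], d$Y)
    expect_equal(unname(fit$coef), unname(oracle$coef), tolerance = 1e-8)
    expect_equal(unname(fit$se), unname(oracle$se), tolerance = 1e-8)
  }
})

test_that("every OLS fit matches the normal-equations oracle on random designs", {
  set.seed(5)
  for (trial in 1:20) {
    n <- sample(15:40, 1)
    k <- sample(1:4, 1)
    X <- cbind(1, matrix(rnorm(n * k), n, k))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(k)))
    y <- rnorm(n)
    fit <- mimisim:::fit_ols(X, y)
    oracle <- ols_oracle(X, y)
    expect_equal(unname(fit$coef), unname(oracle$coef), tolerance = 1e-8)
    expect_equal(unname(fit$se), unname(oracle$se), tolerance = 1e-8)
    expect_identical(fit$df, oracle$df)
  }
})

test_that("indicator models collapse to MI(A) when nothing is missing", {
  set.seed(9)
  d <- manual_dataset(U = rbinom(25, 1, 0.5), A = rnorm(25), R_A = 1L,
                      Y = rnorm(25))
  d$A_imp <- d$A
  class(d) <- c("completed_dataset", class(d))
  f1 <- fit_outcome_model(d, "MI_A")
  f2 <- fit_outcome_model(d, "MI_RplusA")
  expect_true("M" %in% f2$dropped)
  expect_equal(f2$coef, f1$coef, tolerance = 1e-12)
  expect_equal(f2$se, f1$se, tolerance = 1e-12)
})

test_that("complete-case and MI designs include the U terms when U is observed", {
  d <- generate_dataset(scenario_config(beta_U = 1, alpha_U = 1, gamma_U = 1,
                                        gamma_UA = 0.5, n = 1500), 21)
  cc <- fit_complete_case(d, u_observed = TRUE)
  expect_setequal(names(cc$coef), c("(Intercept)", "A", "U", "U:A"))
  fit <- fit_imputation_model(d, imputation_spec(TRUE))
  ci <- draw_proper_imputations(d, fit, m = 1, seed = 1)[[1]]
  f3 <- fit_outcome_model(ci, "MI_RtimesA", u_observed = TRUE)
  expect_setequal(names(f3$coef),
                  c("(Intercept)", "A", "M", "A:M", "U", "U:A"))
})

test_that("the completed-data benchmark targets the completed-data estimand", {
  # no interaction, no confounding: recovers gamma_A = 1
  cfg1 <- scenario_config(gamma_U = 1, n = 4000)
  e1 <- sapply(1:30, function(r) {
    fit_completed_data(generate_dataset(cfg1, derive_seed(2, 0, r, 1)))$coef[["A"]]
  })
  expect_lt(abs(mean(e1) - 1), 3 * sd(e1) / sqrt(30))
  # interaction, pi_U = 0.5: marginal effect 1.25
  cfg2 <- scenario_config(gamma_U = 1, gamma_UA = 0.5, n = 4000)
  e2 <- sapply(1:30, function(r) {
    fit_completed_data(generate_dataset(cfg2, derive_seed(3, 0, r, 1)))$coef[["A"]]
  })
  expect_lt(abs(mean(e2) - 1.25), 3 * sd(e2) / sqrt(30))
  # strong unmeasured confounding biases the benchmark upward, and the
  # complete-case mean agrees with an independent million-row regression
  cfg3 <- scenario_config(alpha_U = 1, beta_U = 1, gamma_U = 1, n = 10000)
  e3 <- sapply(1:30, function(r) {
    d <- generate_dataset(cfg3, derive_seed(4, 0, r, 1))
    c(fit_completed_data(d)$coef[["A"]], fit_complete_case(d)$coef[["A"]])
  })
  expect_gt(mean(e3[1, ]), 1 + 3 * sd(e3[1, ]) / sqrt(30))
  big <- generate_dataset(scenario_config(alpha_U = 1, beta_U = 1,
                                          gamma_U = 1, n = 1e6), 77)
  oracle <- ols_oracle(cbind(1, big$A_star[big$R_A == 1]),
                       big$Y[big$R_A == 1])$coef[2]
  expect_lt(abs(mean(e3[2, ]) - oracle), 3 * sd(e3[2, ]) / sqrt(30))
})

test_that("Rubin pooling matches hand arithmetic", {
  fits <- list(make_fit(c(A = 1.0), c(A = 0.5)),
               make_fit(c(A = 2.0), c(A = 0.5)))
  p <- pool_rubin(fits)
  expect_equal(p$estimate, 1.5)
  expect_equal(p$W, 0.25)
  expect_equal(p$B, 0.5)
  expect_equal(p$T, 0.25 + 1.5 * 0.5)
  oracle <- rubin_oracle(c(1, 2), c(0.5, 0.5))
  expect_equal(p$T, oracle$T)
  expect_true(p$lo <= p$estimate && p$estimate <= p$hi)
})

test_that("pooling handles identical fits, a single fit, and mismatches", {
  f <- make_fit(c(A = 1.2, M = 0.3), c(A = 0.1, M = 0.2))
  p <- pool_rubin(list(f, f, f))
  expect_equal(p$B, c(0, 0))
  expect_equal(p$T, p$W)
  expect_equal(p$estimate, c(1.2, 0.3))
  # m = 1 boundary: B undefined, T = W, flagged
  p1 <- pool_rubin(list(f))
  expect_true(all(is.na(p1$B)))
  expect_equal(p1$T, p1$W)
  expect_true(all(p1$flagged))
  expect_equal(p1$df, c(100, 100))
  # permutation invariance
  fits <- list(make_fit(c(A = 0.9), c(A = 0.1)),
               make_fit(c(A = 1.1), c(A = 0.12)),
               make_fit(c(A = 1.0), c(A = 0.11)))
  expect_equal(pool_rubin(fits), pool_rubin(rev(fits)))
  # inconsistent coefficient sets are a hard error
  bad <- list(make_fit(c(A = 1), c(A = 0.1)),
              make_fit(c(A = 1, M = 0), c(A = 0.1, M = 0.1)))
  expect_error(pool_rubin(bad), "inconsistent")
})

test_that("refitting the same completed data is bit-identical", {
  d <- generate_dataset(scenario_i_config(1000L), 6)
  fit <- fit_imputation_model(d, imputation_spec(FALSE))
  ci <- draw_proper_imputations(d, fit, m = 1, seed = 3)[[1]]
  f1 <- fit_outcome_model(ci, "MI_RplusA")
  f2 <- fit_outcome_model(ci, "MI_RplusA")
  expect_identical(f1, f2)
})
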