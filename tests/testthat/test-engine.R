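test_that("the default factorial grid has the declared cell counts", {
  g <- enumerate_grid(grid_spec())
  expect_identical(nrow(g), 11808L)
  expect_identical(sum(g$stratum == "logistic"), 11520L)
  expect_identical(sum(g$stratum == "deterministic"), 288L)
  expect_identical(11520L, 3L * 4L * 4L * 4L * 5L * 2L * 2L * 3L)
  expect_identical(288L, 4L * 4L * 2L * 3L * 3L)
  expect_identical(g$cell_id, seq_len(nrow(g)))
  # deterministic stratum carries NA betas and p_missing = pi_U
  det <- g[g$stratum == "deterministic", ]
  expect_true(all(is.na(det$beta_U)))
  expect_identical(det$p_missing, det$pi_U)
  # enumeration is deterministic
  expect_identical(g, enumerate_grid(grid_spec()))
})

test_that("single-value grids collapse to a single cell", {
  spec <- grid_spec(alpha_U = 0, beta_A = 0, gamma_U = 1, beta_U = 0,
                    beta_UA = 0, gamma_UA = 0, sigma_Y = 1, p_missing = 0.5,
                    pi_U_det = numeric(0))
  g <- enumerate_grid(spec)
  expect_identical(nrow(g), 1L)
  cfg <- as_scenario_config(g, 1)
  expect_s3_class(cfg, "scenario_config")
  expect_identical(cfg$scenario_label, "i")
})

test_that("grid rows reconstruct validated configurations in both strata", {
  g <- enumerate_grid(grid_spec())
  logi <- as_scenario_config(g, 2)
  expect_identical(logi$missingness, "logistic")
  expect_lt(abs(mimisim:::marginal_p_missing(
    logi$beta_0, logi$beta_U, logi$beta_A, logi$beta_UA, logi$pi_U,
    logi$alpha_0, logi$alpha_U, logi$sigma_A) - logi$target_p_missing), 1e-6)
  det <- as_scenario_config(g, g$cell_id[g$stratum == "deterministic"][1])
  expect_identical(det$missingness, "deterministic")
  expect_identical(det$cell_id, g$cell_id[g$stratum == "deterministic"][1])
})

test_that("results do not depend on cell execution order or re-runs", {
  spec <- grid_spec(alpha_U = c(0, 1), beta_A = 0, gamma_U = 1, beta_U = 0.5,
                    beta_UA = 0, gamma_UA = 0, sigma_Y = 1, p_missing = 0.5,
                    pi_U_det = numeric(0), n = 400L)
  g <- enumerate_grid(spec)
  s12 <- run_grid(g, cells = c(1, 2), replicates = 4, study_seed = 5)
  s21 <- run_grid(g, cells = c(2, 1), replicates = 4, study_seed = 5)
  ord <- function(s) {
    s <- s[order(s$cell_id, s$method, s$coefficient), ]
    rownames(s) <- NULL
    s
  }
  expect_identical(ord(s12), ord(s21))
  # a single cell run alone reproduces its rows from the joint run
  s2 <- run_grid(g, cells = 2, replicates = 4, study_seed = 5)
  expect_identical(ord(s2), ord(s12[s12$cell_id == 2, ]))
})

test_that("two replicates suffice for percentiles, and percentiles are monotone", {
  cfg <- scenario_i_config(400L)
  rc <- run_cell(cfg, replicates = 2, study_seed = 9)
  s <- rc$summary
  expect_gt(nrow(s), 0)
  qcols <- as.matrix(s[, c("p2.5", "p25", "p50", "p75", "p97.5")])
  expect_true(all(apply(qcols, 1, function(x) all(diff(x) >= 0))))
  expect_true(all(s$coverage >= 0 & s$coverage <= 1, na.rm = TRUE))
})

test_that("coverage is the fraction of intervals containing the target", {
  expect_equal(coverage(rep(0.9, 5), rep(1.1, 5), 1), 1)
  expect_equal(coverage(rep(1.1, 5), rep(1.2, 5), 1), 0)
  expect_equal(coverage(c(0.9, 1.05), c(1.2, 1.2), 1), 0.5)
  expect_error(coverage(numeric(0), numeric(0), 1), "empty")
})

test_that("failures are counted explicitly in summaries", {
  est <- rbind(
    data.frame(replicate = 1:3, variant = "hidden", method = "CC",
               coefficient = "A", estimate = c(1, 1.1, 0.9),
               se = 0.1, df = 10, lo = 0.7, hi = 1.3,
               failed = FALSE, reason = NA_character_),
    data.frame(replicate = 4:5, variant = "hidden", method = "CC",
               coefficient = NA_character_, estimate = NA_real_,
               se = NA_real_, df = NA_real_, lo = NA_real_, hi = NA_real_,
               failed = TRUE, reason = "too few complete rows"))
  s <- summarize_cell(est)
  expect_identical(s$n_rep, 3L)
  expect_identical(s$n_fail, 2L)
  expect_equal(s$mean, 1)
})

test_that("coverage targets can follow the standardized marginal effect", {
  spec <- grid_spec(alpha_U = 0, beta_A = 0, gamma_U = 1, beta_U = 0,
                    beta_UA = 0, gamma_UA = 0.5, sigma_Y = 1,
                    p_missing = 0.5, pi_U_det = numeric(0), n = 400L)
  g <- enumerate_grid(spec)
  s <- run_grid(g, replicates = 3, study_seed = 2, use_delta_target = TRUE)
  expect_true(all(s$target[s$coefficient == "A"] == 1.25))
})

test_that("run summaries are written as tidy rows with a metadata sidecar", {
  rc <- run_cell(scenario_i_config(400L), replicates = 3, study_seed = 1)
  dir <- withr::local_tempdir()
  write_run(rc$summary, dir, study_seed = 1, replicates = 3, m = 5)
  long <- read.csv(file.path(dir, "summary.csv"))
  expect_setequal(unique(long$statistic),
                  c("mean", "p2.5", "p25", "p50", "p75", "p97.5", "emp_se",
                    "mean_model_se", "mean_ci_length", "coverage"))
  meta <- yaml::read_yaml(file.path(dir, "run-metadata.yml"))
  expect_identical(meta$package, "mimisim")
  expect_equal(meta$study_seed, 1)
})
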