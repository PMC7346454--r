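#' Specify the factorial simulation grid
#'
#' Defaults reproduce the full factorial design: for the logistic-missingness
#' stratum, alpha_U, beta_A and gamma_U vary over \{0, 0.1, 0.5, 1\}, beta_U
#' over \{-1, 0, 0.1, 0.5, 1\}, the interactions beta_UA and gamma_UA over
#' \{0, 0.5\}, sigma_Y over \{0.1, 0.5, 1\} and the marginal missingness
#' P(R_A = 0) over \{0.25, 0.5, 0.75\}, with gamma_A = 1, sigma_A = 1,
#' pi_U = 0.5 and n = 10,000 fixed. The deterministic stratum R_A = 1 - U
#' drops the (redundant) beta parameters and instead varies pi_U over
#' \{0.25, 0.5, 0.75\}, which is what varies its missingness proportion.
#' Full enumeration yields 11,520 + 288 = 11,808 cells.
#'
#' @param alpha_U,beta_A,gamma_U,beta_U,beta_UA,gamma_UA,sigma_Y,p_missing
#'   parameter grids for the logistic stratum.
#' @param pi_U_det pi_U grid for the deterministic stratum.
#' @param gamma_A,sigma_A,pi_U,n fixed scalars.
#' @param replicates replicates per cell (default 200).
#' @param m imputations per replicate (default 5).
#' @return a `grid_spec` list.
#' @export
grid_spec <- function(alpha_U = c(0, 0.1, 0.5, 1),
                      beta_A = c(0, 0.1, 0.5, 1),
                      gamma_U = c(0, 0.1, 0.5, 1),
                      beta_U = c(-1, 0, 0.1, 0.5, 1),
                      beta_UA = c(0, 0.5),
                      gamma_UA = c(0, 0.5),
                      sigma_Y = c(0.1, 0.5, 1),
                      p_missing = c(0.25, 0.5, 0.75),
                      pi_U_det = c(0.25, 0.5, 0.75),
                      gamma_A = 1, sigma_A = 1, pi_U = 0.5,
                      n = 10000L, replicates = 200L, m = 5L) {
  structure(list(alpha_U = alpha_U, beta_A = beta_A, gamma_U = gamma_U,
                 beta_U = beta_U, beta_UA = beta_UA, gamma_UA = gamma_UA,
                 sigma_Y = sigma_Y, p_missing = p_missing,
                 pi_U_det = pi_U_det, gamma_A = gamma_A, sigma_A = sigma_A,
                 pi_U = pi_U, n = as.integer(n),
                 replicates = as.integer(replicates), m = as.integer(m)),
            class = "grid_spec")
}

#' Enumerate every cell of the factorial grid
#'
#' Deterministic ordering: the logistic stratum first (inner-to-outer factor
#' order as listed in [grid_spec()]), then the deterministic R_A = 1 - U
#' stratum. Each row carries a stable `cell_id`; beta parameters are `NA` in
#' the deterministic stratum, where `p_missing` equals `pi_U`.
#'
#' @param spec a [grid_spec()].
#' @return a data.frame of class `scenario_grid`, one row per cell, with the
#'   spec attached as attribute `spec` and a `scenario` label column.
#' @export
enumerate_grid <- function(spec = grid_spec()) {
  stopifnot(inherits(spec, "grid_spec"))
  logi <- expand.grid(p_missing = spec$p_missing, alpha_U = spec$alpha_U,
                      beta_A = spec$beta_A, gamma_U = spec$gamma_U,
                      beta_U = spec$beta_U, beta_UA = spec$beta_UA,
                      gamma_UA = spec$gamma_UA, sigma_Y = spec$sigma_Y,
                      KEEP.OUT.ATTRS = FALSE)
  logi$stratum <- "logistic"
  logi$pi_U <- spec$pi_U
  det <- expand.grid(alpha_U = spec$alpha_U, gamma_U = spec$gamma_U,
                     gamma_UA = spec$gamma_UA, sigma_Y = spec$sigma_Y,
                     pi_U = spec$pi_U_det, KEEP.OUT.ATTRS = FALSE)
  det$stratum <- rep("deterministic", nrow(det))
  det$p_missing <- det$pi_U
  det$beta_U <- det$beta_A <- det$beta_UA <- rep(NA_real_, nrow(det))
  cols <- c("stratum", "pi_U", "alpha_U", "beta_U", "beta_A", "beta_UA",
            "p_missing", "gamma_U", "gamma_UA", "sigma_Y")
  grid <- rbind(logi[, cols], det[, cols])
  grid$gamma_A <- spec$gamma_A
  grid$sigma_A <- spec$sigma_A
  grid$n <- spec$n
  grid$cell_id <- seq_len(nrow(grid))
  grid$scenario <- mapply(classify_scenario, grid$alpha_U, grid$beta_U,
                          grid$beta_A, grid$beta_UA,
                          grid$stratum == "deterministic")
  rownames(grid) <- NULL
  attr(grid, "spec") <- spec
  class(grid) <- c("scenario_grid", "data.frame")
  grid
}

#' Build the scenario configuration for one grid cell
#'
#' Solves the intercepts for the cell's parameters (beta_0 solving is done
#' here, lazily, rather than during enumeration).
#'
#' @param grid a `scenario_grid` from [enumerate_grid()].
#' @param i row index (or a `cell_id`, equal by construction).
#' @param u_observed analysis-level flag for the returned config.
#' @return a [scenario_config()].
#' @export
as_scenario_config <- function(grid, i, u_observed = FALSE) {
  row <- grid[i, ]
  if (row$stratum == "deterministic") {
    scenario_config(pi_U = row$pi_U, alpha_U = row$alpha_U,
                    sigma_A = row$sigma_A, missingness = "deterministic",
                    gamma_U = row$gamma_U, gamma_A = row$gamma_A,
                    gamma_UA = row$gamma_UA, sigma_Y = row$sigma_Y,
                    u_observed = u_observed, n = row$n,
                    cell_id = row$cell_id)
  } else {
    scenario_config(pi_U = row$pi_U, alpha_U = row$alpha_U,
                    sigma_A = row$sigma_A, missingness = "logistic",
                    beta_U = row$beta_U, beta_A = row$beta_A,
                    beta_UA = row$beta_UA, target_p_missing = row$p_missing,
                    gamma_U = row$gamma_U, gamma_A = row$gamma_A,
                    gamma_UA = row$gamma_UA, sigma_Y = row$sigma_Y,
                    u_observed = u_observed, n = row$n,
                    cell_id = row$cell_id)
  }
}

#' Stratified random subsample of grid cells
#'
#' Samples cells with strata defined by the DAG scenario label crossed with
#' the missingness stratum, allocating as evenly as possible, for smoke
#' testing subsets of the grid.
#'
#' @param grid a `scenario_grid`.
#' @param size total number of cells.
#' @param seed integer seed.
#' @return integer vector of `cell_id`s.
#' @export
sample_grid <- function(grid, size = 20L, seed = 1L) {
  stopifnot(size >= 1, nrow(grid) >= size)
  set.seed(as.integer(seed))
  strata <- split(grid$cell_id, paste(grid$scenario, grid$stratum))
  k <- length(strata)
  base <- size %/% k
  extra <- size %% k
  take <- rep(base, k) + (seq_len(k) <= extra)
  ids <- unlist(mapply(function(ids, nk) {
    sample(ids, min(nk, length(ids)))
  }, strata, take, SIMPLIFY = FALSE), use.names = FALSE)
  short <- size - length(ids)
  if (short > 0) {
    pool <- setdiff(grid$cell_id, ids)
    ids <- c(ids, sample(pool, short))
  }
  sort(ids)
}

.method_label <- c(MI_A = "MI(A)", MI_RplusA = "MI(R+A)",
                   MI_RtimesA = "MI(R*A)")

.estimate_row <- function(replicate, variant, method, tab = NULL,
                          reason = NA_character_) {
  if (is.null(tab)) {
    data.frame(replicate = replicate, variant = variant, method = method,
               coefficient = NA_character_, estimate = NA_real_,
               se = NA_real_, df = NA_real_, lo = NA_real_, hi = NA_real_,
               failed = TRUE, reason = reason)
  } else {
    data.frame(replicate = replicate, variant = variant, method = method,
               coefficient = tab$coefficient, estimate = tab$estimate,
               se = tab$se, df = tab$df, lo = tab$lo, hi = tab$hi,
               failed = FALSE, reason = NA_character_)
  }
}

# One replicate of one cell: generate, then run the requested analysis
# variants (complete case, the three MI outcome models pooled over m
# imputations, and the completed-data benchmark).
run_replicate <- function(config, replicate, study_seed = 1L, m = 5L,
                          variants = "hidden") {
  cell <- config$cell_id
  d <- generate_dataset(config, derive_seed(study_seed, cell, replicate, 1L))
  out <- list()
  add <- function(row) out[[length(out) + 1L]] <<- row
  for (variant in variants) {
    uo <- identical(variant, "observed")
    cc <- fit_complete_case(d, uo)
    add(if (cc$ok) .estimate_row(replicate, variant, "CC", fit_ci(cc))
        else .estimate_row(replicate, variant, "CC", reason = cc$reason))
    cd <- fit_completed_data(d, uo)
    add(if (cd$ok) .estimate_row(replicate, variant, "CD", fit_ci(cd))
        else .estimate_row(replicate, variant, "CD", reason = cd$reason))
    impfit <- fit_imputation_model(d, imputation_spec(uo, m))
    if (!impfit$ok) {
      for (mod in names(.method_label)) {
        add(.estimate_row(replicate, variant, .method_label[[mod]],
                          reason = impfit$reason))
      }
      next
    }
    imps <- draw_proper_imputations(d, impfit, m,
                                    derive_seed(study_seed, cell, replicate,
                                                if (uo) 3L else 2L))
    for (mod in names(.method_label)) {
      fits <- lapply(imps, fit_outcome_model, model = mod, u_observed = uo)
      lab <- .method_label[[mod]]
      pooled <- tryCatch(pool_rubin(fits), error = function(e) e)
      if (inherits(pooled, "error")) {
        add(.estimate_row(replicate, variant, lab,
                          reason = conditionMessage(pooled)))
      } else {
        add(.estimate_row(replicate, variant, lab, pooled))
      }
    }
  }
  do.call(rbind, out)
}

#' Run all replicates of one simulation cell
#'
#' Per replicate: generate a dataset, fit the complete-case model, perform
#' m proper imputations and fit the three MI outcome models (pooled by
#' Rubin's rules), and fit the completed-data benchmark. Replicate failures
#' (degenerate data, too few complete rows) are recorded and counted, never
#' silently dropped. The per-(cell, replicate, stream) seed scheme makes the
#' result independent of cell execution order.
#'
#' @param config a [scenario_config()].
#' @param replicates number of replicates (default 200).
#' @param study_seed study-level integer seed.
#' @param m imputations per replicate.
#' @param variants which analysis variants to run: `"hidden"` (U unavailable
#'   to the analysts), `"observed"`, or both. Default follows
#'   `config$u_observed`.
#' @param target named vector of coverage targets per coefficient (default
#'   `c(A = 1)`, the paper-style target for the exposure coefficient).
#' @return a `cell_result` list: `config`, per-replicate `estimates`,
#'   `summary` (see [summarize_cell()]), plus the run parameters.
#' @export
run_cell <- function(config, replicates = 200L, study_seed = 1L, m = 5L,
                     variants = NULL, target = c(A = 1)) {
  stopifnot(replicates >= 2)
  if (is.null(variants)) {
    variants <- if (config$u_observed) "observed" else "hidden"
  }
  stopifnot(all(variants %in% c("hidden", "observed")))
  est <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    run_replicate(config, r, study_seed, m, variants)
  }))
  rownames(est) <- NULL
  structure(list(config = config,
                 estimates = est,
                 summary = summarize_cell(est, config, target = target),
                 replicates = as.integer(replicates), m = as.integer(m),
                 study_seed = as.integer(study_seed)),
            class = "cell_result")
}

#' Coverage of a target value by a set of confidence intervals
#'
#' @param lo,hi equal-length vectors of interval bounds.
#' @param target the value whose coverage is assessed (default 1, the fixed
#'   exposure effect; the standardized marginal effect from [true_effects()]
#'   can be supplied instead).
#' @return the fraction of intervals containing `target`.
#' @export
coverage <- function(lo, hi, target = 1) {
  stopifnot(length(lo) == length(hi))
  if (length(lo) == 0L) stop("coverage is undefined for empty input")
  mean(lo <= target & target <= hi)
}

#' Summarise per-replicate estimates for one cell
#'
#' Per (variant, method, coefficient): the retained percentiles (2.5, 25,
#' 50, 75, 97.5; linear interpolation between order statistics), the mean
#' estimate, the empirical SE (SD of estimates across replicates), the mean
#' model-based SE, the mean confidence-interval length, coverage of the
#' target (for coefficients with a declared target), and the replicate
#' failure count.
#'
#' @param estimates per-replicate estimates from [run_cell()].
#' @param config the generating config (attached for reference; optional).
#' @param target named vector of coverage targets by coefficient.
#' @return a data.frame of class `scenario_summary`.
#' @export
summarize_cell <- function(estimates, config = NULL, target = c(A = 1)) {
  stopifnot(is.data.frame(estimates))
  keys <- unique(estimates[, c("variant", "method")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    v <- keys$variant[i]; meth <- keys$method[i]
    sub <- estimates[estimates$variant == v & estimates$method == meth, ]
    n_fail <- length(unique(sub$replicate[sub$failed]))
    okr <- sub[!sub$failed, ]
    for (cf in unique(okr$coefficient)) {
      e <- okr[okr$coefficient == cf, ]
      qs <- quantile(e$estimate, c(0.025, 0.25, 0.5, 0.75, 0.975),
                     names = FALSE, type = 7)
      tgt <- if (cf %in% names(target)) target[[cf]] else NA_real_
      cov <- if (is.na(tgt)) NA_real_ else coverage(e$lo, e$hi, tgt)
      out[[length(out) + 1L]] <- data.frame(
        cell_id = if (is.null(config)) NA_integer_ else config$cell_id,
        scenario = if (is.null(config)) NA_character_ else
          config$scenario_label,
        variant = v, method = meth, coefficient = cf,
        n_rep = nrow(e), n_fail = n_fail,
        mean = mean(e$estimate), p2.5 = qs[1], p25 = qs[2], p50 = qs[3],
        p75 = qs[4], p97.5 = qs[5],
        emp_se = sd(e$estimate), mean_model_se = mean(e$se),
        mean_ci_length = mean(e$hi - e$lo),
        target = tgt, coverage = cov)
    }
  }
  if (length(out) == 0L) {
    stop("all replicates failed for this cell; no estimates to summarise")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("scenario_summary", "data.frame")
  res
}

#' Run a set of grid cells
#'
#' Serial loop over cells; because every replicate's seed is derived from
#' (study seed, cell id, replicate, stream), running cells in any order or
#' in parallel partitions yields identical results.
#'
#' @param grid a `scenario_grid`.
#' @param cells `cell_id`s to run (default: all).
#' @param replicates,study_seed,m,variants,target passed to [run_cell()].
#' @param use_delta_target if `TRUE`, each cell's coverage target for the
#'   exposure coefficient is the standardized marginal effect delta_A from
#'   [true_effects()] instead of the fixed default.
#' @return a data.frame of stacked cell summaries (class
#'   `scenario_summary`).
#' @export
run_grid <- function(grid, cells = grid$cell_id, replicates = 200L,
                     study_seed = 1L, m = 5L, variants = NULL,
                     target = c(A = 1), use_delta_target = FALSE) {
  res <- lapply(cells, function(id) {
    cfg <- as_scenario_config(grid, id)
    tgt <- target
    if (use_delta_target) {
      tgt["A"] <- true_effects(cfg$gamma_A, cfg$gamma_UA, cfg$pi_U)$delta_A
    }
    run_cell(cfg, replicates, study_seed, m, variants, tgt)$summary
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("scenario_summary", "data.frame")
  out
}

#' Write grid summaries and a run-metadata sidecar
#'
#' Emits one tidy CSV row per (cell, variant, method, coefficient,
#' statistic) plus a YAML sidecar recording the package version, seeds,
#' replicate counts and the numerical conventions used (percentile
#' definition, Rubin df formula, alias handling).
#'
#' @param summary a `scenario_summary` data.frame.
#' @param dir output directory (created if absent).
#' @param study_seed,replicates,m run parameters recorded in the sidecar.
#' @return `dir`, invisibly.
#' @export
write_run <- function(summary, dir, study_seed = NA_integer_,
                      replicates = NA_integer_, m = NA_integer_) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stats <- c("mean", "p2.5", "p25", "p50", "p75", "p97.5", "emp_se",
             "mean_model_se", "mean_ci_length", "coverage")
  long <- do.call(rbind, lapply(stats, function(s) {
    data.frame(cell_id = summary$cell_id, scenario = summary$scenario,
               variant = summary$variant, method = summary$method,
               coefficient = summary$coefficient,
               n_rep = summary$n_rep, n_fail = summary$n_fail,
               statistic = s, value = summary[[s]])
  }))
  long <- long[order(long$cell_id, long$variant, long$method,
                     long$coefficient, long$statistic), ]
  utils::write.csv(long, file.path(dir, "summary.csv"), row.names = FALSE)
  meta <- list(
    package = "mimisim",
    version = as.character(utils::packageVersion("mimisim")),
    study_seed = study_seed, replicates = replicates, imputations = m,
    percentile_definition = "linear interpolation (R quantile type 7)",
    mi_df = "Barnard-Rubin adjusted degrees of freedom",
    single_fit_ci = "t on residual df",
    alias_handling = "constant/collinear design columns dropped and recorded",
    missing_indicator = "M = 1 - R_A (1 = missing) in all indicator models",
    seed_scheme = "per-(cell, replicate, stream) derivation from study seed")
  yaml::write_yaml(meta, file.path(dir, "run-metadata.yml"))
  invisible(dir)
}
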