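.load_figures_yaml <- function() {
  path <- system.file("extdata", "presets", "figures.yaml",
                      package = "mimisim")
  if (path == "") {
    path <- file.path("inst", "extdata", "presets", "figures.yaml")
  }
  x <- yaml::read_yaml(path)
  x$common <- .fix_yaml_n(x$common)
  x
}

#' Scenario configuration for one results-figure panel cell
#'
#' The six results figures share gamma_A = 1, gamma_U = 1, sigma_Y = 1,
#' sigma_A = 1 and a marginal missingness of 0.5; figures 2-4 vary alpha_U
#' within panels over rows of beta_U (with a deterministic R_A = 1 - U top
#' row), figures 5-7 vary beta_A over rows of beta_U. Figure 4 and 6
#' presets carry `u_observed = TRUE`; figure 7 fixes alpha_U = 0.5 with
#' gamma_UA = 0.5. Presets live in a checked-in YAML catalogue
#' (`extdata/presets/figures.yaml`) shared by documentation and tests.
#'
#' @param figure integer 2..7.
#' @param beta_U row selector (ignored when `deterministic = TRUE`); must
#'   lie on the figure's displayed beta_U grid.
#' @param alpha_U column selector for figures 2-4 (must be `NULL` for 5-7).
#' @param beta_A column selector for figures 5-7 (must be `NULL` for 2-4).
#' @param deterministic select the R_A = 1 - U special-case row (figures
#'   2-4 only).
#' @param n observations per replicate (defaults to the study's 10,000).
#' @return a fully solved [scenario_config()].
#' @examples
#' figure_preset(2, beta_U = 0, alpha_U = 0)$scenario_label  # "i"
#' @export
figure_preset <- function(figure, beta_U = NULL, alpha_U = NULL,
                          beta_A = NULL, deterministic = FALSE, n = NULL) {
  figure <- as.integer(figure)
  if (!figure %in% 2:7) stop("figure must be one of 2..7")
  cat_ <- .load_figures_yaml()
  fig <- cat_[[paste0("fig", figure)]]
  common <- cat_$common
  sel_name <- fig$vary
  sel <- if (sel_name == "alpha_U") alpha_U else beta_A
  other <- if (sel_name == "alpha_U") beta_A else alpha_U
  if (!is.null(other)) {
    stop("figure ", figure, " varies ", sel_name, "; '",
         if (sel_name == "alpha_U") "beta_A" else "alpha_U",
         "' is not a selector for it")
  }
  if (is.null(sel)) stop("selector '", sel_name, "' is required")
  if (!sel %in% fig$vary_grid) {
    stop(sel_name, " = ", sel, " is outside the displayed grid {",
         paste(fig$vary_grid, collapse = ", "), "}")
  }
  n <- n %||% common$n
  if (deterministic) {
    if (!isTRUE(fig$deterministic_row)) {
      stop("figure ", figure, " has no deterministic R_A = 1 - U row")
    }
    if (!is.null(beta_U)) {
      stop("beta_U does not apply to the deterministic row")
    }
    return(scenario_config(
      pi_U = common$pi_U,
      alpha_U = if (sel_name == "alpha_U") sel else fig$alpha_U,
      sigma_A = common$sigma_A, missingness = "deterministic",
      gamma_U = common$gamma_U, gamma_A = common$gamma_A,
      gamma_UA = fig$gamma_UA, sigma_Y = common$sigma_Y,
      u_observed = isTRUE(fig$u_observed), n = n))
  }
  if (is.null(beta_U)) stop("beta_U row selector is required")
  if (!beta_U %in% fig$rows_beta_U) {
    stop("beta_U = ", beta_U, " is outside the displayed grid {",
         paste(fig$rows_beta_U, collapse = ", "), "}")
  }
  scenario_config(
    pi_U = common$pi_U,
    alpha_U = if (sel_name == "alpha_U") sel else fig$alpha_U,
    sigma_A = common$sigma_A, missingness = "logistic",
    beta_U = beta_U,
    beta_A = if (sel_name == "beta_A") sel else fig$beta_A,
    beta_UA = fig$beta_UA,
    target_p_missing = common$target_p_missing,
    gamma_U = common$gamma_U, gamma_A = common$gamma_A,
    gamma_UA = fig$gamma_UA, sigma_Y = common$sigma_Y,
    u_observed = isTRUE(fig$u_observed), n = n)
}

#' Tiny noiseless linear toy dataset
#'
#' Y is an exact linear function of A with a random half of the exposures
#' masked; useful for exact-recovery checks (slope recovered with zero
#' residual variance).
#'
#' @param n rows.
#' @param slope Y = slope * A exactly.
#' @param p_missing masking probability.
#' @param seed integer seed.
#' @return a `sim_dataset`-shaped data.frame (U identically 0).
#' @export
toy_noiseless_linear <- function(n = 20L, slope = 3, p_missing = 0.5,
                                 seed = 1L) {
  set.seed(as.integer(seed))
  A <- rnorm(n)
  R_A <- 1L - rbinom(n, 1L, p_missing)
  d <- data.frame(U = 0L, A = A, R_A = R_A,
                  A_star = ifelse(R_A == 1L, A, NA_real_),
                  Y = slope * A, M = 1L - R_A)
  class(d) <- c("sim_dataset", "data.frame")
  d
}

#' Six-row hand-checkable completed dataset
#'
#' A fixed dataset shipped as plain text (`extdata/toy6.tsv`) with exposure,
#' missingness indicator, outcome and an already-completed exposure column,
#' small enough that outcome-model coefficients can be verified against a
#' direct normal-equations solve.
#'
#' @return a `completed_dataset` data.frame with columns `U`, `A`, `R_A`,
#'   `A_star`, `Y`, `M`, `A_imp`.
#' @export
toy_hand_ols <- function() {
  path <- system.file("extdata", "toy6.tsv", package = "mimisim")
  if (path == "") path <- file.path("inst", "extdata", "toy6.tsv")
  d <- read.table(path, header = TRUE, sep = "\t", na.strings = "")
  d$M <- 1L - d$R_A
  class(d) <- c("completed_dataset", "sim_dataset", "data.frame")
  d
}
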