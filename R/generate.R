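#' Generate one synthetic dataset under a scenario configuration
#'
#' Draws the columns in causal order U -> A -> R_A -> Y and masks the
#' exposure per the missingness indicator. R_A is stored exactly as defined
#' (1 = observed, 0 = missing) and the missing indicator M = 1 - R_A used by
#' the missing-indicator outcome models is exposed as its own column to avoid
#' sign mistakes. Repeated calls with the same (config, seed) are
#' bit-identical.
#'
#' A replicate in which every exposure is observed or every exposure is
#' missing is returned as-is but flagged degenerate (attribute `degenerate`);
#' downstream fitting decides how to handle it. Regeneration is deliberately
#' not offered, since resampling conditional on non-degeneracy would bias the
#' missingness proportion.
#'
#' @param config a [scenario_config()].
#' @param seed integer seed for this replicate.
#' @return a `data.frame` of class `sim_dataset` with columns `U`, `A`
#'   (complete, internal), `R_A`, `A_star` (observed part, `NA` where
#'   missing), `Y` and `M = 1 - R_A`; attributes `config`, `seed`,
#'   `degenerate`.
#' @examples
#' d <- generate_dataset(scenario_config(n = 100), seed = 1)
#' all(d$A_star[d$R_A == 1] == d$A[d$R_A == 1])
#' @export
generate_dataset <- function(config, seed) {
  validate_scenario_config(config)
  set.seed(as.integer(seed))
  n <- config$n
  U <- rbinom(n, 1L, config$pi_U)
  A <- rnorm(n, config$alpha_0 + config$alpha_U * U, config$sigma_A)
  if (config$missingness == "deterministic") {
    R_A <- 1L - U
  } else {
    p_miss <- expit(config$beta_0 + config$beta_U * U +
                      config$beta_A * A + config$beta_UA * U * A)
    R_A <- 1L - rbinom(n, 1L, p_miss)
  }
  Y <- rnorm(n, config$gamma_0 + config$gamma_U * U +
               config$gamma_A * A + config$gamma_UA * U * A, config$sigma_Y)
  A_star <- ifelse(R_A == 1L, A, NA_real_)
  d <- data.frame(U = U, A = A, R_A = R_A, A_star = A_star, Y = Y,
                  M = 1L - R_A)
  attr(d, "config") <- config
  attr(d, "seed") <- as.integer(seed)
  attr(d, "degenerate") <- all(R_A == 1L) || all(R_A == 0L)
  class(d) <- c("sim_dataset", "data.frame")
  d
}

#' Write a simulated dataset as delimited text
#'
#' Tab-separated with a header row and columns `U`, `A`, `R_A`, `A_star`,
#' `Y`; a missing `A_star` is written as an empty field.
#'
#' @param data a `sim_dataset` (or compatible data.frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sim_dataset <- function(data, path) {
  cols <- c("U", "A", "R_A", "A_star", "Y")
  stopifnot(all(cols %in% names(data)))
  write.table(data[, cols], path, sep = "\t", row.names = FALSE,
              quote = FALSE, na = "")
  invisible(path)
}

#' Read a simulated dataset written by [write_sim_dataset()]
#'
#' @param path file path.
#' @return a `data.frame` of class `sim_dataset` (the generating config is
#'   not serialised with the data and is absent on the round trip).
#' @export
read_sim_dataset <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", na.strings = "",
                  colClasses = c(U = "integer", A = "numeric",
                                 R_A = "integer", A_star = "numeric",
                                 Y = "numeric"))
  d$M <- 1L - d$R_A
  class(d) <- c("sim_dataset", "data.frame")
  d
}
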