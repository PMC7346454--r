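#' Write a scenario configuration to a YAML file
#'
#' Serialises the user-set structural parameters together with the solved
#' intercepts and scenario label. [read_scenario_config()] reconstructs the
#' configuration from the user-set fields (re-solving the intercepts), so a
#' round trip reproduces the object exactly.
#'
#' @param cfg a [scenario_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(cfg, path) {
  validate_scenario_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a scenario configuration from a YAML file
#'
#' @param path file written by [write_scenario_config()] or hand-authored
#'   with the same fields (derived fields `alpha_0`, `beta_0`, `gamma_0`,
#'   `scenario_label` may be omitted; they are re-solved).
#' @return a validated [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  x <- .fix_yaml_n(yaml::read_yaml(path))
  det <- identical(x$missingness, "deterministic") ||
    identical(x$missingness, "deterministic_1_minus_U")
  scenario_config(
    pi_U = x$pi_U,
    alpha_U = x$alpha_U %||% 0,
    sigma_A = x$sigma_A %||% 1,
    missingness = if (det) "deterministic" else "logistic",
    beta_U = if (det) 0 else x$beta_U %||% 0,
    beta_A = if (det) 0 else x$beta_A %||% 0,
    beta_UA = if (det) 0 else x$beta_UA %||% 0,
    target_p_missing = if (det) NULL else x$target_p_missing,
    gamma_U = x$gamma_U %||% 0,
    gamma_A = x$gamma_A %||% 1,
    gamma_UA = x$gamma_UA %||% 0,
    sigma_Y = x$sigma_Y %||% 1,
    u_observed = isTRUE(x$u_observed),
    n = x$n %||% 10000L,
    cell_id = x$cell_id %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

# YAML 1.1 treats a bare key `n` as the boolean FALSE; restore it.
.fix_yaml_n <- function(x) {
  names(x)[names(x) %in% c("FALSE", "false")] <- "n"
  x
}

#' Read a grid specification from a YAML file
#'
#' Any subset of the [grid_spec()] arguments may appear; omitted fields take
#' the full-factorial defaults.
#'
#' @param path YAML file path.
#' @return a [grid_spec()].
#' @export
read_grid_spec <- function(path) {
  x <- .fix_yaml_n(yaml::read_yaml(path))
  allowed <- names(formals(grid_spec))
  bad <- setdiff(names(x), allowed)
  if (length(bad)) stop("unknown grid_spec fields: ", paste(bad, collapse = ", "))
  do.call(grid_spec, x)
}
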