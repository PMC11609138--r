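# YAML scenario configuration: serialization round-trip for reproducible
# runs. The file mirrors scenario_config(): top-level keys dentition, design,
# staging, traction, engine, seed, check_convergence (all optional, defaults
# apply).

SCENARIO_KEYS <- c("dentition", "design", "staging", "traction", "engine",
                   "seed", "check_convergence")

#' Read a scenario configuration from YAML
#'
#' Unknown top-level keys are rejected by name. Missing keys fall back to the
#' package defaults, so a minimal file like `design: mhw` is valid.
#'
#' @param path YAML file.
#' @return a [scenario_config()].
#' @export
read_scenario_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  bad <- setdiff(names(y), SCENARIO_KEYS)
  if (length(bad) > 0) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  den <- do.call(dentition_config, as.list(y$dentition))
  staging <- do.call(staging_plan, as.list(y$staging))
  traction <- if (is.null(y$traction)) {
    traction_config()
  } else if (isFALSE(y$traction) ||
             identical(y$traction, "none")) {
    NULL
  } else {
    do.call(traction_config, as.list(y$traction))
  }
  engine <- do.call(engine_config, as.list(y$engine))
  scenario_config(
    dentition = den,
    design = if (is.null(y$design)) "con" else tolower(y$design),
    staging = staging,
    traction = traction,
    engine = engine,
    seed = if (is.null(y$seed)) 1L else as.integer(y$seed),
    check_convergence = isTRUE(y$check_convergence)
  )
}

#' Write a scenario configuration to YAML
#'
#' The written file re-reads to an identical scenario, making run logs
#' self-reproducing.
#'
#' @param scenario a [scenario_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scenario_yaml <- function(scenario, path) {
  y <- list(
    dentition = unclass(scenario$dentition),
    design = scenario$design,
    staging = list(n_steps = scenario$staging$n_steps,
                   step_increment = scenario$staging$step_increment),
    traction = if (is.null(scenario$traction)) "none" else
      list(magnitude_gf = scenario$traction$magnitude_gf),
    engine = unclass(scenario$engine),
    seed = scenario$seed,
    check_convergence = scenario$check_convergence
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Write a trajectory to CSV
#'
#' @param trajectory an `alignersim_trajectory`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  readr::write_csv(trajectory$records, path)
  invisible(path)
}
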