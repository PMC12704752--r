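# Scenario configuration (YAML) and trace CSV input/output.

#' Read a scenario configuration from YAML
#'
#' A configuration file has optional blocks `geometry`, `parameters`,
#' `perturbation` and `simulation` (fields `t_end`, `dt_out`, `t_start`);
#' every field is optional and falls back to the shipped defaults.
#' Unknown keys in any block are rejected.
#'
#' @param path Path to a YAML file.
#' @return A list with `geometry`, `parameters`, `perturb` and
#'   `simulation` components ready for [simulate_follicle()].
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known_blocks <- c("geometry", "parameters", "perturbation", "simulation")
  extra <- setdiff(names(cfg), known_blocks)
  if (length(extra))
    stop("unknown configuration block(s): ", paste(extra, collapse = ", "))

  build <- function(block, fun) {
    args <- cfg[[block]]
    if (is.null(args)) args <- list()
    bad <- setdiff(names(args), names(formals(fun)))
    if (length(bad))
      stop(sprintf("unknown key(s) in '%s': %s", block,
                   paste(bad, collapse = ", ")))
    do.call(fun, args)
  }
  sim <- cfg$simulation
  if (is.null(sim)) sim <- list()
  bad <- setdiff(names(sim), c("t_end", "dt_out", "t_start"))
  if (length(bad))
    stop("unknown key(s) in 'simulation': ", paste(bad, collapse = ", "))
  list(geometry = build("geometry", follicle_geometry),
       parameters = build("parameters", model_parameters),
       perturb = build("perturbation", perturbation_config),
       simulation = utils::modifyList(
         list(t_end = 300, dt_out = 0.5, t_start = -10), sim))
}

#' Run a simulation described by a YAML configuration
#'
#' @param path Path to a YAML scenario configuration.
#' @return A `compartment_traces` data.frame.
#' @export
simulate_from_config <- function(path) {
  cfg <- read_scenario_config(path)
  simulate_follicle(cfg$parameters, cfg$geometry, cfg$perturb,
                    t_end = cfg$simulation$t_end,
                    dt_out = cfg$simulation$dt_out,
                    t_start = cfg$simulation$t_start)
}

#' Write compartment traces to CSV
#'
#' Columns `t_min, cAMP_oocyte, cAMP_cumulus, cAMP_mural, cGMP_oocyte,
#' cGMP_cumulus, cGMP_mural` (nM, 6 significant digits).
#'
#' @param traces A `compartment_traces` data.frame.
#' @param path Output file.
#' @export
write_traces_csv <- function(traces, path) {
  cols <- c("t_min", "cAMP_oocyte", "cAMP_cumulus", "cAMP_mural",
            "cGMP_oocyte", "cGMP_cumulus", "cGMP_mural")
  out <- traces[, cols]
  out[] <- lapply(out, signif, digits = 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read compartment traces from CSV
#'
#' @param path A CSV written by [write_traces_csv()].
#' @return A `compartment_traces` data.frame.
#' @export
read_traces_csv <- function(path) {
  tr <- utils::read.csv(path)
  need <- c("t_min", "cAMP_oocyte", "cAMP_cumulus", "cAMP_mural",
            "cGMP_oocyte", "cGMP_cumulus", "cGMP_mural")
  miss <- setdiff(need, names(tr))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  class(tr) <- c("compartment_traces", "data.frame")
  tr
}
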