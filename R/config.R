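#' Run configuration
#'
#' Bundles every tunable of a boundary-condition run: physical constants,
#' tree parameters, the vessel-group table, solver tolerances and unit /
#' calibration switches.  All downstream functions take a `run_config`
#' so a whole analysis is reproducible from one object (or one YAML
#' file, see [read_run_config()]).
#'
#' @param variant default outflow variant: `"zero_pressure"`,
#'   `"conventional_0d"` (constant \eqn{\lambda = 30}, zero terminal
#'   resistance) or `"present_0d"` (group-wise \eqn{\lambda}, terminal
#'   pressure fixed point).
#' @param params [tree_params()].
#' @param props [blood_properties()].
#' @param table [vessel_group_table()]; `NULL` loads the packaged table.
#' @param coupling_tol convergence tolerance of the coupled solver: the
#'   maximum relative change of any outlet flow between iterations
#'   (default 1e-4, mirroring a residual-oscillation criterion of order
#'   1e-4).
#' @param max_iterations iteration cap of the coupled solver.
#' @param lambda_constant the \eqn{\lambda} of the conventional variant.
#' @param viscosity_mode,hct_ratio,log_base viscosity-law switches, see
#'   [apparent_viscosity()].
#' @param reference_velocity mean velocity (m/s) used to set a reference
#'   flow when a standalone boundary-condition file is built for an
#'   outlet without a measured velocity.
#' @param seed optional integer seed recorded in output provenance.
#' @return an object of class `run_config`.
#' @export
run_config <- function(variant = c("present_0d", "conventional_0d",
                                   "zero_pressure"),
                       params = tree_params(),
                       props = blood_properties(),
                       table = NULL,
                       coupling_tol = 1e-4,
                       max_iterations = 1000,
                       lambda_constant = 30,
                       viscosity_mode = c("calibrated", "literal"),
                       hct_ratio = c("printed", "classical"),
                       log_base = c("log10", "ln"),
                       reference_velocity = 0.2,
                       seed = NULL) {
  variant <- match.arg(variant)
  viscosity_mode <- match.arg(viscosity_mode)
  hct_ratio <- match.arg(hct_ratio)
  log_base <- match.arg(log_base)
  stopifnot(inherits(params, "tree_params"),
            inherits(props, "blood_properties"))
  if (is.null(table)) table <- vessel_group_table()
  stopifnot(inherits(table, "vessel_group_table"))
  check_positive(coupling_tol, "coupling_tol")
  check_positive(max_iterations, "max_iterations")
  check_positive(lambda_constant, "lambda_constant")
  check_positive(reference_velocity, "reference_velocity")
  structure(
    list(variant = variant, params = params, props = props, table = table,
         coupling_tol = coupling_tol,
         max_iterations = as.integer(max_iterations),
         lambda_constant = lambda_constant,
         viscosity_mode = viscosity_mode, hct_ratio = hct_ratio,
         log_base = log_base, reference_velocity = reference_velocity,
         seed = seed),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Unset keys fall back to the [run_config()] defaults.  Recognised
#' nested blocks: `params` (epsilon, terminal_radius_um,
#' terminal_pressure_mmhg), `props` (density, mu_newtonian,
#' mu_newtonian_limit, hct_systemic); `table` may name a CSV path.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (key in c("variant", "coupling_tol", "max_iterations",
                "lambda_constant", "viscosity_mode", "hct_ratio",
                "log_base", "reference_velocity", "seed")) {
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  }
  if (!is.null(y$params)) args$params <- do.call(tree_params, y$params)
  if (!is.null(y$props)) args$props <- do.call(blood_properties, y$props)
  if (!is.null(y$table)) args$table <- vessel_group_table(y$table)
  do.call(run_config, args)
}

## stable hash of a config for provenance headers: canonical JSON -> md5
config_hash <- function(config) {
  stopifnot(inherits(config, "run_config"))
  flat <- config
  flat$table <- as.data.frame(flat$table)
  js <- jsonlite::toJSON(unclass(flat), auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}
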