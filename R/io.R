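#' Write / read a trajectory as CSV
#'
#' Tabular export with header `t,S,I1,I2,R1,R2`, one row per grid point,
#' full precision (17 significant digits, losslessly round-trippable for
#' doubles). The reader re-validates the trajectory invariants; it needs
#' the generating scenario to know `N`, so either pass it or read a file
#' written by [write_trajectory()] alongside its scenario.
#'
#' @param traj A `siirr_trajectory`.
#' @param path File path.
#' @return `write_trajectory()`: `path` invisibly. `read_trajectory()`:
#'   a `siirr_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)[, c("t", "S", "I1", "I2", "R1", "R2")]
  df[] <- lapply(df, function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @param scenario The generating [siirr_scenario()] (required to
#'   re-validate conservation against `N`).
#' @export
read_trajectory <- function(path, scenario) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (file.size(path) == 0) abort("empty trajectory file")
  df <- utils::read.csv(path, colClasses = "numeric")
  req <- c("t", "S", "I1", "I2", "R1", "R2")
  if (!identical(names(df), req)) {
    abort("malformed trajectory CSV: header must be t,S,I1,I2,R1,R2")
  }
  if (nrow(df) == 0) abort("empty trajectory file")
  if (!all(vapply(df, is.numeric, logical(1)))) {
    abort("malformed trajectory CSV: non-numeric rows")
  }
  if (any(diff(df$t) <= 0)) abort("non-monotone time column")
  traj <- new_trajectory(as_tibble(df), scenario)
  validate_trajectory(traj)
  traj
}

config_defaults <- list(rel_tol = 1e-8, abs_tol = 1e-6, n_out = 4001,
                        t_end = NULL)

#' Parse a run configuration
#'
#' Human-editable YAML schema, versioned by the required top-level key
#' `siirr_config: 1`. The `scenario` entry is either the name of a
#' registered scenario (see [siirr_scenarios()]) or an inline map with
#' keys `S0, I1_0, I2_0, tau1, tau2, rho1, rho2` and optional
#' `R1_0, R2_0, N, label`. Optional blocks: `integrator` (`rel_tol`,
#' `abs_tol`, `n_out`, `t_end`), `output` (`trajectory`: a CSV path),
#' `verbosity` (integer). Unknown keys are rejected by name.
#'
#' @param text YAML text, or a file path when `is_file = TRUE`.
#' @param is_file Interpret `text` as a path.
#' @return An object of class `siirr_run_config`: `scenario`,
#'   `integrator`, `output`, `verbosity`.
#' @examples
#' cfg <- parse_config("siirr_config: 1\nscenario: fig1_base\n")
#' cfg$integrator$rel_tol
#' @export
parse_config <- function(text, is_file = FALSE) {
  raw <- if (is_file) yaml::read_yaml(text) else yaml::yaml.load(text)
  if (!is.list(raw)) abort("config must be a YAML mapping")
  known <- c("siirr_config", "scenario", "integrator", "output", "verbosity")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (is.null(raw$siirr_config) || raw$siirr_config != 1) {
    abort("config must declare 'siirr_config: 1'")
  }
  if (is.null(raw$scenario)) abort("missing required field: scenario")
  scenario <- resolve_scenario(raw$scenario)
  integ <- raw$integrator %||% list()
  unknown <- setdiff(names(integ), names(config_defaults))
  if (length(unknown)) {
    abort(sprintf("unknown integrator key(s): %s", paste(unknown, collapse = ", ")))
  }
  integ <- utils::modifyList(config_defaults, integ)
  if (integ$rel_tol <= 0 || integ$abs_tol <= 0) {
    abort("integrator tolerances must be > 0")
  }
  out <- raw$output %||% list()
  unknown <- setdiff(names(out), "trajectory")
  if (length(unknown)) {
    abort(sprintf("unknown output key(s): %s", paste(unknown, collapse = ", ")))
  }
  structure(
    list(scenario = scenario, integrator = integ, output = out,
         verbosity = raw$verbosity %||% 1L,
         scenario_ref = if (is.character(raw$scenario)) raw$scenario else NULL),
    class = "siirr_run_config"
  )
}

resolve_scenario <- function(x) {
  if (is.character(x) && length(x) == 1) return(get_scenario(x))
  if (!is.list(x)) abort("scenario must be a registry name or an inline mapping")
  req <- c("S0", "I1_0", "I2_0", "tau1", "tau2", "rho1", "rho2")
  opt <- c("R1_0", "R2_0", "N", "label", "t_end", "n_out")
  missing <- setdiff(req, names(x))
  if (length(missing)) {
    abort(sprintf("missing required scenario field(s): %s",
                  paste(missing, collapse = ", ")))
  }
  unknown <- setdiff(names(x), c(req, opt))
  if (length(unknown)) {
    abort(sprintf("unknown scenario key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(siirr_scenario, x)
}

#' Serialize a run configuration back to YAML
#'
#' Round-trip partner of [parse_config()]: `parse_config(serialize_config(cfg))`
#' yields an equivalent configuration.
#'
#' @param config A `siirr_run_config`.
#' @return A YAML string.
#' @export
serialize_config <- function(config) {
  stopifnot(inherits(config, "siirr_run_config"))
  sc <- config$scenario
  scenario <- if (!is.null(config$scenario_ref)) config$scenario_ref else {
    y <- sc$initial
    keep <- list(S0 = y[["S"]], I1_0 = y[["I1"]], I2_0 = y[["I2"]],
                 R1_0 = y[["R1"]], R2_0 = y[["R2"]],
                 tau1 = sc$params$tau1, tau2 = sc$params$tau2,
                 rho1 = sc$params$rho1, rho2 = sc$params$rho2,
                 label = sc$label)
  }
  integ <- config$integrator[!vapply(config$integrator, is.null, logical(1))]
  out <- list(siirr_config = 1L, scenario = scenario,
              integrator = integ, verbosity = config$verbosity)
  if (length(config$output)) out$output <- config$output
  yaml::as.yaml(out)
}

#' Execute a run configuration
#'
#' Resolves the scenario, integrates it with the configured tolerances,
#' optionally writes the trajectory CSV, and returns the trajectory.
#' At the default verbosity one log line is emitted per stage.
#'
#' @param config A `siirr_run_config` from [parse_config()].
#' @return The integrated `siirr_trajectory`, invisibly.
#' @export
run_config <- function(config) {
  stopifnot(inherits(config, "siirr_run_config"))
  sc <- config$scenario
  log_line(config$verbosity, "scenario resolved: %s (N = %g)",
           if (nzchar(sc$label)) sc$label else "inline", sc$params$N)
  traj <- siirr_integrate(sc, rel_tol = config$integrator$rel_tol,
                          abs_tol = config$integrator$abs_tol,
                          t_end = config$integrator$t_end,
                          n_out = config$integrator$n_out)
  log_line(config$verbosity, "integrated to t = %g on %d grid points",
           max(traj$t), nrow(traj))
  if (!is.null(config$output$trajectory)) {
    write_trajectory(traj, config$output$trajectory)
    log_line(config$verbosity, "trajectory written: %s", config$output$trajectory)
  }
  invisible(traj)
}

log_line <- function(verbosity, fmt, ...) {
  if (verbosity >= 1) message(sprintf(fmt, ...))
}
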