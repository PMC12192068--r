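#' Integrate a SIIRR scenario
#'
#' Integrates the five-compartment system with an adaptive-step solver
#' (lsoda) and returns the solution on a uniform output grid. The system
#' is smooth and non-stiff but horizons are long at the reference rates,
#' so defaults are tight: `rel_tol = 1e-8`, `abs_tol = 1e-6` (state
#' units). When the scenario has no explicit horizon, the horizon is
#' grown by doubling (from 1000 time units) until both infected classes
#' are below one individual at the end point, with a hard cap of `1e5`.
#'
#' The returned trajectory is checked against the model invariants:
#' conservation `|S+I1+I2+R1+R2-N| <= 1e-8 N` at every grid point,
#' non-increasing `S`, non-decreasing `R1`, `R2`, and positivity within
#' `1e-6 N`.
#'
#' @param scenario A [siirr_scenario()].
#' @param rel_tol,abs_tol Integrator tolerances (`> 0`).
#' @param t_end,n_out Optional overrides of the scenario's grid.
#' @return A tibble of class `siirr_trajectory` with columns
#'   `t, S, I1, I2, R1, R2` and the generating scenario stored as an
#'   attribute.
#' @examples
#' sc <- siirr_scenario(998990, 1000, 10, tau1 = 0.01, tau2 = 0.009,
#'                      rho1 = 5e-4, rho2 = 6e-4, label = "base")
#' traj <- siirr_integrate(sc)
#' find_peaks(traj)
#' @export
siirr_integrate <- function(scenario, rel_tol = 1e-8, abs_tol = 1e-6,
                            t_end = NULL, n_out = NULL) {
  stopifnot(inherits(scenario, "siirr_scenario"))
  if (rel_tol <= 0 || abs_tol <= 0) abort("integrator tolerances must be > 0")
  n_out <- n_out %||% scenario$n_out
  t_end <- t_end %||% scenario$t_end
  if (is.null(t_end)) {
    t_end <- auto_horizon(scenario, rel_tol, abs_tol)
  }
  times <- seq(0, t_end, length.out = n_out)
  out <- integrate_raw(scenario, times, rel_tol, abs_tol)
  traj <- as_tibble(as.data.frame(out))
  names(traj)[1] <- "t"
  traj <- new_trajectory(traj, scenario)
  validate_trajectory(traj)
  traj
}

new_trajectory <- function(df, scenario) {
  structure(df, scenario = scenario,
            class = c("siirr_trajectory", class(tibble())))
}

integrate_raw <- function(scenario, times, rel_tol, abs_tol) {
  p <- scenario$params
  deriv <- function(t, y, parms) {
    S <- y[1L]; I1 <- y[2L]; I2 <- y[3L]
    inf1 <- p$tau1 * S * I1 / p$N
    inf2 <- p$tau2 * S * I2 / p$N
    rec1 <- p$rho1 * I1
    rec2 <- p$rho2 * I2
    list(c(-inf1 - inf2, inf1 - rec1, inf2 - rec2, rec1, rec2))
  }
  out <- deSolve::ode(scenario$initial, times, deriv, parms = NULL,
                      method = "lsoda", rtol = rel_tol, atol = abs_tol)
  if (attr(out, "istate")[1L] < 0) {
    abort(sprintf("integrator failure near t = %g", max(out[, 1L])))
  }
  out
}

# Doubling search for a horizon at which both epidemics are extinct
# (max infected < 1 individual), capped at 1e5 model-time units.
auto_horizon <- function(scenario, rel_tol, abs_tol, cap = 1e5) {
  t_try <- 1000
  repeat {
    out <- integrate_raw(scenario, c(0, t_try), rel_tol, abs_tol)
    last <- out[nrow(out), ]
    if (max(last[["I1"]], last[["I2"]]) < 1 || t_try >= cap) return(t_try)
    t_try <- min(t_try * 2, cap)
  }
}

trajectory_scenario <- function(traj) {
  sc <- attr(traj, "scenario")
  if (is.null(sc)) abort("trajectory carries no scenario attribute")
  sc
}

trajectory_params <- function(traj) trajectory_scenario(traj)$params

#' Check trajectory invariants
#'
#' Verifies the defining invariants of an integrated trajectory: strictly
#' increasing time grid starting at 0, conservation of the total
#' population within `cons_tol * N`, monotone `S` (non-increasing) and
#' `R1`, `R2` (non-decreasing) within a per-step slack of `1e-9 N`, and
#' positivity within `1e-6 N`.
#'
#' @param traj A `siirr_trajectory`.
#' @param cons_tol Relative conservation tolerance (default `1e-8`).
#' @return `traj`, invisibly; aborts on violation.
#' @export
validate_trajectory <- function(traj, cons_tol = 1e-8) {
  req <- c("t", "S", "I1", "I2", "R1", "R2")
  if (!all(req %in% names(traj))) abort("trajectory must have columns t,S,I1,I2,R1,R2")
  if (traj$t[1] != 0 || any(diff(traj$t) <= 0)) {
    abort("trajectory times must be strictly increasing from 0")
  }
  N <- trajectory_params(traj)$N
  resid <- abs(traj$S + traj$I1 + traj$I2 + traj$R1 + traj$R2 - N)
  if (max(resid) > cons_tol * N) {
    abort(sprintf("conservation violated: max residual %g > %g", max(resid), cons_tol * N))
  }
  slack <- 1e-9 * N
  if (any(diff(traj$S) > slack)) abort("S must be non-increasing")
  if (any(diff(traj$R1) < -slack) || any(diff(traj$R2) < -slack)) {
    abort("R1 and R2 must be non-decreasing")
  }
  if (min(traj$S, traj$I1, traj$I2, traj$R1, traj$R2) < -1e-6 * N) {
    abort("compartment positivity violated beyond tolerance")
  }
  invisible(traj)
}

#' Locate the peak of an infected compartment
#'
#' Finds the global maximum of `I1` or `I2` on the output grid and
#' refines the peak time by a local quadratic fit through the three
#' bracketing points. The profile is classified as `"monotone_decay"`
#' when the grid maximum sits at the first point (including the flat
#' trajectory, by convention `t_peak = 0`), `"bell"` when it is interior,
#' and `"monotone_growth_truncated"` when it sits at the last point.
#' Ties between equal grid maxima resolve to the earliest time.
#'
#' @param traj A `siirr_trajectory` (>= 3 grid points).
#' @param compartment `"I1"` or `"I2"`.
#' @return A one-row tibble: `compartment`, `t_peak`, `value_peak`,
#'   `profile_class`.
#' @export
find_peak <- function(traj, compartment = c("I1", "I2")) {
  compartment <- match.arg(compartment)
  y <- traj[[compartment]]
  t <- traj$t
  if (length(y) < 3) abort("trajectory must have at least 3 grid points")
  i <- which.max(y) # which.max takes the earliest of ties
  if (i == 1L) {
    cls <- "monotone_decay"; tp <- t[1]; vp <- y[1]
  } else if (i == length(y)) {
    cls <- "monotone_growth_truncated"; tp <- t[i]; vp <- y[i]
  } else {
    cls <- "bell"
    tt <- t[(i - 1):(i + 1)]; yy <- y[(i - 1):(i + 1)]
    co <- unname(solve(cbind(1, tt, tt^2), yy))
    if (co[3] < 0) {
      tp <- -co[2] / (2 * co[3])
      vp <- co[1] + co[2] * tp + co[3] * tp^2
    } else { # numerically flat top: keep the grid point
      tp <- t[i]; vp <- y[i]
    }
  }
  tibble(compartment = compartment, t_peak = tp, value_peak = vp,
         profile_class = cls)
}

#' Peaks of both infected compartments
#'
#' @param traj A `siirr_trajectory`.
#' @return A two-row tibble, one [find_peak()] row per strain.
#' @export
find_peaks <- function(traj) {
  dplyr::bind_rows(find_peak(traj, "I1"), find_peak(traj, "I2"))
}

#' Susceptible count at which a strain's infection curve peaks
#'
#' Setting `dI_k/dt = 0` in the model gives the threshold
#' `S = N rho_k / tau_k`: a strain's infected count rises while `S` is
#' above this value and falls below it. Along any trajectory with an
#' interior peak of strain `k`, `S(t_peak)` equals this threshold up to
#' grid/interpolation error.
#'
#' @param params A [siirr_params()].
#' @param strain 1 or 2.
#' @return The threshold susceptible count `N * rho / tau`.
#' @export
s_at_peak_threshold <- function(params, strain) {
  stopifnot(inherits(params, "siirr_params"), strain %in% c(1, 2))
  tau <- if (strain == 1) params$tau1 else params$tau2
  rho <- if (strain == 1) params$rho1 else params$rho2
  if (tau == 0) abort("tau = 0: no finite peak threshold")
  params$N * rho / tau
}

#' Interpolate a trajectory column at arbitrary times
#'
#' Natural cubic spline through the output grid; used to read off, e.g.,
#' `S` at an interpolated peak time.
#'
#' @param traj A `siirr_trajectory`.
#' @param column Column name.
#' @param t Times at which to evaluate.
#' @return Numeric vector of interpolated values.
#' @export
trajectory_at <- function(traj, column, t) {
  splinefun(traj$t, traj[[column]], method = "natural")(t)
}
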