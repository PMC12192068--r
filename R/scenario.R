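#' Rate constants of the SIIRR model
#'
#' Bundles the four per-capita rate constants and the total population of
#' the two-strain model. `tau1`, `tau2` are the mass-action transmission
#' rates of strain 1 and strain 2; `rho1`, `rho2` are the corresponding
#' recovery rates. All rates have units 1/time (model time is abstract);
#' `N` is the constant total population, treated as continuous.
#'
#' @param tau1,tau2 Transmission rates, `>= 0`, finite.
#' @param rho1,rho2 Recovery rates, `> 0`, finite.
#' @param N Total population, `> 0`.
#' @return An object of class `siirr_params` (a named list).
#' @examples
#' siirr_params(tau1 = 0.01, tau2 = 0.009, rho1 = 5e-4, rho2 = 6e-4, N = 1e6)
#' @export
siirr_params <- function(tau1, tau2, rho1, rho2, N) {
  vals <- c(tau1 = tau1, tau2 = tau2, rho1 = rho1, rho2 = rho2, N = N)
  if (!all(is.finite(vals))) {
    abort("all model parameters must be finite numbers")
  }
  if (tau1 < 0 || tau2 < 0) abort("transmission rates tau1, tau2 must be >= 0")
  if (rho1 <= 0 || rho2 <= 0) abort("recovery rates rho1, rho2 must be > 0")
  if (N <= 0) abort("total population N must be > 0")
  structure(as.list(vals), class = "siirr_params")
}

#' @export
print.siirr_params <- function(x, ...) {
  cat("<siirr_params>",
      sprintf("tau1 = %g, tau2 = %g, rho1 = %g, rho2 = %g, N = %g",
              x$tau1, x$tau2, x$rho1, x$rho2, x$N), sep = "\n")
  invisible(x)
}

#' Compartment state of the SIIRR model
#'
#' A single point of the five-compartment state space: susceptible `S`,
#' infected by strain 1 or 2 (`I1`, `I2`), recovered from strain 1 or 2
#' (`R1`, `R2`). Counts are continuous (deterministic mean-field reading
#' of the ODE system). All components must be non-negative and finite.
#'
#' @param S,I1,I2,R1,R2 Compartment counts.
#' @return A named numeric vector of length 5.
#' @export
siirr_state <- function(S, I1, I2, R1, R2) {
  y <- c(S = S, I1 = I1, I2 = I2, R1 = R1, R2 = R2)
  validate_state(y)
  y
}

validate_state <- function(y, tol = 0) {
  if (!is.numeric(y) || length(y) != 5L) {
    abort("a SIIRR state has exactly five numeric components (S, I1, I2, R1, R2)")
  }
  if (!all(is.finite(y))) abort("non-finite state component: invalid state")
  if (any(y < -tol)) abort("state components must be non-negative")
  invisible(y)
}

#' Define a simulation scenario
#'
#' A scenario is an initial state plus rate constants and integration
#' horizon. By default the total population is computed from the initial
#' state, `N = S0 + I1_0 + I2_0 + R1_0 + R2_0`, so that the conservation
#' law holds by construction. An explicit larger `N` may be supplied to
#' model a pre-existing immune (recovered) pool: the surplus is split
#' equally between `R1(0)` and `R2(0)`, which leaves the susceptible and
#' infected dynamics untouched. This is how the reference scenarios that
#' vary `S(0)` at fixed total population are encoded.
#'
#' @param S0,I1_0,I2_0 Initial susceptible / infected counts.
#' @param R1_0,R2_0 Initial recovered counts (default 0).
#' @param tau1,tau2,rho1,rho2 Rate constants, see [siirr_params()].
#' @param N Optional explicit total population (must be at least the sum
#'   of the initial compartments).
#' @param t_end Optional integration horizon (`> 0`). When `NULL` the
#'   simulator chooses a horizon that runs the epidemic to effective
#'   extinction (both infected classes below one individual), capped at
#'   `1e5` time units.
#' @param n_out Number of uniformly spaced output grid points (`>= 2`).
#' @param label Free-text label.
#' @return An object of class `siirr_scenario`.
#' @examples
#' sc <- siirr_scenario(S0 = 998990, I1_0 = 1000, I2_0 = 10,
#'                      tau1 = 0.01, tau2 = 0.009, rho1 = 5e-4, rho2 = 6e-4)
#' sc$params$N # 1e6, computed from the initial state
#' @export
siirr_scenario <- function(S0, I1_0, I2_0, R1_0 = 0, R2_0 = 0,
                           tau1, tau2, rho1, rho2,
                           N = NULL, t_end = NULL, n_out = 4001,
                           label = "") {
  y0 <- c(S = S0, I1 = I1_0, I2 = I2_0, R1 = R1_0, R2 = R2_0)
  validate_state(y0)
  total <- sum(y0)
  if (is.null(N)) {
    N <- total
  } else {
    if (!is.finite(N) || N < total - 1e-9 * total) {
      abort("explicit N must be finite and at least the sum of the initial compartments")
    }
    surplus <- N - total
    y0[["R1"]] <- y0[["R1"]] + surplus / 2
    y0[["R2"]] <- y0[["R2"]] + surplus / 2
  }
  if (N <= 0) abort("scenario has zero total population")
  params <- siirr_params(tau1, tau2, rho1, rho2, N)
  if (!is.null(t_end) && (!is.finite(t_end) || t_end <= 0)) {
    abort("t_end must be a positive number")
  }
  if (!is.numeric(n_out) || n_out < 2) abort("n_out must be >= 2")
  structure(
    list(params = params, initial = y0, t_end = t_end,
         n_out = as.integer(n_out), label = label),
    class = "siirr_scenario"
  )
}

#' @export
print.siirr_scenario <- function(x, ...) {
  cat(sprintf("<siirr_scenario> %s\n", if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  initial: S=%g I1=%g I2=%g R1=%g R2=%g (N=%g)\n",
              x$initial[["S"]], x$initial[["I1"]], x$initial[["I2"]],
              x$initial[["R1"]], x$initial[["R2"]], x$params$N))
  cat(sprintf("  rates:   tau1=%g tau2=%g rho1=%g rho2=%g\n",
              x$params$tau1, x$params$tau2, x$params$rho1, x$params$rho2))
  cat(sprintf("  horizon: t_end=%s, n_out=%d\n",
              if (is.null(x$t_end)) "auto" else format(x$t_end), x$n_out))
  invisible(x)
}

#' Swap the two strains of a scenario
#'
#' Exchanges `(tau1, rho1, I1(0), R1(0))` with `(tau2, rho2, I2(0), R2(0))`.
#' By the symmetry of the model equations the resulting trajectory is the
#' original one with the per-strain compartments exchanged.
#'
#' @param scenario A [siirr_scenario()].
#' @return A `siirr_scenario` with strains exchanged.
#' @export
swap_strains <- function(scenario) {
  stopifnot(inherits(scenario, "siirr_scenario"))
  p <- scenario$params
  y <- scenario$initial
  siirr_scenario(
    S0 = y[["S"]], I1_0 = y[["I2"]], I2_0 = y[["I1"]],
    R1_0 = y[["R2"]], R2_0 = y[["R1"]],
    tau1 = p$tau2, tau2 = p$tau1, rho1 = p$rho2, rho2 = p$rho1,
    t_end = scenario$t_end, n_out = scenario$n_out,
    label = paste0(scenario$label, " (strains swapped)")
  )
}
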