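# Numerically safe hyperbolic helpers: sech2(u) = 1/cosh(u)^2 and the
# logistic sigma(x) = 1/(1+exp(x)) evaluated in the log domain so that
# arguments of any magnitude neither overflow nor underflow abruptly.
sech2 <- function(u) {
  e <- exp(-abs(u))
  (2 * e / (1 + e * e))^2
}
sigma_log <- function(x) stats::plogis(-x)

#' Exact susceptible count as a function of the recovered counts
#'
#' Integrating the reduced system gives the exact first integral
#' \deqn{S = S(0)\,e^{-\tau_1 R_1/(\rho_1 N)}\,e^{-\tau_2 R_2/(\rho_2 N)}}
#' (with the convention `R1(0) = R2(0) = 0`). This relation is exact, not
#' a truncation: along any integrated trajectory it reproduces `S(t)`
#' from `R1(t)`, `R2(t)` to integrator tolerance.
#'
#' @param R1,R2 Recovered counts (vectors, `>= 0`).
#' @param params A [siirr_params()].
#' @param S0 Initial susceptible count.
#' @return Susceptible count(s).
#' @export
s_of_r <- function(R1, R2, params, S0) {
  S0 * exp(-params$tau1 * R1 / (params$rho1 * params$N)) *
    exp(-params$tau2 * R2 / (params$rho2 * params$N))
}

#' Truncated series approximation of the susceptible count
#'
#' The solvable chain replaces the exponential in [s_of_r()] (with the
#' second strain's factor taken as 1) by the order-`M` partial sum with
#' term `(-\tau_1 R_1/(\rho_1 N))^j` — a geometric partial sum in
#' `x = \tau_1 R_1/(\rho_1 N)`. For `x < 1` the partial sum converges to
#' `S0/(1+x)` with error bounded by `S0 x^{M+1}/(1-x)`; its usefulness as
#' an approximation of the exponential additionally requires `x << 1`,
#' which is what [validity_metric()] monitors. At `M = 1` the geometric
#' and exponential readings coincide through first order.
#'
#' @param R1 Strain-1 recovered count (vector).
#' @param params A [siirr_params()].
#' @param S0 Initial susceptible count.
#' @param M Truncation order (integer `>= 0`).
#' @return Approximate susceptible count(s).
#' @export
s_taylor <- function(R1, params, S0, M = 1) {
  x <- params$tau1 * R1 / (params$rho1 * params$N)
  acc <- rep(1, length(x))
  term <- rep(1, length(x))
  if (M >= 1) for (j in seq_len(M)) {
    term <- term * (-x)
    acc <- acc + term
  }
  S0 * acc
}

#' Constants of the closed-form solution chain
#'
#' Builds every constant of the `M = 1`, `W = 0` solution branch from a
#' scenario's initial conditions. The chain truncates the susceptible
#' count to first order in `R1`, which turns the second-order equation
#' for `R1` into a Riccati equation
#' \deqn{dR_1/dt = \alpha_2 R_1^2 + \alpha_1 R_1 + \alpha_0}
#' with
#' \deqn{\alpha_0 = C = \rho_1 I_1(0),\quad
#'       \alpha_1 = \tau_1 S(0)/N - \rho_1,\quad
#'       \alpha_2 = -\tau_1^2 S(0)/(2\rho_1 N^2).}
#' (`C` is pinned by evaluating the integrated equation at `t = 0`, where
#' `R1 = 0` and `dR1/dt = rho1 I1(0)`.) The discriminant
#' `theta^2 = alpha1^2 - 4 alpha0 alpha2` is positive whenever
#' `S(0), I1(0) > 0`. The time-shift `V` is obtained by root-solving the
#' defining requirement `R1(0) = 0` (a monotone one-dimensional problem),
#' and the strain-2 constant `D` by enforcing `R2(0) = 0` on the linear
#' solution. The printed closed-form counterparts (`theta` from the
#' radical, `V` from the arc-tanh expression, `D = S(0) - N`) are
#' evaluated and stored alongside as cross-checks.
#'
#' The strain-2 branch of the chain additionally requires
#' `rho2 == rho1`; constants are computed for any parameters, but
#' [r2_analytic()] and [i2_analytic()] refuse to evaluate when the
#' special case does not hold.
#'
#' @param params A [siirr_params()].
#' @param S0 Initial susceptible count (`> 0`).
#' @param I1_0 Initial strain-1 infected count (`> 0`).
#' @return An object of class `riccati_constants`.
#' @examples
#' p <- siirr_params(0.012, 0.009, 5e-4, 5e-4, N = 1e6)
#' rc <- riccati_constants(p, S0 = 998990, I1_0 = 1000)
#' r1_analytic(0, rc) # ~0 by construction
#' @export
riccati_constants <- function(params, S0, I1_0) {
  if (S0 <= 0 || I1_0 <= 0) abort("S0 and I1_0 must be > 0")
  tau1 <- params$tau1; rho1 <- params$rho1; rho2 <- params$rho2; N <- params$N
  C <- rho1 * I1_0
  alpha0 <- C
  alpha1 <- tau1 * S0 / N - rho1
  alpha2 <- -tau1^2 * S0 / (2 * rho1 * N^2)
  theta2 <- alpha1^2 - 4 * alpha0 * alpha2
  if (theta2 <= 0) abort("solution family invalid for these parameters (theta^2 <= 0)")
  theta <- sqrt(theta2)
  A <- -alpha1 / (2 * alpha2)
  B <- -theta / (2 * alpha2)
  # R1(0) = A + B tanh(theta V / 2) = 0; monotone in V since B > 0.
  # |A/B| = |alpha1|/theta < 1 guarantees a bracketing interval.
  v_lim <- 2 * atanh(1 - 1e-12) / theta
  V <- uniroot(function(v) A + B * tanh(theta * v / 2),
               lower = -v_lim, upper = v_lim, tol = 1e-14 * max(1, v_lim))$root
  V_closed <- (2 / theta) * atanh(-alpha1 / theta)
  # linear chain for R2 (coefficients of q(R1) = beta0 + (beta1+gamma1) R1
  # + beta2 R1^2, evaluated along the Riccati solution)
  beta0 <- -alpha0 * rho2 / rho1 + rho2 * N - rho2 * S0
  beta1 <- -rho2 * alpha1 / rho1 - rho2 - rho2 * S0 * tau1 / (rho1 * N)
  gamma1 <- rho2 * S0 * tau1 / (rho1 * N)
  beta2 <- -rho2 / rho1 * alpha2
  lambda_lin <- beta1 + gamma1
  p <- rho2
  R1_inf <- A + B
  # particular solution R2_p = K - (theta/alpha2) sigma(theta (t+V)); the
  # constant matches the t -> Inf limit of q / p (valid when rho2 == rho1)
  K <- (beta0 + lambda_lin * R1_inf + beta2 * R1_inf^2) / p
  D <- (theta / alpha2) * sigma_log(theta * V) - K
  # printed cross-checks (grouping of the radical resolved so that it
  # coincides with sqrt(alpha1^2 - 4 alpha0 alpha2) when rho2 == rho1)
  theta_printed <- sqrt(N^2 * rho2^3 - 2 * N * S0 * rho2^2 * tau1 +
                          S0^2 * rho2 * tau1^2 + 2 * C * S0 * tau1^2) /
    (N * sqrt(rho2))
  D_printed <- S0 - N
  structure(
    list(M = 1L, C = C, alpha0 = alpha0, alpha1 = alpha1, alpha2 = alpha2,
         theta = theta, V = V, D = D, W = 0, E = 1, p = p,
         beta0 = beta0, beta1 = beta1, beta2 = beta2, gamma1 = gamma1,
         lambda_lin = lambda_lin, K = K, R1_inf = R1_inf,
         V_closed = V_closed, theta_printed = theta_printed,
         D_printed = D_printed,
         params = params, S0 = S0, I1_0 = I1_0),
    class = "riccati_constants"
  )
}

#' @export
print.riccati_constants <- function(x, ...) {
  cat("<riccati_constants> (M = 1 branch)\n")
  cat(sprintf("  alpha: %g, %g, %g  theta: %g\n",
              x$alpha0, x$alpha1, x$alpha2, x$theta))
  cat(sprintf("  V: %g (closed form %g)  D: %g (printed %g)\n",
              x$V, x$V_closed, x$D, x$D_printed))
  cat(sprintf("  peak time -V: %g  peak height: %g\n",
              -x$V, -x$theta^2 / (4 * x$params$rho1 * x$alpha2)))
  invisible(x)
}

#' @rdname riccati_constants
#' @param x A `riccati_constants` object.
#' @param ... Unused.
#' @export
tidy.riccati_constants <- function(x, ...) {
  keep <- c("C", "alpha0", "alpha1", "alpha2", "theta", "V", "D", "W", "E",
            "p", "beta0", "beta1", "beta2", "gamma1", "K",
            "R1_inf", "V_closed", "theta_printed", "D_printed")
  tibble(constant = keep, value = vapply(x[keep], as.numeric, numeric(1)))
}

#' @rdname riccati_constants
#' @export
glance.riccati_constants <- function(x, ...) {
  tibble(
    theta = x$theta,
    t_peak = -x$V,
    peak_height = -x$theta^2 / (4 * x$params$rho1 * x$alpha2),
    final_size_R1 = x$R1_inf,
    rho_equal = x$params$rho2 == x$params$rho1
  )
}

require_r2_branch <- function(constants) {
  p <- constants$params
  if (p$rho2 != p$rho1) {
    abort(paste("the closed-form R2 branch requires rho2 == rho1;",
                "integrate the full system numerically instead"))
  }
  if (constants$W != 0) abort("the closed-form R2 branch requires W = 0")
  invisible(constants)
}

#' Closed-form cumulative strain-1 recovered count
#'
#' The `W = 0` branch is the tanh special solution of the Riccati
#' equation,
#' \deqn{R_1(t) = -\frac{\alpha_1}{2\alpha_2}
#'   - \frac{\theta}{2\alpha_2}\tanh\frac{\theta(t+V)}{2},}
#' a monotone non-decreasing curve rising from 0 to the final epidemic
#' size `(-alpha1 - theta)/(2 alpha2)`. With `W != 0` the general
#' solution adds `W / (cosh^2(u) (E - (2 alpha2 W/theta) tanh u))` with
#' `u = theta (t+V)/2`; a vanishing denominator is a pole and raises an
#' error reporting the offending time.
#'
#' @param t Time(s).
#' @param constants A [riccati_constants()].
#' @param W,E Constants of the general branch (defaults: the `W = 0`
#'   special solution).
#' @return `R1(t)` value(s).
#' @export
r1_analytic <- function(t, constants, W = constants$W, E = constants$E) {
  a1 <- constants$alpha1; a2 <- constants$alpha2; th <- constants$theta
  u <- th * (t + constants$V) / 2
  base <- -a1 / (2 * a2) - th / (2 * a2) * tanh(u)
  if (W == 0) return(base)
  den <- E - (2 * a2 * W / th) * tanh(u)
  bad <- which(abs(den) < 1e-300)
  if (length(bad)) abort(sprintf("pole of the general solution at t = %g", t[bad[1]]))
  base + W * sech2(u) / den
}

#' Closed-form cumulative strain-2 recovered count
#'
#' Valid for the solvable special case `W = 0`, `rho2 == rho1`: the
#' linear equation `dR2/dt + rho2 R2 = q(R1(t))` then has the exact
#' solution
#' \deqn{R_2(t) = D e^{-\rho_1 t}
#'   - \frac{\theta}{\alpha_2\{1 + e^{\theta(t+V)}\}} + K,}
#' where the constant `K` collects the long-time limit of `q/\rho_2` and
#' `D` enforces `R2(0) = 0`. As `t` grows the decaying exponential and
#' the logistic term both vanish, so `R2` approaches the finite plateau
#' `K` — the strain-2 final size.
#'
#' @param t Time(s).
#' @param constants A [riccati_constants()] built with `rho2 == rho1`.
#' @return `R2(t)` value(s).
#' @export
r2_analytic <- function(t, constants) {
  require_r2_branch(constants)
  th <- constants$theta; a2 <- constants$alpha2
  constants$D * exp(-constants$p * t) + constants$K -
    (th / a2) * sigma_log(th * (t + constants$V))
}

#' Closed-form strain-1 infected count
#'
#' Via `I1 = rho1^{-1} dR1/dt`, the `W = 0` branch gives the symmetric
#' bell
#' \deqn{I_1(t) = -\frac{\theta^2}{4\rho_1\alpha_2}
#'   \,\mathrm{sech}^2\frac{\theta(t+V)}{2},}
#' with maximum `-theta^2/(4 rho1 alpha2)` (positive, since `alpha2 < 0`)
#' attained at `t = -V`.
#'
#' @param t Time(s).
#' @param constants A [riccati_constants()].
#' @return `I1(t)` value(s).
#' @export
i1_analytic <- function(t, constants) {
  th <- constants$theta
  -th^2 / (4 * constants$params$rho1 * constants$alpha2) *
    sech2(th * (t + constants$V) / 2)
}

#' Closed-form strain-2 infected count
#'
#' Via `I2 = rho2^{-1} dR2/dt` on the `W = 0`, `rho2 == rho1` branch:
#' \deqn{I_2(t) = \frac{1}{\rho_2}\left[-\rho_1 D e^{-\rho_1 t}
#'   + \frac{\theta^2 e^{\theta(t+V)}}
#'          {\alpha_2\{1 + e^{\theta(t+V)}\}^2}\right].}
#' With constants built from the initial conditions, `I2(0)` equals the
#' scenario's implied initial strain-2 count `N - S0 - I1(0)` exactly.
#' In the regime the chain is built for (strain 2 negligible) the curve
#' decays monotonically from `t = 0`.
#'
#' @param t Time(s).
#' @param constants A [riccati_constants()] built with `rho2 == rho1`.
#' @return `I2(t)` value(s).
#' @export
i2_analytic <- function(t, constants) {
  require_r2_branch(constants)
  th <- constants$theta; a2 <- constants$alpha2
  x <- th * (t + constants$V)
  # e^x/(1+e^x)^2 = sech^2(x/2)/4, log-domain safe
  bell <- th^2 / a2 * sech2(x / 2) / 4
  (-constants$p * constants$D * exp(-constants$p * t) + bell) / constants$params$rho2
}

#' Evaluate the full analytic solution on a time grid
#'
#' Convenience wrapper: builds constants from a scenario (which must have
#' `R1(0) = R2(0) = 0`) and evaluates the closed-form curves. The
#' susceptible column is the truncated series [s_taylor()] evaluated
#' along the analytic `R1` — the approximation the chain itself uses.
#'
#' @param scenario A [siirr_scenario()] with no initial recovered pool.
#' @param times Time grid; default `n_out` uniform points covering twice
#'   the analytic peak time (or the scenario horizon when set).
#' @return A tibble `t, S_approx, I1, I2, R1, R2` with the constants
#'   attached as attribute `"constants"`.
#' @export
siirr_analytic <- function(scenario, times = NULL) {
  y0 <- scenario$initial
  if (y0[["R1"]] != 0 || y0[["R2"]] != 0) {
    abort("the analytic chain assumes R1(0) = R2(0) = 0")
  }
  rc <- riccati_constants(scenario$params, y0[["S"]], y0[["I1"]])
  if (is.null(times)) {
    t_end <- scenario$t_end %||% max(2 * (-rc$V), 10 / rc$theta)
    times <- seq(0, t_end, length.out = scenario$n_out)
  }
  R1 <- r1_analytic(times, rc)
  out <- tibble(
    t = times,
    S_approx = s_taylor(R1, scenario$params, y0[["S"]], M = rc$M),
    I1 = i1_analytic(times, rc),
    I2 = i2_analytic(times, rc),
    R1 = R1,
    R2 = r2_analytic(times, rc)
  )
  attr(out, "constants") <- rc
  out
}

#' Validity diagnostics of the truncated chain
#'
#' The chain assumes `tau1 R1/(rho1 N) << 1` and `tau2 R2/(rho2 N) << 1`.
#' This reports the maxima of both dimensionless ratios over the horizon
#' and flags the regime as acceptable when both stay below `threshold`.
#' Accepts an integrated trajectory, or a `riccati_constants` object (the
#' analytic curves are then evaluated out to their own plateau).
#'
#' @param x A `siirr_trajectory` or [riccati_constants()].
#' @param threshold Regime flag threshold (default 0.2, dimensionless).
#' @return A one-row tibble: `strain1_max`, `strain2_max`, `regime_ok`.
#' @export
validity_metric <- function(x, threshold = 0.2) {
  if (inherits(x, "riccati_constants")) {
    p <- x$params
    tt <- seq(0, max(2 * abs(x$V), 20 / x$theta), length.out = 512)
    R1 <- r1_analytic(tt, x)
    R2 <- if (p$rho2 == p$rho1) r2_analytic(tt, x) else rep(0, length(tt))
  } else {
    p <- trajectory_params(x)
    R1 <- x$R1; R2 <- x$R2
  }
  m1 <- max(p$tau1 * R1 / (p$rho1 * p$N))
  m2 <- max(p$tau2 * R2 / (p$rho2 * p$N))
  tibble(strain1_max = m1, strain2_max = m2,
         regime_ok = m1 < threshold && m2 < threshold)
}
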