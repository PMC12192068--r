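#' Right-hand side of the SIIRR system
#'
#' Time derivatives of the five compartments under mass-action
#' transmission with absolute cross-protection:
#' \deqn{dS/dt = -\tau_1 S I_1/N - \tau_2 S I_2/N}
#' \deqn{dI_k/dt = \tau_k S I_k/N - \rho_k I_k, \quad dR_k/dt = \rho_k I_k}
#' The five derivatives sum to zero exactly (conservation of `N`).
#'
#' @param state Named numeric state, see [siirr_state()].
#' @param params A [siirr_params()].
#' @return Named numeric vector `(dS, dI1, dI2, dR1, dR2)`.
#' @examples
#' p <- siirr_params(0.01, 0.009, 5e-4, 6e-4, N = 1e6)
#' siirr_rhs(siirr_state(998990, 1000, 10, 0, 0), p)
#' @export
siirr_rhs <- function(state, params) {
  if (!all(is.finite(state))) abort("non-finite state component: invalid state")
  S <- state[["S"]]; I1 <- state[["I1"]]; I2 <- state[["I2"]]
  inf1 <- params$tau1 * S * I1 / params$N
  inf2 <- params$tau2 * S * I2 / params$N
  rec1 <- params$rho1 * I1
  rec2 <- params$rho2 * I2
  c(dS = -inf1 - inf2, dI1 = inf1 - rec1, dI2 = inf2 - rec2,
    dR1 = rec1, dR2 = rec2)
}

#' Right-hand side of the classic SIR model
#'
#' The one-strain reduction used as an oracle: the SIIRR system with the
#' second strain absent (`I2 = R2 = 0`) must reproduce it exactly.
#'
#' @param state Named numeric `(S, I, R)`.
#' @param tau,rho Transmission and recovery rate.
#' @param N Total population.
#' @return Named numeric vector `(dS, dI, dR)`.
#' @export
sir_rhs <- function(state, tau, rho, N) {
  if (!all(is.finite(state))) abort("non-finite state component: invalid state")
  S <- state[["S"]]; I <- state[["I"]]
  inf <- tau * S * I / N
  c(dS = -inf, dI = inf - rho * I, dR = rho * I)
}

#' Residuals of the reduced three-equation system
#'
#' The full five-equation system reduces to three equations in `S`, `R1`,
#' `R2`:
#' \deqn{\rho_1^{-1} dR_1/dt + \rho_2^{-1} dR_2/dt = N - R_1 - R_2 - S}
#' \deqn{S^{-1} dS/dt = -N^{-1}(\tau_1\rho_1^{-1} dR_1/dt + \tau_2\rho_2^{-1} dR_2/dt)}
#' \deqn{d^2R_1/dt^2 = \rho_1 (dR_1/dt)(\tau_1 S/(\rho_1 N) - 1)}
#' This evaluates the three residuals along an integrated trajectory with
#' central finite differences for the time derivatives. For a consistent
#' trajectory all residuals tend to zero as the integration tolerance and
#' grid spacing tighten; a corrupted trajectory produces large residuals.
#'
#' @param traj A trajectory from [siirr_integrate()] (or any tibble with
#'   columns `t, S, I1, I2, R1, R2` on a uniform grid of at least 5 points).
#' @return A tibble with columns `t`, `res_balance`, `res_logS`,
#'   `res_r1_curvature`, each scaled by the natural magnitude of its
#'   equation so values are dimensionless.
#' @export
reduced_residuals <- function(traj) {
  if (nrow(traj) < 5) abort("trajectory too short for derivative estimation")
  p <- trajectory_params(traj)
  t <- traj$t
  h <- t[2] - t[1]
  mid <- 2:(nrow(traj) - 1)
  cd <- function(x) (x[mid + 1] - x[mid - 1]) / (2 * h)
  cd2 <- function(x) (x[mid + 1] - 2 * x[mid] + x[mid - 1]) / h^2
  dR1 <- cd(traj$R1); dR2 <- cd(traj$R2); dS <- cd(traj$S)
  d2R1 <- cd2(traj$R1)
  S <- traj$S[mid]; R1 <- traj$R1[mid]; R2 <- traj$R2[mid]
  N <- p$N
  r_bal <- dR1 / p$rho1 + dR2 / p$rho2 - (N - R1 - R2 - S)
  r_logS <- dS / pmax(S, .Machine$double.xmin) +
    (p$tau1 / p$rho1 * dR1 + p$tau2 / p$rho2 * dR2) / N
  r_curv <- d2R1 - p$rho1 * dR1 * (p$tau1 * S / (p$rho1 * N) - 1)
  scale_bal <- max(abs(N - R1 - R2 - S), N * 1e-3)
  scale_logS <- max(abs(dS / pmax(S, 1e-300)), 1e-12)
  scale_curv <- max(abs(d2R1), 1e-12)
  tibble(
    t = t[mid],
    res_balance = r_bal / scale_bal,
    res_logS = r_logS / scale_logS,
    res_r1_curvature = r_curv / scale_curv
  )
}
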