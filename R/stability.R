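#' Jacobian of the SIIRR system
#'
#' Exact analytic partial derivatives of the right-hand side with
#' respect to the state, in the order `(S, I1, I2, R1, R2)`.
#'
#' @param state Named numeric state, see [siirr_state()].
#' @param params A [siirr_params()].
#' @return A 5x5 numeric matrix with dimnames.
#' @export
siirr_jacobian <- function(state, params) {
  validate_state(state)
  S <- state[["S"]]; I1 <- state[["I1"]]; I2 <- state[["I2"]]
  t1N <- params$tau1 / params$N; t2N <- params$tau2 / params$N
  nm <- c("S", "I1", "I2", "R1", "R2")
  J <- matrix(0, 5, 5, dimnames = list(nm, nm))
  J["S", "S"] <- -t1N * I1 - t2N * I2
  J["S", "I1"] <- -t1N * S
  J["S", "I2"] <- -t2N * S
  J["I1", "S"] <- t1N * I1
  J["I1", "I1"] <- t1N * S - params$rho1
  J["I2", "S"] <- t2N * I2
  J["I2", "I2"] <- t2N * S - params$rho2
  J["R1", "I1"] <- params$rho1
  J["R2", "I2"] <- params$rho2
  J
}

#' Disease-free fixed point
#'
#' The model's fixed points form a two-parameter family
#' `(S*, 0, 0, R1*, N - S* - R1*)`: any state with both infected classes
#' empty is stationary.
#'
#' @param S_star,R1_star Susceptible and strain-1-recovered counts at the
#'   fixed point (`>= 0`, with `S_star + R1_star <= N`).
#' @param N Total population.
#' @return A state vector (class as [siirr_state()]) with `I1 = I2 = 0`.
#' @export
siirr_fixed_point <- function(S_star, R1_star, N) {
  R2_star <- N - S_star - R1_star
  if (R2_star < -1e-9 * N) abort("S_star + R1_star exceeds N")
  siirr_state(S_star, 0, 0, R1_star, max(R2_star, 0))
}

#' Closed-form eigenvalues at a disease-free fixed point
#'
#' At any fixed point of the family the Jacobian has three structurally
#' zero eigenvalues (the `S`, `R1`, `R2` rows depend only on the vanished
#' infected classes) and two informative ones:
#' \deqn{\lambda_4 = \tau_2 S^*/N - \rho_2, \qquad
#'       \lambda_5 = \tau_1 S^*/N - \rho_1.}
#'
#' @param fp A fixed point from [siirr_fixed_point()].
#' @param params A [siirr_params()].
#' @return Numeric vector `(0, 0, 0, lambda4, lambda5)`.
#' @export
eigenvalues_closed_form <- function(fp, params) {
  S_star <- fp[["S"]]
  c(0, 0, 0,
    params$tau2 * S_star / params$N - params$rho2,
    params$tau1 * S_star / params$N - params$rho1)
}

#' Classify a disease-free fixed point
#'
#' Marginally stable iff `S* <= N * min(rho1/tau1, rho2/tau2)` (the
#' boundary is inclusive): every nonzero eigenvalue is then non-positive,
#' with zeros always present. Otherwise unstable. A zero transmission
#' rate removes the corresponding threshold (that strain can never grow).
#'
#' @param fp A fixed point from [siirr_fixed_point()].
#' @param params A [siirr_params()].
#' @return `"marginally_stable"` or `"unstable"`.
#' @export
classify_fixed_point <- function(fp, params) {
  lam <- eigenvalues_closed_form(fp, params)
  if (max(lam) > 0) "unstable" else "marginally_stable"
}

#' Full stability analysis at a fixed point
#'
#' Builds the analytic Jacobian, computes its spectrum with a dense
#' eigenvalue solver, pairs it with the closed-form eigenvalues, and
#' classifies the fixed point. Numerical eigenvalues are reported sorted
#' by increasing absolute value, so the first three are the structurally
#' zero ones (zero to within `1e-9` times the largest Jacobian entry).
#'
#' @param fp A fixed point from [siirr_fixed_point()].
#' @param params A [siirr_params()].
#' @return An object of class `siirr_stability` with elements
#'   `fixed_point`, `jacobian`, `eigenvalues` (numerical, sorted by
#'   `|lambda|`), `closed_form`, `classification`.
#' @examples
#' p <- siirr_params(0.01, 0.009, 5e-4, 6e-4, N = 1e6)
#' st <- siirr_stability(siirr_fixed_point(2e5, 3e5, N = 1e6), p)
#' tidy(st)
#' glance(st)
#' @export
siirr_stability <- function(fp, params) {
  J <- siirr_jacobian(fp, params)
  # spectrum at a fixed point is real; drop numerically zero imaginary parts
  ev <- Re(eigen(J, only.values = TRUE)$values)
  ev <- ev[order(abs(ev))]
  structure(
    list(fixed_point = fp, jacobian = J, eigenvalues = ev,
         closed_form = eigenvalues_closed_form(fp, params),
         classification = classify_fixed_point(fp, params),
         params = params),
    class = "siirr_stability"
  )
}

#' @export
print.siirr_stability <- function(x, ...) {
  cat("<siirr_stability>\n")
  cat(sprintf("  fixed point: S*=%g R1*=%g R2*=%g\n",
              x$fixed_point[["S"]], x$fixed_point[["R1"]], x$fixed_point[["R2"]]))
  cat("  eigenvalues (|.| sorted):", format(x$eigenvalues, digits = 6), "\n")
  cat("  classification:", x$classification, "\n")
  invisible(x)
}

#' @rdname siirr_stability
#' @param x A `siirr_stability` object.
#' @param ... Unused.
#' @export
tidy.siirr_stability <- function(x, ...) {
  cf <- sort(x$closed_form)
  num <- sort(x$eigenvalues)
  tibble(eigenvalue = num, closed_form = cf,
         abs_diff = abs(num - cf))
}

#' @rdname siirr_stability
#' @export
glance.siirr_stability <- function(x, ...) {
  tibble(
    S_star = x$fixed_point[["S"]],
    R1_star = x$fixed_point[["R1"]],
    R2_star = x$fixed_point[["R2"]],
    n_zero = sum(abs(x$eigenvalues) <= 1e-9 * max(abs(x$jacobian))),
    lambda_max = max(x$eigenvalues),
    classification = x$classification
  )
}
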