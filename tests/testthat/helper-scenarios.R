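# Shared fixtures, built in code.

fig1_params <- function() siirr_params(0.01, 0.009, 5e-4, 6e-4, N = 1e6)

fig1_scenario <- function(...) {
  siirr_scenario(S0 = 998990, I1_0 = 1000, I2_0 = 10,
                 tau1 = 0.01, tau2 = 0.009, rho1 = 5e-4, rho2 = 6e-4,
                 label = "fig1", ...)
}

# memoized reference trajectory at default tolerances
fig1_trajectory <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- siirr_integrate(fig1_scenario())
    cache
  }
})

# near-threshold scenario for the analytic chain: ratio = tau1 S0/(rho1 N),
# strain 2 tiny, rho2 = rho1 (the closed-form branch's special case)
analytic_scenario <- function(ratio, I1_0 = 100, I2_0 = 1, S0 = 1e6,
                              rho = 5e-4) {
  N <- S0 + I1_0 + I2_0
  tau1 <- ratio * rho * N / S0
  siirr_scenario(S0 = S0, I1_0 = I1_0, I2_0 = I2_0,
                 tau1 = tau1, tau2 = 0.9 * tau1, rho1 = rho, rho2 = rho,
                 label = sprintf("near-threshold r=%g", ratio))
}

# five-point central difference, O(h^4)
fd_deriv <- function(f, t, h) {
  (-f(t + 2 * h) + 8 * f(t + h) - 8 * f(t - h) + f(t - 2 * h)) / (12 * h)
}

random_params <- function() {
  siirr_params(tau1 = runif(1, 0, 0.05), tau2 = runif(1, 0, 0.05),
               rho1 = runif(1, 1e-5, 0.02), rho2 = runif(1, 1e-5, 0.02),
               N = runif(1, 1e3, 1e7))
}

random_state <- function(N) {
  w <- runif(5)
  y <- N * w / sum(w)
  siirr_state(y[1], y[2], y[3], y[4], y[5])
}
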