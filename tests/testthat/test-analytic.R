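test_that("S as a function of the recovered counts is exact along a trajectory", {
  traj <- fig1_trajectory()
  p <- fig1_params()
  S_rec <- s_of_r(traj$R1, traj$R2, p, S0 = traj$S[1])
  expect_lt(max(abs(S_rec - traj$S)), 1e-6 * p$N)
  # boundary values and the monotone limit
  expect_equal(s_of_r(0, 0, p, 998990), 998990)
  expect_lt(s_of_r(1e9, 0, p, 998990), 1e-3)
  expect_true(all(diff(s_of_r(seq(0, 1e6, length.out = 50), 0, p, 998990)) < 0))
})

test_that("truncated series is the geometric partial sum with its error bound", {
  p <- fig1_params()
  S0 <- 998990
  expect_equal(s_taylor(0, p, S0, M = 7), S0)
  # x = tau1 R1/(rho1 N) = 0.1 at R1 = 5000: two-term sum is (1 - x) S0
  expect_equal(s_taylor(5000, p, S0, M = 1), 0.9 * S0)
  # partial geometric sums converge to S0/(1+x) within x^(M+1)/(1-x)
  R1 <- 25000 # x = 0.5
  x <- p$tau1 * R1 / (p$rho1 * p$N)
  for (M in c(1, 3, 6, 12)) {
    err <- abs(s_taylor(R1, p, S0, M) - S0 / (1 + x))
    expect_lte(err, S0 * x^(M + 1) / (1 - x) + 1e-9)
  }
})

test_that("constants enforce the defining initial conditions", {
  sc <- analytic_scenario(1.2)
  rc <- riccati_constants(sc$params, sc$initial[["S"]], sc$initial[["I1"]])
  N <- sc$params$N
  expect_lt(abs(r1_analytic(0, rc)), 1e-8 * N)
  expect_lt(abs(r2_analytic(0, rc)), 1e-8 * N)
  # I1(0) and I2(0) are recovered through I = dR/dt / rho
  expect_equal(i1_analytic(0, rc), 100, tolerance = 1e-6)
  expect_equal(i2_analytic(0, rc), 1, tolerance = 1e-6)
  # alpha2 < 0 and theta^2 > 0 in the admissible family
  expect_lt(rc$alpha2, 0)
  expect_gt(rc$theta, 0)
})

test_that("root-solved constants match the printed closed forms", {
  for (r in c(1.3, 1.1, 0.9)) {
    sc <- analytic_scenario(r)
    rc <- riccati_constants(sc$params, sc$initial[["S"]], sc$initial[["I1"]])
    expect_equal(rc$V, rc$V_closed, tolerance = 1e-9)
    # theta radical (resolved grouping) and D = S(0) - N, exact when rho2 = rho1
    expect_equal(rc$theta, rc$theta_printed, tolerance = 1e-12)
    expect_equal(rc$D, rc$D_printed, tolerance = 1e-9)
  }
})

test_that("R1 satisfies its Riccati equation and is a monotone plateau curve", {
  sc <- analytic_scenario(1.2)
  rc <- riccati_constants(sc$params, sc$initial[["S"]], sc$initial[["I1"]])
  tg <- seq(0, 4 * abs(rc$V), length.out = 1000)
  h <- 0.02 / max(rc$theta, rc$p)
  lhs <- fd_deriv(function(t) r1_analytic(t, rc), tg, h)
  rhs <- rc$alpha2 * r1_analytic(tg, rc)^2 + rc$alpha1 * r1_analytic(tg, rc) +
    rc$alpha0
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-6)
  r1 <- r1_analytic(tg, rc)
  expect_true(all(diff(r1) >= 0))
  # tanh plateau: the strain-1 final size
  plateau <- (-rc$alpha1 - rc$theta) / (2 * rc$alpha2)
  expect_equal(r1_analytic(1e9, rc), plateau, tolerance = 1e-9)
})

test_that("the general Riccati branch also satisfies the equation", {
  sc <- analytic_scenario(1.2)
  rc <- riccati_constants(sc$params, sc$initial[["S"]], sc$initial[["I1"]])
  tg <- seq(0, 2 * abs(rc$V), length.out = 200)
  h <- 0.02 / max(rc$theta, rc$p)
  W <- 1e3; E <- 5
  f <- function(t) r1_analytic(t, rc, W = W, E = E)
  lhs <- fd_deriv(f, tg, h)
  rhs <- rc$alpha2 * f(tg)^2 + rc$alpha1 * f(tg) + rc$alpha0
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-6)
})

test_that("R2 satisfies the linear equation driven by the q polynomial", {
  sc <- analytic_scenario(1.2)
  rc <- riccati_constants(sc$params, sc$initial[["S"]], sc$initial[["I1"]])
  tg <- seq(0, 4 * abs(rc$V), length.out = 1000)
  h <- 0.02 / max(rc$theta, rc$p)
  r1 <- r1_analytic(tg, rc)
  q <- rc$beta0 + (rc$beta1 + rc$gamma1) * r1 + rc$beta2 * r1^2
  lhs <- fd_deriv(function(t) r2_analytic(t, rc), tg, h) +
    rc$p * r2_analytic(tg, rc)
  expect_lt(max(abs(lhs - q)) / max(abs(q)), 1e-6)
  # long-time plateau: the strain-2 final size constant
  expect_equal(r2_analytic(1e9, rc), rc$K, tolerance = 1e-9)
})

test_that("the strain-2 branch refuses rho2 != rho1", {
  sc <- analytic_scenario(1.2)
  p <- sc$params
  p_uneq <- siirr_params(p$tau1, p$tau2, p$rho1, 2 * p$rho1, p$N)
  rc <- riccati_constants(p_uneq, sc$initial[["S"]], sc$initial[["I1"]])
  expect_error(r2_analytic(1, rc), "rho2 == rho1")
  expect_error(i2_analytic(1, rc), "rho2 == rho1")
})

test_that("infected closed forms are rho^-1 dR/dt", {
  sc <- analytic_scenario(1.1)
  rc <- riccati_constants(sc$params, sc$initial[["S"]], sc$initial[["I1"]])
  tg <- seq(0, 3 * abs(rc$V), length.out = 400)
  h <- 0.02 / max(rc$theta, rc$p)
  rho <- sc$params$rho1
  i1_fd <- fd_deriv(function(t) r1_analytic(t, rc), tg, h) / rho
  expect_lt(max(abs(i1_fd - i1_analytic(tg, rc))) / max(i1_analytic(tg, rc)),
            1e-6)
  i2_fd <- fd_deriv(function(t) r2_analytic(t, rc), tg, h) / sc$params$rho2
  expect_lt(max(abs(i2_fd - i2_analytic(tg, rc))) /
              max(abs(i2_analytic(tg, rc))), 1e-6)
})

test_that("the strain-1 bell is symmetric with the stated peak", {
  sc <- analytic_scenario(1.2)
  rc <- riccati_constants(sc$params, sc$initial[["S"]], sc$initial[["I1"]])
  peak <- -rc$theta^2 / (4 * sc$params$rho1 * rc$alpha2)
  expect_gt(peak, 0)
  expect_equal(i1_analytic(-rc$V, rc), peak)
  s <- c(10, 500, 5000, 5e4)
  expect_equal(i1_analytic(-rc$V + s, rc), i1_analytic(-rc$V - s, rc))
  # huge arguments evaluate without overflow
  expect_equal(i1_analytic(1e7, rc), 0, tolerance = 1e-12)
})

test_that("analytic I2 decays monotonically at early times", {
  # the closed-form I2 inherits the truncation error of the strain-1 bell at
  # later times; its contracted behaviour is the early-time exponential decay
  sc <- analytic_scenario(1.05, I1_0 = 100, I2_0 = 1)
  rc <- riccati_constants(sc$params, sc$initial[["S"]], sc$initial[["I1"]])
  early <- seq(0, 0.1 * abs(rc$V), length.out = 200)
  i2 <- i2_analytic(early, rc)
  expect_equal(i2[1], 1, tolerance = 1e-6)
  expect_true(all(diff(i2) <= 0))
})

test_that("validity diagnostics flag the reference scenario and pass near threshold", {
  traj <- fig1_trajectory()
  vm <- validity_metric(traj)
  expect_gt(vm$strain1_max, 1)
  expect_false(vm$regime_ok)
  # trivially in regime: no recovered individuals at all
  empty <- traj[1, ]
  attr(empty, "scenario") <- attr(traj, "scenario")
  vm0 <- validity_metric(empty)
  expect_equal(vm0$strain1_max, 0)
  expect_true(vm0$regime_ok)
  # near threshold the final sizes are small
  sc <- analytic_scenario(1.05)
  rc <- riccati_constants(sc$params, sc$initial[["S"]], sc$initial[["I1"]])
  expect_true(validity_metric(rc)$regime_ok)
})

test_that("analytic and integrated strain-1 waves converge as the threshold nears", {
  devs <- vapply(c(1.4, 1.2, 1.1, 1.05), function(r) {
    sc <- analytic_scenario(r)
    rc <- riccati_constants(sc$params, sc$initial[["S"]], sc$initial[["I1"]])
    times <- seq(0, 2 * abs(rc$V), length.out = 1001)
    traj <- siirr_integrate(sc, t_end = max(times), n_out = 1001)
    max(abs(i1_analytic(times, rc) - traj$I1)) / max(traj$I1)
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
})

test_that("constants builder validates its preconditions", {
  p <- fig1_params()
  expect_error(riccati_constants(p, 0, 100), "S0 and I1_0")
  expect_error(riccati_constants(p, 1e5, -1), "S0 and I1_0")
})

test_that("full analytic evaluation returns consistent curves", {
  sc <- analytic_scenario(1.1)
  curves <- siirr_analytic(sc)
  rc <- attr(curves, "constants")
  expect_equal(names(curves), c("t", "S_approx", "I1", "I2", "R1", "R2"))
  expect_equal(curves$R1[1], 0, tolerance = 1e-6)
  expect_equal(curves$S_approx[1], sc$initial[["S"]])
  expect_equal(max(curves$I1), -rc$theta^2 / (4 * sc$params$rho1 * rc$alpha2),
               tolerance = 1e-4)
  sc_r <- siirr_scenario(S0 = 1e5, I1_0 = 10, I2_0 = 1, R1_0 = 5,
                         tau1 = 0.01, tau2 = 0.009, rho1 = 5e-4, rho2 = 5e-4)
  expect_error(siirr_analytic(sc_r), "R1\\(0\\)")
})
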