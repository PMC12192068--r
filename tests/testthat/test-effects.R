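test_that("registry scenarios are valid and anchored to the reference values", {
  reg <- siirr_scenarios()
  expect_true(all(!duplicated(reg$name)))
  for (sc in reg$scenario) {
    expect_s3_class(sc, "siirr_scenario")
    expect_equal(sum(sc$initial), sc$params$N, tolerance = 1e-12)
  }
  f1 <- get_scenario("fig1_base")
  expect_equal(f1$params$N, 1e6)
  expect_equal(unname(f1$initial[c("S", "I1", "I2")]), c(998990, 1000, 10))
  f9 <- get_scenario("fig9_base")
  expect_equal(unname(f9$initial[["I1"]]), 10000)
  expect_equal(unname(f9$initial[["I2"]]), 10000)
  expect_equal(unname(f9$initial[["S"]]), 980000)
  expect_error(get_scenario("nope"), "unknown scenario")
  # caption irregularities are carried as notes
  expect_true(any(!is.na(reg$caption_note)))
})

test_that("reference scenario report: two bells, strain 2 first, forgetting", {
  eff <- detect_effects(fig1_trajectory())
  g <- glance(eff)
  expect_equal(eff$peaks$profile_class, c("bell", "bell"))
  expect_equal(g$peak_order, "I2")
  expect_true(g$forgetting)
  expect_false(g$single_peak)
  expect_false(any(eff$suppression))
  # a window of dominance exists: I1 still rising while I2 falls
  w <- eff$dominance_windows
  expect_gt(nrow(w), 0)
  expect_true(all(w$start < w$end))
  expect_equal(w$falling, ifelse(w$rising == "I1", "I2", "I1"))
  expect_true(all(w$start >= 0 & w$end <= max(fig1_trajectory()$t)))
  if (nrow(w) > 1) expect_true(all(w$start[-1] >= w$end[-nrow(w)]))
})

test_that("small susceptible pools suppress both popularity waves", {
  traj <- siirr_integrate(get_scenario("fig2_S0_10000"), t_end = 20000,
                          n_out = 2001)
  eff <- detect_effects(traj)
  expect_true(all(eff$suppression))
  expect_equal(nrow(eff$dominance_windows), 0)
  expect_false(eff$single_peak)
})

test_that("intermediate susceptible pool yields the single-peak effect", {
  traj <- siirr_integrate(get_scenario("fig11_S0_60000"))
  eff <- detect_effects(traj)
  expect_true(eff$single_peak)
  pk <- eff$peaks
  expect_equal(pk$profile_class[pk$compartment == "I1"], "bell")
  expect_equal(pk$profile_class[pk$compartment == "I2"], "monotone_decay")
})

test_that("forgetting is undetermined while a strain is still growing", {
  traj <- siirr_integrate(fig1_scenario(), t_end = 500, n_out = 501)
  eff <- detect_effects(traj)
  expect_true(is.na(eff$forgetting))
})

test_that("short-term win-long-term loss on the reference scenario", {
  eff <- detect_effects(fig1_trajectory())
  # the earlier-peaking strain also decays to half peak faster
  hd <- eff$stwltl$half_decay
  expect_equal(eff$stwltl$first_peak, "I2")
  expect_lt(hd[["I2"]], hd[["I1"]])
  expect_true(eff$stwltl$present)
  expect_equal(eff$stwltl$higher_peak, "I1")
})

test_that("strain swap swaps the per-strain report fields exactly", {
  sc <- fig1_scenario(t_end = 8000, n_out = 1601)
  eff <- detect_effects(siirr_integrate(sc))
  eff_sw <- detect_effects(siirr_integrate(swap_strains(sc)))
  pk <- eff$peaks; pk_sw <- eff_sw$peaks
  expect_equal(pk$t_peak[pk$compartment == "I1"],
               pk_sw$t_peak[pk_sw$compartment == "I2"])
  expect_equal(pk$value_peak[pk$compartment == "I2"],
               pk_sw$value_peak[pk_sw$compartment == "I1"])
  expect_equal(unname(eff$suppression[c("I1", "I2")]),
               unname(eff_sw$suppression[c("I2", "I1")]))
  expect_equal(eff$stwltl$first_peak,
               c(I1 = "I2", I2 = "I1")[[eff_sw$stwltl$first_peak]])
  w <- eff$dominance_windows; w_sw <- eff_sw$dominance_windows
  expect_equal(w$start, w_sw$start)
  expect_equal(w$rising, ifelse(w_sw$rising == "I1", "I2", "I1"))
})

test_that("raising the initial positive popularity advances and grows its peak while suppressing the rival", {
  sw <- siirr_sweep(fig1_scenario(), "I1_0", c(5000, 10000),
                    t_end = 20000, n_out = 2001)
  expect_true(all(diff(sw$t_peak_I1) < 0))
  expect_true(all(diff(sw$peak_I1) > 0))
  expect_true(all(diff(sw$peak_I2) < 0))
})

test_that("raising the rival transmission rate grows the rival peak and curbs the dominant one", {
  sw <- siirr_sweep(fig1_scenario(), "tau2", c(0.002, 0.009, 0.011, 0.015),
                    t_end = 20000, n_out = 2001)
  expect_true(all(diff(sw$peak_I2) > 0))
  expect_true(all(diff(sw$peak_I1) < 0))
  expect_true(all(diff(sw$t_peak_I1) < 0))
  # the rival peak moves later while strain 2 remains the minor strain;
  # once it rivals strain 1 (largest value) the shift reverses
  expect_true(all(diff(sw$t_peak_I2[1:3]) > 0))
})

test_that("raising the recovery rate of a strain shrinks its own peak and feeds the rival", {
  # dominant-strain study values (the rival-strain panel stops at 0.005)
  sw7 <- siirr_sweep(fig1_scenario(), "rho1", c(0.0005, 0.0025, 0.005, 0.0075),
                     t_end = 20000, n_out = 2001)
  expect_true(all(diff(sw7$peak_I1) < 0))
  expect_true(all(diff(sw7$peak_I2) > 0))
  expect_true(all(diff(sw7$t_peak_I2[1:3]) > 0))
  # faster decay of the strain whose recovery rate rose
  hd1 <- vapply(sw7$report, function(r) r$stwltl$half_decay[["I1"]], numeric(1))
  expect_true(all(diff(hd1) < 0))
  # equal-initial-infection study values: every ordering holds, including
  # the advance of the strain-1 peak
  sw12 <- siirr_sweep(get_scenario("fig9_base"), "rho1",
                      c(0.0002, 0.001, 0.003, 0.005),
                      t_end = 20000, n_out = 2001)
  expect_true(all(diff(sw12$peak_I1) < 0))
  expect_true(all(diff(sw12$t_peak_I1) < 0))
  expect_true(all(diff(sw12$peak_I2) > 0))
  expect_true(all(diff(sw12$t_peak_I2) > 0))
  # the rival peak eventually exceeds the dominant one
  expect_gt(sw12$peak_I2[4], sw12$peak_I1[4])
})

test_that("sweeps keep going past inadmissible values", {
  sw <- siirr_sweep(fig1_scenario(), "rho1", c(-0.1, 0.0005),
                    t_end = 2000, n_out = 201)
  expect_false(is.na(sw$error[1]))
  expect_true(is.na(sw$error[2]))
  expect_false(is.na(sw$peak_I1[2]))
})

test_that("sweep validates the parameter name", {
  expect_error(siirr_sweep(fig1_scenario(), "gamma", 1), "arg")
})
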