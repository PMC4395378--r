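test_that("rate constants match the printed expressions, including limits", {
  # removable singularities evaluated by their analytic limits
  expect_equal(rate_constants(-55, TC = 6.3)[, "alpha_n"], 0.1,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(rate_constants(-40, TC = 6.3)[, "alpha_m"], 1.0,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(rate_constants(-65, TC = 6.3)[, "beta_m"], 4.0,
               ignore_attr = TRUE)

  # whole curve against direct evaluation at several temperatures
  v <- seq(-120, 60, by = 7.3)
  for (tc in c(6.3, 18.5, 26)) {
    expect_equal(unclass(rate_constants(v, tc)), rates_reference(v, tc),
                 tolerance = 1e-10)
  }
  # all six rates scale together by Q10
  r1 <- rate_constants(-65, 6.3)
  r2 <- rate_constants(-65, 18.5)
  expect_equal(as.numeric(r2 / r1), rep(3 ^ 1.22, 6), tolerance = 1e-12)
})

test_that("steady-state gates are temperature independent and bounded", {
  v <- seq(-110, 60, by = 11)
  g1 <- steady_state_gates(v, TC = 6.3)
  g2 <- steady_state_gates(v, TC = 26)
  expect_equal(g1, g2, tolerance = 1e-12)
  expect_true(all(g1 >= 0 & g1 <= 1))
  # m activates with depolarization
  expect_gt(steady_state_gates(50)[, "m"], 0.99)
  r <- rate_constants(-65, 6.3)
  expect_equal(steady_state_gates(-65)[, "n"],
               r[, "alpha_n"] / (r[, "alpha_n"] + r[, "beta_n"]),
               ignore_attr = TRUE)
})

test_that("leak potential fit makes the resting state exactly stationary", {
  # leak-only axon rests at V_L
  expect_equal(solve_leak_potential(0, 0, 0.3), -65)
  expect_error(solve_leak_potential(120, 36, G_L = 0), "G_L")

  # fitted V_L satisfies the current balance
  vl <- solve_leak_potential(120, 36, 0.3)
  g <- steady_state_gates(-65)
  bal <- 36 * g[, "n"]^4 * (-65 + 77) + 120 * g[, "m"]^3 * g[, "h"] *
    (-65 - 50) + 0.3 * (-65 - vl)
  expect_equal(unname(bal), 0, tolerance = 1e-10)

  # unstimulated simulation holds -65 mV to < 0.1 mV for several phenotypes
  for (gg in list(c(120, 36), c(81, 36), c(300, 10))) {
    p <- params_185(t_total = 20)
    sim <- simulate_axon(p, conductances(gg[1], gg[2], p), record_at = 5,
                         stim_amp = 0)
    expect_lt(max(abs(sim$v + 65)), 0.1)
    expect_lt(max(abs(sim$final$v + 65)), 0.1)
  }
})

test_that("gating capacitance is linear in closed fraction and in G_Na", {
  expect_equal(gating_capacitance(1, 120), 0)
  expect_equal(gating_capacitance(0, 120), 0.13)
  expect_equal(gating_capacitance(0, 240), 0.26)
  expect_equal(gating_capacitance(0.5, 60), 0.13 * 0.5 * 0.5)
  expect_error(gating_capacitance(1.2, 120))
})

test_that("a single action potential propagates the full cable at defaults", {
  sim <- default_sim()
  met <- ap_metrics(sim)
  expect_true(met$conducted)
  expect_equal(met$spike_count, 1)
  expect_gt(met$velocity, 15)
  expect_lt(met$velocity, 30)
  expect_gt(met$na_flux, 0)
  expect_lte(met$apd50, met$apd90)
  # gates stay within [0, 1] at every recorded node and step
  for (gate in c("m", "h", "n"))
    expect_true(all(sim[[gate]] >= 0 & sim[[gate]] <= 1))
})

test_that("conduction velocity is independent of the stimulus amplitude", {
  v20 <- ap_metrics(default_sim(stim_amp = 20))$velocity
  v40 <- ap_metrics(default_sim(stim_amp = 40))$velocity
  expect_lt(abs(v40 / v20 - 1), 0.005)
})

test_that("halving dt and dx changes the measured velocity by under 1%", {
  v1 <- ap_metrics(default_sim())$velocity
  p2 <- cable_params(TC = 18.5, t_total = 12, dt = 5e-4, dx = 5e-3)
  v2 <- ap_metrics(simulate_axon(p2, conductances(120, 36, p2)))$velocity
  expect_lt(abs(v2 / v1 - 1), 0.01)
})

test_that("zero sodium conductance means no spike anywhere", {
  sim <- default_sim(g_na = 0, t_total = 8)
  met <- ap_metrics(sim)
  expect_false(met$conducted)
  expect_equal(met$spike_count, 0)
  expect_true(is.na(met$velocity))
  expect_equal(met$na_flux, 0)
})

test_that("trace export has one voltage column per recording site", {
  sim <- default_sim(t_total = 5, record_at = c(2.5, 7.5))
  df <- as.data.frame(sim)
  expect_named(df, c("time_ms", "v_2.495_cm", "v_7.495_cm"))
  expect_equal(nrow(df), length(sim$time))
})

test_that("invalid discretization and geometry are rejected", {
  expect_error(cable_params(dx = 0.3), "divide")
  expect_error(cable_params(dt = 0), "dt")
})
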